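# nemaspindle

Quantification of mitotic-spindle mechanics during the first asymmetric
embryonic division of nematodes, and phylogenetic comparative analysis of
how those mechanics evolve.

The first division of the one-cell nematode embryo is asymmetric: the
spindle is displaced toward the posterior while it elongates and, in
*Caenorhabditis* species, its poles rock in antiphase across the transverse
axis. The degree of asymmetry, the displacement, the elongation and the
oscillations all vary between strains and species. This package is for
evolutionary cell biologists who want to turn centrosome trajectory tables
into quantitative traits and ask how those traits change along a phylogeny:
whether they drift like a random walk or sit near an optimum, which traits
covary once phylogenetic inertia is removed, and how robust those
conclusions are to measurement error.

## What it computes

* **Trait extraction** — 22 traits per embryo from anterior/posterior
  centrosome tracks (0.5 s frames, micrometre coordinates) plus cell
  geometry: cell size/shape/asymmetry, spindle positions and displacement,
  elongation plateaus `L0`, `Lf`, fold `Lf/L0`, duration and speed, and
  transverse-oscillation amplitudes (peak-to-valley, um), frequencies
  (mHz), total duration (s) and posterior/anterior asymmetry ratios.
* **Evolutionary models** — phylogenetically independent contrasts by the
  pruning recursion; Brownian-motion likelihood in O(n) with closed-form ML
  fit (σ̂², ẑ₀); single-optimum Ornstein–Uhlenbeck fit with covariance
  σ²/(2α)·e^(−α d_ij)(1 − e^(−2α s_ij)) and α profiled on the log scale;
  likelihood-ratio model comparison against χ²₁; GLS ancestral states for
  continuous trait maps; species means by arithmetic averaging or a
  hierarchical Gibbs sampler (strains ~ Normal(species mean, σ²_w),
  species means ~ Brownian on the tree).
* **Comparative battery** — trait-pair correlations of contrasts with
  1,000-fold one-strain-per-species resampling and within-replicate BH
  adjustment; Kruskal–Wallis species-difference tests at FDR 0.001;
  selfer/outbreeder-style variance F tests; correlation-matrix PCA of the
  phenotypic space with permutation tests of metadata groupings; and a
  measurement-error robustness simulation (1%, 5%, 10% multiplicative
  error on every measurement).
* **Synthetic cohorts** — a seeded generator that evolves species trait
  means on a tree, adds strain- and embryo-level dispersion, and renders
  centrosome trajectories (logistic displacement/elongation ramps,
  antiphase sinusoids under a raised-cosine envelope, Gaussian tracking
  noise), so the whole pipeline runs and is tested end to end without any
  video data.

## Worked example

Generate a small cohort, extract traits from one oscillating embryo, and
compare evolutionary models for a simulated trait:

```r
library(nemaspindle)

cfg <- generator_config(n_species = 12, strains_per_species = 2,
                        embryos_per_strain = 3, seed = 7)
coh <- generate_cohort(cfg)
i <- which(coh$ground_truth$embryo$species %in% coh$oscillating_species)[1]
rec <- coh$recordings[[i]]
rec
#> embryo recording: s2_st1 (s2), 611 frames at 0.5 s, cell 53.3 x 33.8 um

round(extract_all(rec)$traits[c("relative_asymmetry", "spindle_displacement_um",
                                "elongation_fold", "osc_max_amplitude_post_um",
                                "osc_frequency_post_mhz", "osc_asymmetry_max")], 2)
#>        relative_asymmetry   spindle_displacement_um           elongation_fold
#>                      1.42                      5.15                      1.66
#> osc_max_amplitude_post_um    osc_frequency_post_mhz         osc_asymmetry_max
#>                      5.89                     37.27                      1.26
```

So this embryo divided with an AB/P1 length ratio of 1.42, its spindle
moved 5.15 um posteriorly and elongated 1.66-fold, and the posterior pole
oscillated with a 5.89 um maximum excursion at 37 mHz, 1.26 times the
anterior amplitude. (The generator's ground truth for this embryo was
1.42, 5.02 um, 1.66, 6.38 um, 40.5 mHz and 1.28 — extraction recovers each
trait to within a few percent.)

```r
x <- simulate_trait_evolution(coh$tree, list(type = "BM", sigma2 = 2, root = 0),
                              seed = 9)
fb <- fit_bm(coh$tree, x)
fo <- fit_ou(coh$tree, x)
fb
#> BM fit (ML): sigma2 = 2.30675, root/optimum = -0.216709, logLik = -15.651, n = 12 tips
lrt_bm_vs_ou(fb, fo)$p_value
#> [1] 1
```

For this Brownian-simulated trait the OU attraction term adds nothing (the
fit collapses onto the α = 0 boundary), so the likelihood-ratio test
returns p = 1 and the random-walk model is retained.

## The analysis workflow

The numbered drivers in `analysis/` run the full study on a synthetic
cohort at the original scale (42 species, ~126 strains, ~1,260 embryos)
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort config, tree, ground truth
Rscript analysis/02_extract_traits.R       # per-embryo and per-strain trait tables
Rscript analysis/03_model_comparison.R     # BM vs OU per trait, ancestral states
Rscript analysis/04_correlations.R         # resampled + species-mean PIC correlations
Rscript analysis/05_phenotypic_space.R     # PCA, Kruskal-Wallis, variance F tests
Rscript analysis/06_error_robustness.R     # 1/5/10% measurement-error simulation
```

Each stage prints a one-paragraph summary of what it found; all outputs
are regenerable from the stage-1 configuration and its seed.

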