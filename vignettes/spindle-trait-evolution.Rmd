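---
title: "Quantifying and comparing spindle mechanics across a nematode phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing spindle mechanics across a nematode phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The scientific problem

During the first embryonic division of rhabditid nematodes the mitotic
spindle is positioned asymmetrically: it is displaced toward the posterior
while it elongates, and in *Caenorhabditis* species its two poles rock in
antiphase across the transverse axis. The division is asymmetric in every
species, but the movements that produce it — displacement, elongation,
oscillation — vary widely between and within species. `nemaspindle`
implements the full quantitative pipeline for studying that variation:
trait extraction from centrosome trajectories, evolutionary model fitting
on a species phylogeny, and the comparative statistical battery, together
with a synthetic-cohort generator that makes every stage testable end to
end without any microscopy data.

The pipeline is organised as an analysis workflow: the numbered scripts in
`analysis/` are thin narrative drivers over the package functions, writing
their tables under `results/`; the same functions are exercised by the test
suite and by `scripts/acceptance.R`.

# The trait inventory

Each embryo recording is a pair of centrosome tracks (anterior and
posterior, x antero/posterior with origin at the cell center and positive
toward posterior, y transverse with origin at the cell equator, both in
micrometres, frames every 0.5 s, t = 0 at nuclear envelope breakdown) plus
cell geometry. From this `extract_all()` computes 22 traits:

* **Geometry (5)**: cell length and width (um), their aspect ratio, the
  division-plane position (P1 daughter length, um) and the relative
  asymmetry (AB/P1 length ratio).
* **Position (3)**: initial spindle position (the most anterior excursion
  of the spindle/nuclei center before elongation onset; negative =
  anterior overshoot), final position (mean over the terminal plateau of
  the center series), and their difference, the displacement.
* **Elongation (5)**: initial and final spindle length (the two plateaus
  of the pole-to-pole distance), their ratio (elongation fold), the
  elongation duration, and the mean elongation speed.
* **Oscillations (9)**: per centrosome the maximum and mean peak-to-valley
  amplitude (um) and the frequency (mHz); one total oscillation duration
  (s); and the posterior/anterior ratios of maximum and mean amplitude.

Counting one shared oscillation duration (rather than one per centrosome)
is what makes the inventory come out at 22; the frequency is still scored
per centrosome even though the two poles are mechanically phase-locked, so
the pair of frequency traits doubles as an internal consistency check.

Amplitudes follow the *peak-to-valley excursion* convention: the absolute
value difference between successive extrema. This matches the magnitude of
the classically reported values for *C. elegans*-scale oscillations
(maximum posterior excursions of several micrometres); envelope
half-heights would be half as large.

# Trait-extraction procedure and its tunables

All settings live in `extraction_settings()` and are logged with results.

* **Smoothing**: centered moving average, 5 frames (2.5 s). Wide enough to
  suppress sub-pixel tracking jitter, narrow enough that a 64 mHz
  oscillation (the fast end of the observed range) is attenuated by < 5%.
* **Extrema**: alternating peaks/valleys on the smoothed transverse track;
  extrema are pruned until every successive excursion reaches the
  **prominence** threshold of 0.5 um (about five times the tracking noise
  SD). Slopes within `1e-9` of zero are treated as flat so that adding a
  constant to the series (an equator offset) or reflecting it cannot move
  an extremum through floating-point ties.
* **Frequency**: `1000 / mean full-cycle length` in mHz when at least
  three same-kind extrema exist, else cycle count over duration; the rule
  used is recorded. Duration is the time between first and last extremum;
  profiles with fewer than two extrema are flagged, not scored.
* **Plateaus**: the manual first/final-plateau reading is replaced by a
  slope rule: plateau = longest prefix/suffix with smoothed slope below
  `max(0.01 um/s, 5% of the peak slope)`. The elongation interval is then
  bounded by the crossings of 2% of the total rise above/below the plateau
  levels. The 2% fraction was calibrated once on noise-free logistic
  ramps so that the detected interval matches the nominal 2.5%-97.5% rise
  of the ramp despite the slight contamination of plateau means by the
  ramp tails; shallow, very slow ramps (rise of a few micrometres over
  > 300 s) remain biased short by up to ~25% and are the known weak spot
  of the rule.
* **Gaps**: track gaps up to 5 frames are linearly interpolated; longer
  gaps are an error, never silently filled.
* **Exclusion rule**: if the center track is already moving posteriorly at
  the first frames and its minimum sits at the recording start, the
  anterior-most position is undetectable and the embryo is flagged
  (`started_after_rotation`) rather than scored.

# The synthetic cohort

`generate_cohort()` emulates the study design: 42 species on a unit-depth
Yule phylogeny, 3 strains per species, 10 embryos per strain (~1,260
recordings), frames every 0.5 s. Species trait means evolve by Brownian
motion with roots at *C. elegans*-like values (e.g. posterior amplitude
6 um, frequency 45 mHz, elongation fold 1.92, relative asymmetry 1.29) and
rates chosen so the simulated species span the reported ranges (amplitudes
~1.5-12.5 um, frequencies ~29-64 mHz, oscillation durations ~64-369 s,
folds ~1.4-2.8). Strain and embryo values are Gaussian around their parent
level, truncated to physical bounds by resampling (clipping would distort
the distribution shape); oscillations are confined to one clade covering
roughly 60% of species, emulating the genus-level innovation of transverse
rocking.

Rendering is kinematic, not biophysical: spindle center and length follow
logistic ramps whose 2.5%-97.5% rise spans the elongation-duration trait;
transverse tracks are antiphase sinusoids under a raised-cosine envelope;
i.i.d. Gaussian tracking noise (SD 0.1 um, about one pixel) is added to
every coordinate. The envelope support is scaled by `1/(1 - 2u*)`, where
`u*` is the phase fraction whose excursion falls below the 0.5 um
detection prominence, so that the span of *detectable* extrema matches the
oscillation-duration trait; the residual disagreement is of the order of a
quarter oscillation period at each end. The "true" mean amplitude of a
rendered embryo is defined consistently as the maximum amplitude times the
mean envelope factor over the detectable span.

What the generator does **not** emulate: force-generator stochastics,
amplitude drift unrelated to a smooth envelope, rotation/centering
kinetics before NEB, frame drop-outs, or tracking failures. Passing
recovery tests therefore shows that the extraction conventions are
self-consistent and noise-robust at realistic magnitudes — not that they
are correct for every pathology of real DIC tracking.

# Evolutionary models

All comparative machinery runs on `ape` `"phylo"` trees with validated
branch lengths.

* **Contrasts** (`pic_contrasts`): the pruning recursion — contrast
  `(v1 - v2)/sqrt(t1 + t2)` at each internal node, variance-weighted
  averages propagated with branch-length inflation `t + t1 t2/(t1+t2)`.
  Correlations between traits are computed through the origin with
  `n_contrasts - 1` degrees of freedom; on every tree this equals the GLS
  correlation under the Brownian covariance (tested to 1e-8 against a
  dense-matrix oracle).
* **Brownian motion** (`bm_loglik`, `fit_bm`): O(n) pruning likelihood;
  ML estimates in closed form (root = GLS mean, rate = mean squared
  standardized contrast, dividing by n). ML rather than REML is used,
  matching the default of the standard fitting packages in this field; the
  choice is recorded in the fit metadata since the original analyses do
  not state it.
* **Ornstein-Uhlenbeck** (`fit_ou`): single optimum, root clamped at the
  optimum, covariance
  `sigma^2/(2 alpha) e^(-alpha d_ij)(1 - e^(-2 alpha s_ij))`. `alpha` is
  profiled by a bounded golden-section search on the log scale over
  `[1e-8, 50/height]` (stable down to the BM limit; the upper bound stops
  the white-noise plateau), with rate and root in closed form at each
  step; fits at the upper bound carry a convergence note, and if the
  profile never beats BM the exact `alpha = 0` limit is reported.
* **Model choice** (`lrt_bm_vs_ou`): `2 (logL_OU - logL_BM)` clamped at
  zero against chi-square(1), as plain likelihood-ratio tests, without a
  boundary-mixture correction. Because `alpha = 0` lies on the boundary
  this reference is asymptotically conservative, but **on small ultrametric
  trees the test is empirically anticonservative**: with ~50 species,
  profiling `alpha` up to the white-noise regime absorbs enough sampling
  noise that the type-I rate at p < 0.05 is roughly twice nominal,
  relaxing toward nominal by ~200 tips. The acceptance suite measures and
  reports this rate rather than hiding it; OU preferences near p = 0.05 on
  trees of this size should be read accordingly.
* **Ancestral states** (`ancestral_states_bm`): GLS/empirical-Bayes
  conditional expectations of internal nodes at the ML root, equal to the
  re-rooting estimates of independent implementations to 1e-8; linear
  per-branch interpolation supports continuous trait maps.
* **Species means** (`estimate_species_means`): arithmetic averaging, or a
  hierarchical Gibbs sampler for strain values Normal(species mean,
  sigma2_w) with species means Brownian on the tree — a deliberately
  simplified, fully documented hierarchical model in place of the cited
  Bayesian species-mean machinery, whose exact priors are not public. All
  full conditionals are conjugate (inverse-gamma(0.001, 0.001) on both
  variances, flat root); defaults 2,000 iterations, 500 burn-in, seed
  mandatory. With flat data the posterior collapses onto the datum; with
  no within-species noise it reproduces arithmetic means.

# The comparative battery

* **Resampled correlations**: intraspecific variation is large, so each of
  1,000 replicates draws one strain per species, computes the PIC
  correlation for every trait pair, and BH-adjusts within the replicate
  across pairs (the multiple-testing family). Pairs involving oscillation
  traits are restricted to the oscillating clade, where they are defined.
  The original analyses say only that the 1,000 correlations were
  "statistically assessed"; here the documented rule is: *significant* if
  at least 95% of replicates have adjusted p below the level, with the
  median R as the similarity score. Both thresholds are arguments. This is
  deliberately conservative; a pair whose single-draw correlations are
  significant in, say, 90% of replicates is reported with exactly that
  fraction rather than a verdict.
* **Species differences**: Kruskal-Wallis per trait on strain values
  grouped by species (the unit is a documented choice — per-embryo
  grouping is available by passing the embryo table), BH-corrected, with
  the historically used FDR of 0.001.
* **Variance comparison**: the "pairwise F test" between selfing and
  outcrossing groups is under-specified in the original text; here strain
  values are centered by species mean within each group, pooled, and
  compared by a two-sided F test with pooled degrees of freedom, BH across
  traits. The construction is stated in the output.
* **PCA**: correlation-matrix PCA (standardized traits) on complete-case
  rows, component signs fixed so the dominant loading is positive. The
  oscillation-asymmetry ratios are undefined for non-oscillating strains;
  excluding those two traits keeps every strain in the phenotypic space.
* **Metadata grouping**: per-group centroids and dispersions in PC space
  with a seeded PERMANOVA (999 permutations) for separation; refused, with
  a reason, for single groups or one-observation groups.
* **Error robustness**: every measurement in the supplied table is
  multiplied by `1 + Normal(0, pct/100)` and the species-mean PIC
  correlation recomputed; reported is the count of replicates whose
  significance verdict flips. The table should be the most granular one
  available (per-embryo in this pipeline): contrasts divide by square
  roots of branch lengths, so unstructured noise injected *after*
  aggregation is amplified through short terminal branches far more than
  per-measurement error that averaging attenuates. The multiplicative
  Gaussian form matches the original simulation's framing of a 10% error
  as tens of pixels on a 50 um embryo.

# Numerical choices and degenerate inputs

Polytomies are resolved with zero-length branches before pruning (the
correlation through the origin is invariant to the resolution order);
zero-length cherries are an error rather than an infinite-weight average.
Constant traits yield a flagged `sigma2 = 0` boundary fit with the
likelihood reported as its limit, all-equal groups give H = 0, p = 1, and
zero-variance columns are dropped from PCA with a warning. Missing species
are pruned per trait before fitting. Every stochastic routine takes an
explicit seed, and cohort generation derives per-embryo noise streams from
the master seed by embryo counter, so results are bit-reproducible
regardless of iteration order.

# Problem sizes used by the checks

The acceptance suite and script run the generator at the full study scale
(42 species x 3 strains x 10 embryos), 50-tree oracle-equivalence sweeps,
100-replicate rate-recovery and null-correlation studies, 200-replicate
LRT calibration at 50 tips, and 1,000-replicate robustness runs — sizes
chosen so each study gives stable estimates while the whole suite stays
interactive on a single core.

# Known limitations

* The elongation-duration rule biases shallow slow ramps short; durations
  from embryos with small rises should be treated cautiously.
* Extracted oscillation durations carry O(quarter-period) edge noise from
  discrete extrema under a smooth envelope.
* The OU-vs-BM LRT is anticonservative at this study's tree size (above).
* The Gibbs species-mean model assumes a single within-species variance
  shared across species and strains.
* The generator's measurement-noise model is a stand-in (i.i.d. Gaussian,
  0.1 um); real tracking error is temporally correlated and
  contrast-dependent, and no quantitative noise model is published for
  these recordings.
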