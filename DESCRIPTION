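Package: nemaspindle
Title: Evolution of Mitotic Spindle Mechanics Across Nematode Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mitotic spindle behaviour during the first asymmetric
    embryonic division of nematodes and analyses how those traits evolve across
    a species phylogeny. Extracts 22 quantitative traits (cell geometry, spindle
    displacement, elongation, and transverse pole oscillations) from centrosome
    trajectory tables, fits Brownian-motion and Ornstein-Uhlenbeck models of
    continuous-trait evolution with likelihood-ratio model comparison,
    reconstructs ancestral states, estimates species means from strain-level
    data with a hierarchical Gibbs sampler, and runs the comparative battery:
    phylogenetically independent contrast correlations with one-strain-per-
    species resampling, Kruskal-Wallis species-difference tests with FDR
    control, selfer/outbreeder variance comparisons, principal component
    analysis of the phenotypic space, and a measurement-error robustness
    simulation. A seeded synthetic-cohort generator renders centrosome
    trajectories from known trait values so that every stage of the pipeline is
    testable end to end without video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    phytools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
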