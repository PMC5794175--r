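#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Builds the synthetic analogue of the study design: 42 species on an
# ultrametric phylogeny, ~3 strains per species, 10 embryos per strain,
# species trait means evolving by Brownian motion, transverse oscillations
# confined to one clade, and per-embryo centrosome trajectories at 0.5 s
# resolution. Writes the configuration, the tree, the ground-truth trait
# tables, and a handful of example trajectory CSVs under results/.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressPackageStartupMessages(library(nemaspindle))

cli <- commandArgs(trailingOnly = TRUE)
seed <- if (length(cli) >= 1L) as.integer(cli[1]) else 2026L
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
coh <- generate_cohort(cfg)

write_run_config(cfg, "results/cohort/generator_config.yml")
writeLines(write_newick(coh$tree), "results/cohort/species_tree.nwk")
writeLines(coh$oscillating_species, "results/cohort/oscillating_species.txt")
write_trait_table(coh$ground_truth$species, "results/cohort/truth_species.csv")
write_trait_table(coh$ground_truth$strain, "results/cohort/truth_strain.csv")
write_trait_table(coh$ground_truth$embryo, "results/cohort/truth_embryo.csv")
for (i in seq_len(3)) {
  write_trajectory_csv(coh$recordings[[i]],
                       sprintf("results/cohort/example_trajectory_%d.csv", i))
}

cat(sprintf("cohort: %d species (%d oscillating), %d strains, %d embryos\n",
            ape::Ntip(coh$tree), length(coh$oscillating_species),
            nrow(coh$ground_truth$strain), length(coh$recordings)))
cat("ground truth and configuration written to results/cohort/\n")
cat("recordings are regenerated deterministically by later stages from the config\n")
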