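#!/usr/bin/env Rscript

# Stage 4 — phylogeny-corrected trait correlations.
#
# Runs the resampled correlation battery (1,000 draws of one strain per
# species, PIC correlation through the origin per trait pair, BH adjustment
# within each draw) and the single species-mean correlation matrix.
# Oscillation-trait pairs are restricted to the oscillating clade.
#
# Usage: Rscript analysis/04_correlations.R

suppressPackageStartupMessages(library(nemaspindle))

tree <- read_newick("results/cohort/species_tree.nwk")
osc_sp <- readLines("results/cohort/oscillating_species.txt")
strain_tab <- read_trait_table("results/traits_strain.csv")

res <- resampled_pic_correlation(tree, strain_tab, n_rep = 1000L, seed = 81L,
                                 oscillating_species = osc_sp)
write_trait_table(res, "results/correlations_resampled.csv")

smc <- species_mean_correlation(tree, species_mean_table(strain_tab, tree),
                                oscillating_species = osc_sp)
utils::write.csv(round(smc$r, 4), "results/correlations_species_mean_r.csv")
utils::write.csv(round(smc$p_adjusted, 6),
                 "results/correlations_species_mean_padj.csv")

sig <- res[res$significant, c("trait1", "trait2", "median_r")]
cat(sprintf("resampled correlations: %d of %d pairs significant (>=95%% of 1,000 draws at BH p < 0.05)\n",
            nrow(sig), nrow(res)))
top <- sig[order(-abs(sig$median_r)), ][seq_len(min(5, nrow(sig))), ]
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %s ~ %s: median R = %.2f\n",
              top$trait1[i], top$trait2[i], top$median_r[i]))
}
cat("full matrices in results/correlations_*.csv\n")
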