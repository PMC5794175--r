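#!/usr/bin/env Rscript

# Stage 5 — phenotypic space, species differences, and variance structure.
#
# PCA of the strain-by-trait matrix (with and without oscillation traits),
# Kruskal-Wallis species-difference tests at FDR 0.001, a selfer/outbreeder-
# style variance comparison between two species groups, and a permutation
# test of climate-like metadata groupings in PC space (labels are assigned
# at random here, so no separation is expected — the null finding).
#
# Usage: Rscript analysis/05_phenotypic_space.R

suppressPackageStartupMessages(library(nemaspindle))

strain_tab <- read_trait_table("results/traits_strain.csv")
osc_sp <- readLines("results/cohort/oscillating_species.txt")

# PCA over all strains: asymmetry ratios are undefined without oscillations
pc_all <- pca_traits(strain_tab, exclude = c("osc_asymmetry_max",
                                             "osc_asymmetry_mean"))
pc_noosc <- pca_traits(strain_tab, exclude = oscillation_trait_names())
utils::write.csv(round(pc_all$loadings, 4), "results/pca_loadings.csv")
utils::write.csv(round(pc_all$scores, 4), "results/pca_scores.csv")
write_trait_table(data.frame(component = seq_along(pc_all$percent_variance),
                             pct_all_traits = round(pc_all$percent_variance, 2),
                             pct_without_osc = round(c(pc_noosc$percent_variance,
                                                       rep(NA, length(pc_all$percent_variance) -
                                                             length(pc_noosc$percent_variance))), 2)),
                  "results/pca_variance.csv")

# does PC1 separate oscillating from non-oscillating strains?
is_osc <- strain_tab$species %in% osc_sp
sep <- metadata_grouping(pc_all$scores[, 1:2],
                         ifelse(is_osc, "oscillating", "non_oscillating"),
                         n_perm = 999L, seed = 91L)

# Kruskal-Wallis species differences per trait, FDR 0.001
kw <- do.call(rbind, lapply(trait_names(), function(tr) {
  ok <- is.finite(strain_tab[[tr]])
  if (length(unique(strain_tab$species[ok])) < 2L) {
    return(data.frame(trait = tr, H = NA, p = NA))
  }
  k <- kruskal_wallis(strain_tab[[tr]][ok], strain_tab$species[ok])
  data.frame(trait = tr, H = k$H, p = k$p)
}))
kw$p_adjusted <- stats::p.adjust(kw$p, method = "BH")
kw$significant_fdr_0.001 <- !is.na(kw$p_adjusted) & kw$p_adjusted < 0.001
write_trait_table(kw, "results/kruskal_wallis.csv")

# variance comparison between two species groups with several strains each
counts <- table(strain_tab$species)
multi <- names(counts)[counts >= 2]
set.seed(92)
half <- sample(length(multi)) <= length(multi) / 2
ft <- variance_f_test(strain_tab, group_a = multi[half],
                      group_b = multi[!half],
                      traits = setdiff(trait_names(),
                                       c("osc_asymmetry_max", "osc_asymmetry_mean")))
write_trait_table(ft, "results/variance_f_test.csv")

# climate-like metadata assigned at random: the expected null
set.seed(93)
climate <- sample(c("temperate", "tropical", "monsoon", "oceanic"),
                  nrow(strain_tab), replace = TRUE)
clim <- metadata_grouping(pc_all$scores[, 1:2], climate, n_perm = 999L,
                          seed = 94L)

cat(sprintf("PC1 explains %.2f%% of variance (%.2f%% without oscillation traits)\n",
            pc_all$percent_variance[1], pc_noosc$percent_variance[1]))
cat(sprintf("oscillating vs non-oscillating separation in PC space: p = %.3g\n",
            sep$p_value))
cat(sprintf("Kruskal-Wallis: %d of %d traits differ between species at FDR 0.001\n",
            sum(kw$significant_fdr_0.001), nrow(kw)))
cat(sprintf("variance F tests: %d of %d traits show no group difference at BH 0.05\n",
            attr(ft, "n_not_different"), sum(!ft$skipped)))
cat(sprintf("random climate labels: separation p = %.3g (no structure, as expected)\n",
            clim$p_value))
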