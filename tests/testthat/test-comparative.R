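# small strain table on a fixed tree, two traits evolving independently
make_strain_table <- function(tree, n_strains = 3, seed = 1, sd_strain = 0.5) {
  set.seed(seed)
  xa <- simulate_trait_evolution(tree, list(type = "BM", sigma2 = 2, root = 0),
                                 seed = seed + 1)
  xb <- simulate_trait_evolution(tree, list(type = "BM", sigma2 = 2, root = 0),
                                 seed = seed + 2)
  do.call(rbind, lapply(tree$tip.label, function(sp) {
    data.frame(species = sp,
               strain = sprintf("%s_st%d", sp, seq_len(n_strains)),
               cell_length_um = xa[sp] + rnorm(n_strains, 0, sd_strain),
               cell_width_um = xb[sp] + rnorm(n_strains, 0, sd_strain))
  }))
}

test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(vals, grp)
  expect_equal(kw$H, 7.2, tolerance = 1e-9)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(round(kw$p, 4), 0.0273)
  flat <- kruskal_wallis(rep(5, 9), grp)
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
})

test_that("BH step-up rejects the documented set", {
  out <- bh_fdr(c(0.001, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(bh_fdr(rep(0, 5), 0.05)$reject))
  single <- bh_fdr(0.031, 0.05)
  expect_equal(single$adjusted, 0.031)
  # adjusted p are monotone in the raw ranks
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)$adjusted[order(p)]) >= 0))
})

test_that("resampling is degenerate with one strain per species", {
  tr <- random_ultrametric_tree(12, seed = 81)
  tab <- make_strain_table(tr, n_strains = 1, seed = 81)
  res <- resampled_pic_correlation(tr, tab, n_rep = 25L, seed = 82)
  r_mat <- attr(res, "r_replicates")
  expect_true(all(apply(r_mat, 2L, function(col) length(unique(col)) == 1L)))
  # and equals the species-mean correlation
  smc <- species_mean_correlation(tr, tab)
  expect_equal(res$median_r, smc$pairs$r, tolerance = 1e-12)
})

test_that("an exact linear relation gives R = 1 in every replicate", {
  tr <- random_ultrametric_tree(10, seed = 83)
  tab <- make_strain_table(tr, n_strains = 3, seed = 83)
  tab$cell_width_um <- 2 * tab$cell_length_um
  res <- resampled_pic_correlation(tr, tab, n_rep = 50L, seed = 84)
  expect_equal(unname(attr(res, "r_replicates")[, 1]), rep(1, 50),
               tolerance = 1e-9)
  expect_true(res$significant[1])
})

test_that("oscillation-trait pairs are restricted to the oscillating clade", {
  tr <- random_ultrametric_tree(14, seed = 85)
  osc_sp <- oscillating_clade(tr, 0.6)
  tab <- make_strain_table(tr, n_strains = 2, seed = 85)
  set.seed(86)
  tab$osc_duration_s <- ifelse(tab$species %in% osc_sp, rnorm(nrow(tab), 200, 30), NA)
  res <- resampled_pic_correlation(tr, tab, n_rep = 10L, seed = 87,
                                   oscillating_species = osc_sp)
  osc_rows <- res$trait1 == "osc_duration_s" | res$trait2 == "osc_duration_s"
  expect_true(all(res$scope[osc_rows] == "oscillating"))
  expect_true(all(res$n_species[osc_rows] == length(osc_sp)))
  expect_true(all(res$scope[!osc_rows] == "all"))
})

test_that("species-mean correlation matrix is symmetric with unit diagonal", {
  tr <- random_ultrametric_tree(10, seed = 88)
  tab <- make_strain_table(tr, n_strains = 1, seed = 88)
  smc <- species_mean_correlation(tr, tab)
  expect_equal(smc$r, t(smc$r))
  expect_equal(unname(diag(smc$r)), rep(1, ncol(smc$r)))
  # the single pair matches an independent contrasts implementation
  x <- tapply(tab$cell_length_um, tab$species, mean)[tr$tip.label]
  y <- tapply(tab$cell_width_um, tab$species, mean)[tr$tip.label]
  cx <- ape::pic(x, tr); cy <- ape::pic(y, tr)
  r_ape <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(smc$r["cell_length_um", "cell_width_um"], r_ape,
               tolerance = 1e-8)
})

test_that("zero measurement error reproduces the baseline exactly", {
  tr <- random_ultrametric_tree(12, seed = 89)
  tab <- make_strain_table(tr, n_strains = 3, seed = 89)
  rob <- error_robustness(tr, tab, c("cell_length_um", "cell_width_um"),
                          error_pct = 0, n_rep = 20L, seed = 90)
  expect_equal(rob$n_flips, 0L)
  expect_equal(unname(rob$r_values), rep(rob$baseline$r, 20), tolerance = 1e-12)
})

test_that("PCA of two perfectly correlated traits loads 100% on PC1", {
  set.seed(91)
  tab <- data.frame(cell_length_um = rnorm(30, 50, 5))
  tab$cell_width_um <- 0.6 * tab$cell_length_um
  pc <- pca_traits(tab)
  expect_equal(pc$percent_variance[1], 100, tolerance = 1e-9)
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-9)
})

test_that("PCA matches an independent eigen-decomposition", {
  set.seed(92)
  M <- matrix(rnorm(40 * 5), 40, 5)
  colnames(M) <- trait_names()[1:5]
  pc <- pca_traits(as.data.frame(M))
  ev <- eigen(stats::cor(M), symmetric = TRUE)
  expect_equal(pc$percent_variance, 100 * ev$values / sum(ev$values),
               tolerance = 1e-9)
  for (k in 1:5) {
    expect_equal(abs(pc$loadings[, k]), abs(ev$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: dominant loading is positive
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  }
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-9)
})

test_that("PCA drops incomplete rows and zero-variance columns with notice", {
  set.seed(93)
  tab <- data.frame(cell_length_um = rnorm(20, 50),
                    cell_width_um = rnorm(20, 30),
                    aspect_ratio = rep(1.6, 20))
  tab$cell_length_um[3] <- NA
  expect_warning(pc <- pca_traits(tab), "zero-variance")
  expect_equal(pc$dropped_rows, 3L)
  expect_equal(pc$dropped_columns, "aspect_ratio")
})

test_that("variance F test is exact for equal variances and detects 4x", {
  tr_labels <- c("A", "B", "C", "D")
  tab <- data.frame(
    species = rep(tr_labels, each = 4),
    cell_length_um = rep(c(1, 2, 3, 4), times = 4) + rep(c(0, 10, 20, 30), each = 4))
  out <- variance_f_test(tab, group_a = c("A", "B"), group_b = c("C", "D"))
  expect_equal(out$F, 1)
  expect_equal(out$p, 1)
  expect_false(out$different)
  # power against a 4x variance ratio, 15 strains per group: the simulated
  # rejection rate must match the closed-form F-distribution power
  rej <- vapply(1:200, function(i) {
    set.seed(9400 + i)
    tb <- data.frame(species = rep(c("A", "B"), each = 15),
                     cell_length_um = c(rnorm(15, 0, 1), rnorm(15, 0, 2)))
    variance_f_test(tb, "A", "B")$different
  }, logical(1))
  power_exact <- stats::pf(stats::qf(0.025, 14, 14) * 4, 14, 14) +
    stats::pf(stats::qf(0.975, 14, 14) * 4, 14, 14, lower.tail = FALSE)
  se <- sqrt(power_exact * (1 - power_exact) / 200)
  expect_lt(abs(mean(rej) - power_exact), 3 * se)
  # size under the null stays near the nominal level
  rej0 <- vapply(1:200, function(i) {
    set.seed(9600 + i)
    tb <- data.frame(species = rep(c("A", "B"), each = 15),
                     cell_length_um = rnorm(30))
    variance_f_test(tb, "A", "B")$different
  }, logical(1))
  expect_lt(mean(rej0), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("metadata grouping separates split groups and refuses degenerate ones", {
  set.seed(95)
  scores <- rbind(matrix(rnorm(20 * 2, 0), ncol = 2),
                  matrix(rnorm(20 * 2, 10), ncol = 2))
  g <- rep(c("temperate", "tropical"), each = 20)
  mg <- metadata_grouping(scores, g, n_perm = 999, seed = 96)
  expect_lte(mg$p_value, 0.001)
  expect_equal(mg$summary$n, c(20L, 20L))
  one <- metadata_grouping(scores, rep("x", 40), seed = 97)
  expect_true(is.na(one$p_value))
  singl <- metadata_grouping(scores[1:3, ], c("a", "b", "c"), seed = 98)
  expect_true(is.na(singl$p_value))
  expect_match(singl$reason, "refused")
  # shuffled labels are not declared separated
  ps <- vapply(1:10, function(i) {
    set.seed(9900 + i)
    metadata_grouping(scores, sample(g), n_perm = 199, seed = 9900 + i)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.3)
})
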