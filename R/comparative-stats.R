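# The statistical battery: species-difference tests, FDR control, resampled
# phylogenetic correlations, measurement-error robustness, PCA of the
# phenotypic space, and selfer/outbreeder variance comparison.

#' Kruskal-Wallis comparison of a trait between species
#'
#' Rank-based test (with tie correction) of whether the trait distribution
#' differs between groups; wraps [stats::kruskal.test()]. Identical values in
#' every group give `H = 0`, `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Grouping labels (species), same length.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- is.finite(values)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure via [stats::p.adjust()]; the rejection set consists of
#' the hypotheses whose adjusted p-value is at most `q`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param q Target FDR level.
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Trait names associated with spindle oscillations
#' @return Character vector (subset of [trait_names()]).
#' @export
oscillation_trait_names <- function() {
  grep("^osc_", trait_names(), value = TRUE)
}

# internal: (n-1) x n matrix mapping tip values to standardized contrasts for
# a fixed tree (contrasts are linear in the tip values).
contrast_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  basis <- diag(n)
  rownames(basis) <- tree$tip.label
  cols <- lapply(seq_len(n), function(j) {
    pic_contrasts(tree, stats::setNames(basis[, j], tree$tip.label))$contrast
  })
  C <- do.call(cbind, cols)
  colnames(C) <- tree$tip.label
  C
}

# internal: correlations through the origin between all columns of a
# contrast matrix U ((n-1) x traits), with t-based p on df = nrow(U) - 1.
origin_correlations <- function(U) {
  ss <- colSums(U^2)
  G <- crossprod(U)
  denom <- sqrt(outer(ss, ss))
  R <- ifelse(denom > 0, G / denom, NA_real_)
  df <- nrow(U) - 1L
  r2 <- pmin(R^2, 1)
  tstat <- ifelse(r2 >= 1, Inf, abs(R) * sqrt(df / (1 - r2)))
  P <- pmin(2 * stats::pt(tstat, df, lower.tail = FALSE), 1)
  list(r = R, p = P, df = df)
}

#' Phylogeny-corrected trait correlations with one-strain-per-species resampling
#'
#' Intraspecific variation is high, so instead of a single species-mean
#' correlation the analysis draws, in each of `n_rep` replicates, one strain
#' per species uniformly at random, computes the correlation of
#' phylogenetically independent contrasts (through the origin) for every
#' trait pair, and BH-adjusts the p-values across pairs within the
#' replicate. Pairs where either trait is oscillation-associated are
#' restricted to the oscillating species; all other pairs use every species.
#' A pair is called significant when at least `verdict_frac` of replicates
#' have adjusted p below `q`; the similarity score is the median R.
#'
#' @param tree A `"phylo"` object.
#' @param strain_table Data frame: `species`, `strain`, trait columns.
#' @param traits Trait columns to analyse (default: intersection of
#'   [trait_names()] with the table).
#' @param n_rep Number of resampling replicates.
#' @param q FDR level within each replicate.
#' @param seed Integer seed (mandatory).
#' @param oscillating_species Character vector; `NULL` disables the
#'   oscillation-pair restriction.
#' @param verdict_frac Fraction of significant replicates required for a
#'   significant verdict.
#' @return Data frame with one row per trait pair: `trait1`, `trait2`,
#'   `median_r`, `frac_significant`, `significant`, `scope`, `n_species`;
#'   the per-replicate R matrix is attached as attribute `r_replicates`.
#' @export
resampled_pic_correlation <- function(tree, strain_table, traits = NULL,
                                      n_rep = 1000L, q = 0.05, seed,
                                      oscillating_species = NULL,
                                      verdict_frac = 0.95) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(traits)) {
    traits <- intersect(trait_names(), names(strain_table))
  }
  species_all <- intersect(tree$tip.label, unique(strain_table$species))
  scopes <- build_scopes(tree, strain_table, traits, species_all,
                         oscillating_species)
  pairs <- scopes$pairs
  n_pairs <- nrow(pairs)
  r_mat <- matrix(NA_real_, n_rep, n_pairs)
  sig_mat <- matrix(FALSE, n_rep, n_pairs)
  by_species <- split(seq_len(nrow(strain_table)), strain_table$species)
  set.seed(seed)
  for (rep in seq_len(n_rep)) {
    pick <- vapply(species_all, function(sp) {
      idx <- by_species[[sp]]
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
    X <- as.matrix(strain_table[pick, traits, drop = FALSE])
    rownames(X) <- species_all
    res <- pair_correlations(X, scopes)
    r_mat[rep, ] <- res$r
    adj <- stats::p.adjust(res$p, method = "BH")
    sig_mat[rep, ] <- !is.na(adj) & adj < q
  }
  out <- data.frame(trait1 = pairs$trait1, trait2 = pairs$trait2,
                    median_r = apply(r_mat, 2L, stats::median, na.rm = TRUE),
                    frac_significant = colMeans(sig_mat),
                    scope = pairs$scope,
                    n_species = pairs$n_species)
  out$significant <- out$frac_significant >= verdict_frac
  attr(out, "r_replicates") <- r_mat
  attr(out, "settings") <- list(n_rep = n_rep, q = q, seed = seed,
                                verdict_frac = verdict_frac)
  out
}

# internal: precompute contrast matrices and the pair/scope layout.
build_scopes <- function(tree, strain_table, traits, species_all,
                         oscillating_species) {
  full_tree <- ape::keep.tip(tree, species_all)
  C_full <- contrast_matrix(full_tree)
  osc_traits <- intersect(traits, oscillation_trait_names())
  has_osc <- length(osc_traits) > 0L && !is.null(oscillating_species)
  if (has_osc) {
    osc_sp <- intersect(species_all, oscillating_species)
    if (length(osc_sp) < 3L) stop("fewer than 3 oscillating species", call. = FALSE)
    osc_tree <- ape::keep.tip(tree, osc_sp)
    C_osc <- contrast_matrix(osc_tree)
  } else {
    osc_sp <- character(0); C_osc <- NULL
  }
  cmb <- utils::combn(traits, 2L)
  scope <- vapply(seq_len(ncol(cmb)), function(k) {
    if (has_osc && (cmb[1L, k] %in% osc_traits || cmb[2L, k] %in% osc_traits))
      "oscillating" else "all"
  }, character(1))
  pairs <- data.frame(trait1 = cmb[1L, ], trait2 = cmb[2L, ], scope = scope,
                      n_species = ifelse(scope == "all",
                                         length(species_all), length(osc_sp)))
  list(pairs = pairs, traits = traits,
       C_full = C_full, full_species = colnames(C_full),
       C_osc = C_osc, osc_species = osc_sp)
}

# internal: per-pair correlations for one species-by-trait value matrix.
pair_correlations <- function(X, scopes) {
  traits <- scopes$traits
  U_full <- scopes$C_full %*% X[scopes$full_species, traits, drop = FALSE]
  oc_full <- origin_correlations(U_full)
  if (!is.null(scopes$C_osc)) {
    U_osc <- scopes$C_osc %*% X[scopes$osc_species, traits, drop = FALSE]
    oc_osc <- origin_correlations(U_osc)
  }
  pairs <- scopes$pairs
  r <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    oc <- if (pairs$scope[k] == "all") oc_full else oc_osc
    r[k] <- oc$r[pairs$trait1[k], pairs$trait2[k]]
    p[k] <- oc$p[pairs$trait1[k], pairs$trait2[k]]
  }
  list(r = r, p = p)
}

#' Phylogenetic correlation matrix from species means
#'
#' Single PIC correlation per trait pair on species-mean values, with the
#' same BH handling and oscillation-pair restriction as the resampled
#' version; equals the unique replicate of [resampled_pic_correlation()]
#' when every species has exactly one strain.
#'
#' @param tree A `"phylo"` object.
#' @param species_table Data frame: `species` + trait columns (species means).
#' @param traits Trait columns (default as in [resampled_pic_correlation()]).
#' @param q FDR level.
#' @param oscillating_species See [resampled_pic_correlation()].
#' @return List: `r` and `p_adjusted` (symmetric matrices, unit / zero
#'   diagonal), `pairs` (data frame with `r`, `p`, `p_adjusted`,
#'   `significant`, `scope`).
#' @export
species_mean_correlation <- function(tree, species_table, traits = NULL,
                                     q = 0.05, oscillating_species = NULL) {
  if (is.null(traits)) {
    traits <- intersect(trait_names(), names(species_table))
  }
  species_all <- intersect(tree$tip.label, unique(species_table$species))
  scopes <- build_scopes(tree, species_table, traits, species_all,
                         oscillating_species)
  X <- as.matrix(species_table[match(species_all, species_table$species),
                               traits, drop = FALSE])
  rownames(X) <- species_all
  res <- pair_correlations(X, scopes)
  adj <- stats::p.adjust(res$p, method = "BH")
  pairs <- cbind(scopes$pairs,
                 data.frame(r = res$r, p = res$p, p_adjusted = adj,
                            significant = !is.na(adj) & adj < q))
  R <- P <- matrix(NA_real_, length(traits), length(traits),
                   dimnames = list(traits, traits))
  diag(R) <- 1; diag(P) <- 0
  for (k in seq_len(nrow(pairs))) {
    R[pairs$trait1[k], pairs$trait2[k]] <- R[pairs$trait2[k], pairs$trait1[k]] <- pairs$r[k]
    P[pairs$trait1[k], pairs$trait2[k]] <- P[pairs$trait2[k], pairs$trait1[k]] <- pairs$p_adjusted[k]
  }
  list(r = R, p_adjusted = P, pairs = pairs)
}

#' Measurement-error robustness of a phylogenetic correlation
#'
#' Multiplies every strain-level measurement of the two traits by
#' `1 + Normal(0, error_pct / 100)` (multiplicative Gaussian error),
#' recomputes species means and the PIC correlation, and counts replicates
#' whose significance verdict flips relative to the error-free baseline.
#'
#' @param tree A `"phylo"` object.
#' @param strain_table Data frame: `species`, trait columns.
#' @param trait_pair Character vector of two trait names.
#' @param error_pct Error level in percent (0 reproduces the baseline
#'   exactly).
#' @param n_rep Number of perturbation replicates.
#' @param q Significance level on the (single-pair) p-value.
#' @param seed Integer seed.
#' @param species_subset Optional species restriction (e.g. the oscillating
#'   clade for oscillation traits).
#' @return List: `baseline` (`r`, `p`, `significant`), `n_flips`,
#'   `flip_fraction`, `retained_fraction`, `r_values` (per replicate).
#' @export
error_robustness <- function(tree, strain_table, trait_pair, error_pct,
                             n_rep = 1000L, q = 0.05, seed,
                             species_subset = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(length(trait_pair) == 2L)
  if (!is.null(species_subset)) {
    strain_table <- strain_table[strain_table$species %in% species_subset, ]
  }
  species_all <- intersect(tree$tip.label, unique(strain_table$species))
  tr <- ape::keep.tip(tree, species_all)
  sp_mean <- function(v) {
    vapply(split(v, strain_table$species)[species_all], mean, numeric(1))
  }
  x0 <- sp_mean(strain_table[[trait_pair[1L]]])
  y0 <- sp_mean(strain_table[[trait_pair[2L]]])
  base <- pic_correlation(tr, x0, y0)
  base_sig <- base$p < q
  set.seed(seed)
  nx <- length(strain_table[[trait_pair[1L]]])
  r_vals <- numeric(n_rep); sig <- logical(n_rep)
  sd_err <- error_pct / 100
  for (i in seq_len(n_rep)) {
    xe <- strain_table[[trait_pair[1L]]] * (1 + stats::rnorm(nx, 0, sd_err))
    ye <- strain_table[[trait_pair[2L]]] * (1 + stats::rnorm(nx, 0, sd_err))
    pc <- pic_correlation(tr, sp_mean(xe), sp_mean(ye))
    r_vals[i] <- pc$r
    sig[i] <- pc$p < q
  }
  flips <- sum(sig != base_sig)
  list(baseline = list(r = base$r, p = base$p, significant = base_sig),
       n_flips = flips, flip_fraction = flips / n_rep,
       retained_fraction = mean(sig == base_sig),
       r_values = r_vals)
}

#' Principal component analysis of the phenotypic space
#'
#' Column-standardized PCA (eigen-decomposition of the correlation matrix,
#' via [stats::prcomp()]) on complete-case rows; zero-variance columns are
#' dropped with a warning, rows with missing values are dropped and logged.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param trait_table Data frame with trait columns (plus any label columns,
#'   ignored).
#' @param exclude Trait columns to exclude (e.g. the oscillation traits).
#' @param scale. Standardize columns (default `TRUE`).
#' @return List: `loadings`, `scores`, `percent_variance` (sums to 100),
#'   `dropped_rows` (row indices removed as incomplete), `dropped_columns`.
#' @export
pca_traits <- function(trait_table, exclude = character(0), scale. = TRUE) {
  traits <- intersect(trait_names(), names(trait_table))
  traits <- setdiff(traits, exclude)
  M <- as.matrix(trait_table[, traits, drop = FALSE])
  complete <- stats::complete.cases(M)
  dropped_rows <- which(!complete)
  M <- M[complete, , drop = FALSE]
  vars <- apply(M, 2L, stats::var)
  dropped_cols <- colnames(M)[vars == 0]
  if (length(dropped_cols)) {
    warning("dropping zero-variance trait(s): ",
            paste(dropped_cols, collapse = ", "), call. = FALSE)
    M <- M[, vars > 0, drop = FALSE]
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = scale.)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, scores = pc$x, percent_variance = pv,
       dropped_rows = dropped_rows, dropped_columns = dropped_cols)
}

#' Per-trait variance comparison between two species groups
#'
#' Tests, trait by trait, whether among-strain variance differs between two
#' groups of species (e.g. selfing vs outcrossing). Strain values are
#' centered by their species mean within each group (removing species-mean
#' differences), the centered values pooled, and a two-sided F test performed
#' on the pooled variances with pooled degrees of freedom
#' (`n_strains - n_species` per group); BH correction across traits.
#'
#' @param strain_table Data frame: `species` + trait columns.
#' @param group_a,group_b Character vectors of species names.
#' @param traits Trait columns (default as usual).
#' @param q FDR level.
#' @return Data frame per trait: `var_a`, `var_b`, `df_a`, `df_b`, `F`, `p`,
#'   `p_adjusted`, `different`, `skipped`; attribute `n_not_different`.
#' @export
variance_f_test <- function(strain_table, group_a, group_b, traits = NULL,
                            q = 0.05) {
  if (is.null(traits)) {
    traits <- intersect(trait_names(), names(strain_table))
  }
  pooled <- function(group, tr) {
    tab <- strain_table[strain_table$species %in% group, ]
    v <- tab[[tr]]; sp <- tab$species
    keep <- is.finite(v)
    v <- v[keep]; sp <- sp[keep]
    ns <- table(sp)
    if (any(ns < 2L)) {
      stop("each group needs >= 2 strains per species (trait ", tr, ")",
           call. = FALSE)
    }
    centered <- v - stats::ave(v, sp)
    list(ss = sum(centered^2), df = length(v) - length(unique(sp)))
  }
  rows <- lapply(traits, function(tr) {
    a <- pooled(group_a, tr); b <- pooled(group_b, tr)
    var_a <- a$ss / a$df; var_b <- b$ss / b$df
    if (var_a == 0 || var_b == 0) {
      return(data.frame(trait = tr, var_a = var_a, var_b = var_b,
                        df_a = a$df, df_b = b$df, F = NA_real_, p = NA_real_,
                        skipped = TRUE))
    }
    Fs <- var_a / var_b
    p <- 2 * min(stats::pf(Fs, a$df, b$df),
                 stats::pf(Fs, a$df, b$df, lower.tail = FALSE))
    data.frame(trait = tr, var_a = var_a, var_b = var_b,
               df_a = a$df, df_b = b$df, F = Fs, p = min(p, 1),
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$different <- !is.na(out$p_adjusted) & out$p_adjusted < q
  attr(out, "n_not_different") <- sum(!out$different & !out$skipped)
  out
}

#' Metadata grouping of PCA scores
#'
#' Per-group centroids and dispersions in principal-component space plus a
#' seeded permutation test of between-group separation (PERMANOVA on
#' Euclidean distances via [vegan::adonis2()]).
#'
#' @param scores Numeric matrix of PC scores (rows: strains).
#' @param metadata Grouping vector (e.g. climate of origin), same length as
#'   `nrow(scores)`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List: `summary` (per-group n, centroid, mean distance to
#'   centroid), `p_value` (`NA` with a reason when the test is refused),
#'   `test` (the `adonis2` table or `NULL`).
#' @export
metadata_grouping <- function(scores, metadata, n_perm = 999L, seed = 1L) {
  scores <- as.matrix(scores)
  g <- factor(metadata)
  stopifnot(nrow(scores) == length(g))
  cent <- apply(scores, 2L, function(col) tapply(col, g, mean))
  cent <- matrix(cent, nrow = nlevels(g),
                 dimnames = list(levels(g), colnames(scores)))
  disp <- vapply(levels(g), function(lv) {
    rows <- which(g == lv)
    if (length(rows) == 1L) return(0)
    d <- sweep(scores[rows, , drop = FALSE], 2L, cent[lv, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  summary_df <- data.frame(group = levels(g),
                           n = as.integer(table(g)),
                           dispersion = disp)
  if (nlevels(g) < 2L) {
    return(list(summary = summary_df, p_value = NA_real_, test = NULL,
                reason = "single group: no test"))
  }
  if (all(table(g) == 1L)) {
    return(list(summary = summary_df, p_value = NA_real_, test = NULL,
                reason = "one observation per group: test refused"))
  }
  set.seed(seed)
  ad <- vegan::adonis2(stats::dist(scores) ~ g, permutations = n_perm)
  list(summary = summary_df, p_value = ad$`Pr(>F)`[1L], test = ad,
       centroids = cent)
}
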