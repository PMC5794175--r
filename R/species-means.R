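#' Estimate species trait means from strain-level values
#'
#' Strain-level measurements carry substantial intraspecific dispersion, so
#' species values feeding the comparative models can either be plain
#' arithmetic means or posterior means under a hierarchical model that
#' shares information across the phylogeny:
#'
#' \deqn{y_{js} \sim N(\mu_s, \sigma^2_w), \qquad
#'       \mu \sim N(z_0 \mathbf{1}, \sigma^2_B V),}
#'
#' with `V` the unit-rate Brownian-motion covariance of the tree, a flat prior
#' on the root state `z_0`, and conjugate inverse-gamma(0.001, 0.001) priors
#' on both variances. The posterior is explored by a Gibbs sampler (all full
#' conditionals are conjugate), reproducible under a mandatory seed.
#'
#' @param values Numeric vector of strain-level trait values.
#' @param species Character vector of species labels, same length as `values`;
#'   every label must be a tip of `tree`.
#' @param tree A `"phylo"` object; tips without any strain are pruned.
#' @param method `"arithmetic"` or `"hierarchical"`.
#' @param mcmc List of sampler settings: `n_iter` (default 2000), `burn_in`
#'   (default 500), `seed` (required for the hierarchical method).
#' @return Named numeric vector of species means (a species trait vector),
#'   with attributes `method` and, for the hierarchical method,
#'   `posterior` (posterior means of `sigma2_within`, `sigma2_bm`, `z0`).
#' @export
estimate_species_means <- function(values, species, tree,
                                   method = c("arithmetic", "hierarchical"),
                                   mcmc = list()) {
  method <- match.arg(method)
  stopifnot(length(values) == length(species))
  keep <- is.finite(values)
  values <- values[keep]; species <- as.character(species)[keep]
  bad <- setdiff(unique(species), tree$tip.label)
  if (length(bad)) {
    stop("species absent from tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sp <- intersect(tree$tip.label, unique(species))
  arith <- vapply(sp, function(s) mean(values[species == s]), numeric(1))
  if (method == "arithmetic") {
    return(structure(arith, method = "arithmetic"))
  }
  if (is.null(mcmc$seed)) {
    stop("hierarchical method requires mcmc$seed", call. = FALSE)
  }
  if (!any(table(species) >= 2L)) {
    stop("hierarchical method requires >= 2 strains for at least one species",
         call. = FALSE)
  }
  n_iter <- mcmc$n_iter %||% 2000L
  burn_in <- mcmc$burn_in %||% 500L
  drop_tips <- setdiff(tree$tip.label, sp)
  if (length(drop_tips)) tree <- ape::drop.tip(tree, drop_tips)
  sp <- tree$tip.label
  S <- length(sp)
  V <- ape::vcv(tree)[sp, sp]
  Vinv <- chol2inv(chol(V))
  one <- rep(1, S)
  Vinv1 <- Vinv %*% one
  sum_Vinv1 <- sum(Vinv1)
  idx <- match(species, sp)
  n_s <- tabulate(idx, nbins = S)
  ybar <- vapply(seq_len(S), function(s) mean(values[idx == s]), numeric(1))
  N <- length(values)
  a0 <- b0 <- 0.001
  set.seed(mcmc$seed)
  mu <- arith[sp]
  s2w <- max(stats::var(values - ybar[idx]) * N / max(N - S, 1), 1e-8)
  s2b <- max(stats::var(ybar), 1e-8)
  z0 <- mean(mu)
  keep_iter <- n_iter - burn_in
  mu_sum <- numeric(S)
  s2w_sum <- s2b_sum <- z0_sum <- 0
  for (it in seq_len(n_iter)) {
    # z0 | mu, s2b : GLS mean of mu on the tree
    m_z <- sum(Vinv1 * mu) / sum_Vinv1
    z0 <- stats::rnorm(1, m_z, sqrt(s2b / sum_Vinv1))
    # mu | y, z0, variances : multivariate normal
    P <- diag(n_s / s2w, S) + Vinv / s2b
    b <- n_s * ybar / s2w + as.numeric(Vinv1) * z0 / s2b
    R <- chol(P)
    mean_mu <- backsolve(R, forwardsolve(t(R), b))
    mu <- as.numeric(mean_mu + backsolve(R, stats::rnorm(S)))
    # sigma2_within | y, mu
    ss_w <- sum((values - mu[idx])^2)
    s2w <- 1 / stats::rgamma(1, a0 + N / 2, rate = b0 + ss_w / 2)
    # sigma2_bm | mu, z0
    d <- mu - z0
    ss_b <- sum(d * (Vinv %*% d))
    s2b <- 1 / stats::rgamma(1, a0 + S / 2, rate = b0 + ss_b / 2)
    if (it > burn_in) {
      mu_sum <- mu_sum + mu
      s2w_sum <- s2w_sum + s2w
      s2b_sum <- s2b_sum + s2b
      z0_sum <- z0_sum + z0
    }
  }
  out <- stats::setNames(mu_sum / keep_iter, sp)
  structure(out, method = "hierarchical",
            posterior = list(sigma2_within = s2w_sum / keep_iter,
                             sigma2_bm = s2b_sum / keep_iter,
                             z0 = z0_sum / keep_iter),
            mcmc = list(n_iter = n_iter, burn_in = burn_in, seed = mcmc$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Species-mean table across all traits
#'
#' Applies [estimate_species_means()] trait by trait to a strain-level trait
#' table.
#'
#' @param trait_table Data frame with a `species` column and numeric trait
#'   columns.
#' @param tree A `"phylo"` object.
#' @param traits Trait column names (default: all numeric columns).
#' @param method,mcmc Passed to [estimate_species_means()].
#' @return Data frame of species by traits, with a `species` column.
#' @export
species_mean_table <- function(trait_table, tree, traits = NULL,
                               method = "arithmetic", mcmc = list()) {
  if (is.null(traits)) {
    traits <- names(trait_table)[vapply(trait_table, is.numeric, logical(1))]
  }
  sp_all <- intersect(tree$tip.label, unique(trait_table$species))
  out <- data.frame(species = sp_all)
  for (tr in traits) {
    est <- estimate_species_means(trait_table[[tr]], trait_table$species,
                                  tree, method = method, mcmc = mcmc)
    out[[tr]] <- as.numeric(est[sp_all])
  }
  out
}
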