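# Continuous-trait evolutionary statistics on a phylogeny.
#
# The pruning recursion below is the workhorse shared by the independent
# contrasts and the Brownian-motion likelihood: traversing the tree tip-to-root
# it peels off, at every internal node, one Gaussian increment (the contrast)
# whose variance is the sum of the (recursively inflated) child branch
# lengths, replaces the pair by their variance-weighted average, and lengthens
# the parent branch by t1*t2/(t1+t2).

# internal: postorder pruning pass over a (possibly multifurcating) tree.
# Polytomies are resolved with zero-length branches first; the likelihood and
# correlation-through-origin quantities are invariant to the resolution order.
prune_pass <- function(tree, x) {
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips", call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  value <- numeric(nn)
  extra <- numeric(nn)          # accumulated branch-length inflation
  value[seq_len(n)] <- x[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  child_of <- split(seq_len(nrow(edge)), edge[, 1L])
  # parents listed in order of postorder completion: children always first
  parents <- unique(edge[, 1L])
  node_out <- contrast_raw <- contrast_var <- numeric(tree$Nnode)
  k <- 0L
  for (nd in parents) {
    ce <- child_of[[as.character(nd)]]
    stopifnot(length(ce) == 2L)            # binary after multi2di
    c1 <- edge[ce[1L], 2L]; c2 <- edge[ce[2L], 2L]
    t1 <- elen[ce[1L]] + extra[c1]
    t2 <- elen[ce[2L]] + extra[c2]
    tv <- t1 + t2
    if (tv <= 0) {
      stop("zero-length cherry at node ", nd,
           ": contrast variance would be 0", call. = FALSE)
    }
    k <- k + 1L
    node_out[k] <- nd
    contrast_raw[k] <- value[c1] - value[c2]
    contrast_var[k] <- tv
    value[nd] <- (t2 * value[c1] + t1 * value[c2]) / tv
    extra[nd] <- t1 * t2 / tv
  }
  root <- edge[nrow(edge), 1L]
  list(node = node_out, contrast_raw = contrast_raw,
       contrast_var = contrast_var,
       root_value = value[root], root_extra = extra[root], n_tips = n)
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts by the pruning recursion: at each internal node the
#' difference of the two daughter values divided by the square root of the
#' summed (inflated) branch lengths. Under Brownian motion the contrasts are
#' i.i.d. Normal(0, sigma^2), which is what makes them the currency of
#' phylogeny-corrected correlation.
#'
#' @param tree A `"phylo"` object; polytomies are resolved with zero-length
#'   branches.
#' @param x Named numeric vector of tip values covering every tip.
#' @return A data frame with columns `node`, `contrast` (standardized),
#'   `variance` (expected contrast variance in unit-rate branch-length units).
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 1, B = 3, C = 2))
pic_contrasts <- function(tree, x) {
  al <- align_trait(tree, x)
  pr <- prune_pass(al$tree, al$x)
  data.frame(node = pr$node,
             contrast = pr$contrast_raw / sqrt(pr$contrast_var),
             variance = pr$contrast_var)
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Correlation through the origin of the standardized contrasts of `x` and
#' `y`, with a t-test on `n_contrasts - 1` degrees of freedom.
#'
#' @param tree A `"phylo"` object.
#' @param x,y Named numeric tip vectors.
#' @return List with `r`, `p`, `df`, `n_contrasts`.
#' @export
pic_correlation <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)$contrast
  cy <- pic_contrasts(tree, y)$contrast
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) {
    return(list(r = NA_real_, p = NA_real_, df = length(cx) - 1L,
                n_contrasts = length(cx)))
  }
  r <- sum(cx * cy) / sqrt(sxx * syy)
  df <- length(cx) - 1L
  r2 <- min(r^2, 1)
  tstat <- if (r2 >= 1) Inf else abs(r) * sqrt(df / (1 - r2))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  list(r = r, p = min(p, 1), df = df, n_contrasts = length(cx))
}

#' Brownian-motion log-likelihood by pruning
#'
#' Log density of the tip values under Brownian motion with rate `sigma2`
#' and fixed root state: a multivariate normal with covariance
#' `sigma2 * V`, `V[i,j]` the shared root-to-tip path length, evaluated in
#' O(n) by the pruning recursion.
#'
#' @param tree A `"phylo"` object.
#' @param x Named numeric tip vector.
#' @param sigma2 Rate (trait units squared per unit branch length), > 0.
#' @param root_state State at the root (trait units).
#' @return Scalar log-likelihood.
#' @export
bm_loglik <- function(tree, x, sigma2, root_state) {
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be > 0", call. = FALSE)
  }
  al <- align_trait(tree, x)
  pr <- prune_pass(al$tree, al$x)
  ll <- sum(stats::dnorm(pr$contrast_raw, 0,
                         sqrt(sigma2 * pr$contrast_var), log = TRUE))
  if (pr$root_extra > 0) {
    ll <- ll + stats::dnorm(pr$root_value, root_state,
                            sqrt(sigma2 * pr$root_extra), log = TRUE)
  } else if (pr$root_value != root_state) {
    ll <- -Inf
  }
  ll
}

new_evol_fit <- function(model, sigma2, alpha, root_state, loglik, n_params,
                         n_tips, fingerprint, method = "ML",
                         boundary = FALSE, convergence_note = NA_character_) {
  structure(list(model = model, sigma2 = sigma2, alpha = alpha,
                 root_state = root_state, loglik = loglik,
                 n_params = n_params, n_tips = n_tips,
                 fingerprint = fingerprint, method = method,
                 boundary = boundary, convergence_note = convergence_note),
            class = "evol_model_fit")
}

#' @export
print.evol_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): sigma2 = %.6g", x$model, x$method, x$sigma2))
  if (x$model == "OU") cat(sprintf(", alpha = %.6g", x$alpha))
  cat(sprintf(", root/optimum = %.6g, logLik = %.6g, n = %d tips\n",
              x$root_state, x$loglik, x$n_tips))
  if (x$boundary) cat("  [boundary fit]\n")
  if (!is.na(x$convergence_note)) cat("  note:", x$convergence_note, "\n")
  invisible(x)
}

data_fingerprint <- function(tree, x) {
  paste(ape::write.tree(tree),
        paste(tree$tip.label, signif(x[tree$tip.label], 12), collapse = ";"),
        sep = "|")
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Closed-form ML estimates: the root state is the GLS mean (the pruned root
#' value) and `sigma2_hat` is the mean squared standardized contrast,
#' including the root term (which vanishes at the GLS mean), i.e. the ML (not
#' REML) estimator dividing by n.
#'
#' @param tree A `"phylo"` object with >= 3 tips (2 allowed for closed-form
#'   checks).
#' @param x Named numeric tip vector.
#' @return An `"evol_model_fit"` with `model = "BM"`. A constant trait gives a
#'   `sigma2 = 0` boundary fit with the log-likelihood reported as its
#'   (infinite) limit.
#' @export
fit_bm <- function(tree, x) {
  al <- align_trait(tree, x)
  pr <- prune_pass(al$tree, al$x)
  n <- pr$n_tips
  z0 <- pr$root_value
  s2 <- sum(pr$contrast_raw^2 / pr$contrast_var) / n
  if (s2 <= 0) {
    return(new_evol_fit("BM", 0, 0, z0, Inf, 2L, n,
                        data_fingerprint(al$tree, al$x),
                        boundary = TRUE,
                        convergence_note = "constant trait: sigma2 at 0 boundary, loglik is the limiting value"))
  }
  ll <- bm_loglik(al$tree, al$x, s2, z0)
  new_evol_fit("BM", s2, 0, z0, ll, 2L, n, data_fingerprint(al$tree, al$x))
}

# internal: OU unit-rate covariance with the root clamped at the optimum.
# V1[i,j] = exp(-alpha d_ij) (1 - exp(-2 alpha s_ij)) / (2 alpha) with d the
# patristic distance and s the shared root-to-node path length; alpha -> 0
# recovers the BM covariance s_ij.
ou_unit_vcv <- function(S, D, alpha) {
  if (alpha < 1e-12) return(S)
  exp(-alpha * D) * (1 - exp(-2 * alpha * S)) / (2 * alpha)
}

# internal: profile GLS estimates of root state and rate given a unit-rate
# covariance matrix.
gls_profile <- function(V1, x) {
  n <- length(x)
  R <- chol(V1)
  one <- rep(1, n)
  iR_one <- backsolve(R, forwardsolve(t(R), one))
  iR_x <- backsolve(R, forwardsolve(t(R), x))
  z0 <- sum(one * iR_x) / sum(one * iR_one)
  r <- x - z0
  iR_r <- backsolve(R, forwardsolve(t(R), r))
  s2 <- sum(r * iR_r) / n
  logdet <- 2 * sum(log(diag(R)))
  ll <- if (s2 <= 0) Inf else -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(root_state = z0, sigma2 = s2, loglik = ll)
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' Single-optimum OU with the root state clamped at the optimum. The
#' attraction strength `alpha` is profiled by a bounded one-dimensional search
#' on the log scale over `[1e-8, 50 / tree height]`; for each `alpha` the rate
#' and root state have closed-form GLS solutions. The `alpha -> 0` limit
#' reproduces the BM fit, so the OU log-likelihood can never fall below the BM
#' one.
#'
#' @param tree A `"phylo"` object (ultrametric preferred; a warning is issued
#'   otherwise).
#' @param x Named numeric tip vector.
#' @return An `"evol_model_fit"` with `model = "OU"`; a fit whose `alpha`
#'   lands near the upper search bound carries a convergence note.
#' @export
fit_ou <- function(tree, x) {
  al <- align_trait(tree, x)
  tree <- al$tree; x <- al$x
  if (ape::Ntip(tree) < 3L) stop("OU fit needs >= 3 tips", call. = FALSE)
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("tree is not ultrametric; OU shared-path parameterization assumes contemporaneous tips", call. = FALSE)
  }
  S <- ape::vcv(tree)
  S <- S[tree$tip.label, tree$tip.label]
  dep <- diag(S)
  D <- outer(dep, dep, "+") - 2 * S
  xv <- x[tree$tip.label]
  h <- max(dep)
  lo <- 1e-8
  hi <- 50 / h
  obj <- function(la) gls_profile(ou_unit_vcv(S, D, exp(la)), xv)$loglik
  opt <- stats::optimize(obj, interval = c(log(lo), log(hi)),
                         maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, log(lo), log(hi))
  lls <- c(opt$objective, obj(log(lo)), obj(log(hi)))
  best <- which.max(lls)
  alpha <- exp(cand[best])
  prof <- gls_profile(ou_unit_vcv(S, D, alpha), xv)
  bm <- fit_bm(tree, x)
  note <- NA_character_
  boundary <- FALSE
  if (is.finite(bm$loglik) && prof$loglik < bm$loglik) {
    # the nested alpha = 0 point dominates: report the BM limit
    alpha <- 0
    prof <- list(root_state = bm$root_state, sigma2 = bm$sigma2,
                 loglik = bm$loglik)
    boundary <- TRUE
    note <- "alpha at the Brownian-motion (alpha = 0) boundary"
  } else if (alpha > 0.95 * hi) {
    note <- sprintf("alpha (%.3g) near upper search bound %.3g: attraction is effectively unresolvable upward", alpha, hi)
  }
  new_evol_fit("OU", prof$sigma2, alpha, prof$root_state, prof$loglik, 3L,
               length(xv), data_fingerprint(tree, xv),
               boundary = boundary, convergence_note = note)
}

#' Likelihood-ratio test of OU against BM
#'
#' `statistic = 2 * (loglik_OU - loglik_BM)`, clamped at zero, compared to a
#' chi-square with 1 degree of freedom. Because the null value of `alpha` sits
#' on the boundary of its parameter space the plain chi-square reference is
#' conservative; no boundary-mixture correction is applied.
#'
#' @param fit_bm,fit_ou `"evol_model_fit"` objects computed on the same tree
#'   and data (checked via fingerprints).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
lrt_bm_vs_ou <- function(fit_bm, fit_ou) {
  stopifnot(inherits(fit_bm, "evol_model_fit"),
            inherits(fit_ou, "evol_model_fit"))
  if (fit_bm$model != "BM" || fit_ou$model != "OU") {
    stop("expected one BM and one OU fit", call. = FALSE)
  }
  if (!identical(fit_bm$fingerprint, fit_ou$fingerprint)) {
    stop("fits were computed on different data or trees", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_ou$loglik - fit_bm$loglik))
  p <- if (stat == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, df = 1L)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' GLS / empirical-Bayes estimates of internal-node states: the conditional
#' expectation of each internal node given the tips, at the ML root state.
#' The root estimate equals the GLS mean of [fit_bm()]; tip states are the
#' observed values.
#'
#' @param tree A `"phylo"` object.
#' @param x Named numeric tip vector.
#' @param n_interp Number of interpolated points per branch in the export
#'   table (0 for node states only), supporting continuous trait maps.
#' @return List with `states` (named by internal node id), `root_state`,
#'   `export` (data frame `node`, `height`, `state`, including interpolated
#'   per-branch rows when `n_interp > 0`).
#' @export
ancestral_states_bm <- function(tree, x, n_interp = 0L) {
  al <- align_trait(tree, x)
  tree <- al$tree; x <- al$x
  n <- ape::Ntip(tree)
  fit <- fit_bm(tree, x)
  z0 <- fit$root_state
  S <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  dep <- node_depths(tree)
  mr <- ape::mrca(tree, full = TRUE)
  internal <- (n + 1L):(n + tree$Nnode)
  # cov(node k, tip i) = depth of their most recent common ancestor
  C <- matrix(dep[mr[internal, seq_len(n), drop = FALSE]],
              nrow = length(internal))
  xv <- x[tree$tip.label]
  states <- as.numeric(z0 + C %*% solve(S, xv - z0))
  names(states) <- internal
  all_states <- c(stats::setNames(xv, seq_len(n)), states)
  export <- data.frame(node = as.integer(names(all_states)),
                       height = dep[as.integer(names(all_states))],
                       state = as.numeric(all_states))
  if (n_interp > 0L) {
    extra <- lapply(seq_len(nrow(tree$edge)), function(i) {
      p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      f <- seq_len(n_interp) / (n_interp + 1)
      data.frame(node = ch,
                 height = dep[p] + f * (dep[ch] - dep[p]),
                 state = all_states[as.character(p)] +
                   f * (all_states[as.character(ch)] - all_states[as.character(p)]))
    })
    export <- rbind(export, do.call(rbind, extra))
    export <- export[order(export$node, export$height), ]
    rownames(export) <- NULL
  }
  list(states = states, root_state = z0, export = export, fit = fit)
}
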