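# Independent oracles used across the suite: dense-matrix GLS/MVN
# computations that never share code with the pruning implementation.

# dense multivariate-normal log density of tip values under BM
dense_bm_loglik <- function(tree, x, sigma2, root_state) {
  V <- sigma2 * ape::vcv(tree)[tree$tip.label, tree$tip.label]
  r <- x[tree$tip.label] - root_state
  n <- length(r)
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# dense GLS correlation under the BM covariance
dense_gls_correlation <- function(tree, x, y) {
  V <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  gmean <- function(v) sum(Vi %*% v) / sum(Vi %*% one)
  rx <- x[tree$tip.label] - gmean(x[tree$tip.label])
  ry <- y[tree$tip.label] - gmean(y[tree$tip.label])
  as.numeric((t(rx) %*% Vi %*% ry) /
               sqrt((t(rx) %*% Vi %*% rx) * (t(ry) %*% Vi %*% ry)))
}

# random non-ultrametric tree with canonical tip labels
random_test_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_tips <- function(tree) {
  stats::setNames(stats::rnorm(ape::Ntip(tree)), tree$tip.label)
}

# a trait vector with every field render_trajectory needs
demo_true_traits <- function(osc = TRUE) {
  base <- c(cell_length_um = 50, cell_width_um = 30, relative_asymmetry = 1.29,
            initial_spindle_position_um = -2, final_spindle_position_um = 6,
            initial_spindle_length_um = 14, elongation_fold = 1.92,
            elongation_duration_s = 150,
            osc_max_amplitude_post_um = if (osc) 6 else 0,
            osc_max_amplitude_ant_um = if (osc) 3.7 else 0,
            osc_frequency_mhz = if (osc) 40 else 0,
            osc_duration_s = if (osc) 200 else 0)
  nemaspindle:::derive_traits(base, 0.5)
}

noise_free_config <- function() {
  cfg <- generator_config()
  cfg$tracking_noise_sd <- 0
  cfg
}
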