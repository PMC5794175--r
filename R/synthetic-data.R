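# Synthetic cohort generator: species trait means evolving on a phylogeny,
# Gaussian strain- and embryo-level dispersion, and kinematic rendering of
# per-embryo centrosome trajectories (logistic displacement/elongation ramps,
# antiphase transverse oscillations under a raised-cosine envelope, Gaussian
# tracking noise). Every stage is seeded and reproducible.

#' Simulate continuous-trait evolution along a tree
#'
#' Recursive root-to-tip simulation. Brownian motion adds independent
#' Gaussian increments with variance `sigma2 * t` per branch; the
#' Ornstein-Uhlenbeck model uses the exact transition
#' `child = theta + (parent - theta) * exp(-alpha t) + N(0, sigma2 (1 -
#' exp(-2 alpha t)) / (2 alpha))` with the optimum `theta` equal to the root
#' state.
#'
#' @param tree A `"phylo"` object.
#' @param model List: `type` (`"BM"` or `"OU"`), `sigma2` (> 0 or 0 for a
#'   constant trait), `root`, and for OU `alpha` (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait_evolution <- function(tree, model, seed) {
  stopifnot(model$type %in% c("BM", "OU"), model$sigma2 >= 0)
  set.seed(seed)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  value <- numeric(nn)
  root <- n + 1L
  value[root] <- model$root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]; t <- ord$edge.length[i]
    if (model$type == "BM") {
      value[ch] <- value[p] + stats::rnorm(1, 0, sqrt(model$sigma2 * t))
    } else {
      a <- model$alpha
      decay <- exp(-a * t)
      sd_t <- sqrt(model$sigma2 * (1 - exp(-2 * a * t)) / (2 * a))
      value[ch] <- model$root + (value[p] - model$root) * decay +
        stats::rnorm(1, 0, sd_t)
    }
  }
  stats::setNames(value[seq_len(n)], tree$tip.label)
}

#' Default generator configuration
#'
#' The defaults emulate the study design: 42 species on an ultrametric
#' phylogeny, ~3 strains per species and 10 embryos per strain (~1,260
#' embryos), frames every 0.5 s, an oscillating clade covering roughly the
#' *Caenorhabditis*-like fraction of species, and trait roots/dispersions
#' spanning the reported ranges (posterior amplitudes ~1.5-12.5 um,
#' frequencies ~29-64 mHz, oscillation durations ~64-369 s, elongation folds
#' ~1.4-2.8).
#'
#' @param n_species,strains_per_species,embryos_per_strain Cohort dimensions.
#' @param seed Master seed; all substreams derive from it by fixed offsets.
#' @param tree Optional `"phylo"` to use instead of a random Yule tree.
#' @return A `"generator_config"` list. Fields of note:
#'   `trait_models` (per base trait: root, sigma2 on the unit-depth tree),
#'   `sigma_strain`, `sigma_embryo` (intraspecific SDs),
#'   `oscillating_fraction` (share of tips in the oscillating clade),
#'   `dt` (s), `tracking_noise_sd` (um), `pre_time` (s recorded before NEB),
#'   `t_mid` (s, midpoint of the anaphase ramps), `prominence_ref` (um,
#'   detection threshold the envelope-support correction is derived for),
#'   `bounds` (physical truncation bounds, enforced by resampling).
#' @export
generator_config <- function(n_species = 42L, strains_per_species = 3L,
                             embryos_per_strain = 10L, seed = 1L,
                             tree = NULL) {
  base <- c("cell_length_um", "cell_width_um", "relative_asymmetry",
            "initial_spindle_position_um", "final_spindle_position_um",
            "initial_spindle_length_um", "elongation_fold",
            "elongation_duration_s", "osc_max_amplitude_post_um",
            "osc_max_amplitude_ant_um", "osc_frequency_mhz", "osc_duration_s")
  trait_models <- list(
    cell_length_um = list(root = 50, sigma2 = 36),
    cell_width_um = list(root = 30, sigma2 = 12),
    relative_asymmetry = list(root = 1.29, sigma2 = 0.0064),
    initial_spindle_position_um = list(root = -1, sigma2 = 4),
    final_spindle_position_um = list(root = 6, sigma2 = 2.25),
    initial_spindle_length_um = list(root = 14, sigma2 = 4),
    elongation_fold = list(root = 1.92, sigma2 = 0.09),
    elongation_duration_s = list(root = 150, sigma2 = 900),
    osc_max_amplitude_post_um = list(root = 6, sigma2 = 6),
    osc_max_amplitude_ant_um = list(root = 3.7, sigma2 = 2),
    osc_frequency_mhz = list(root = 45, sigma2 = 64),
    osc_duration_s = list(root = 200, sigma2 = 4900)
  )
  for (nm in base) trait_models[[nm]]$type <- "BM"
  sigma_strain <- c(cell_length_um = 2, cell_width_um = 1.5,
                    relative_asymmetry = 0.04,
                    initial_spindle_position_um = 0.5,
                    final_spindle_position_um = 0.5,
                    initial_spindle_length_um = 0.5, elongation_fold = 0.05,
                    elongation_duration_s = 10,
                    osc_max_amplitude_post_um = 0.5,
                    osc_max_amplitude_ant_um = 0.3,
                    osc_frequency_mhz = 2, osc_duration_s = 15)
  sigma_embryo <- c(cell_length_um = 2, cell_width_um = 1.5,
                    relative_asymmetry = 0.08,
                    initial_spindle_position_um = 1.0,
                    final_spindle_position_um = 0.8,
                    initial_spindle_length_um = 1.0, elongation_fold = 0.12,
                    elongation_duration_s = 15,
                    osc_max_amplitude_post_um = 1.0,
                    osc_max_amplitude_ant_um = 0.6,
                    osc_frequency_mhz = 3, osc_duration_s = 25)
  bounds <- list(cell_length_um = c(20, 90), cell_width_um = c(12, 60),
                 relative_asymmetry = c(1, 2),
                 initial_spindle_position_um = c(-15, 15),
                 final_spindle_position_um = c(-15, 20),
                 initial_spindle_length_um = c(5, 30),
                 elongation_fold = c(1, 3.5),
                 elongation_duration_s = c(40, 400),
                 osc_max_amplitude_post_um = c(1, 15),
                 osc_max_amplitude_ant_um = c(1, 15),
                 osc_frequency_mhz = c(15, 90),
                 osc_duration_s = c(50, 450))
  structure(list(n_species = n_species,
                 strains_per_species = strains_per_species,
                 embryos_per_strain = embryos_per_strain,
                 seed = as.integer(seed), tree = tree,
                 base_traits = base, trait_models = trait_models,
                 sigma_strain = sigma_strain, sigma_embryo = sigma_embryo,
                 bounds = bounds, oscillating_fraction = 0.62,
                 dt = 0.5, tracking_noise_sd = 0.1, pre_time = 60,
                 t_mid = 100, post_time = 60, prominence_ref = 0.5,
                 max_resample = 100L),
            class = "generator_config")
}

# internal: sub-threshold phase fraction of the raised-cosine envelope for a
# peak-to-valley excursion M and detection prominence p.
envelope_u_star <- function(M, p) {
  if (M <= p) return(0.5)
  acos(1 - 2 * p / M) / (2 * pi)
}

# internal: mean envelope factor over the detectable span (defines the true
# mean-amplitude trait consistently with the rendering convention).
envelope_mean_factor <- function(M, p) {
  u <- envelope_u_star(M, p)
  if (u >= 0.5) return(0)
  us <- seq(u, 1 - u, length.out = 401L)
  mean(0.5 * (1 - cos(2 * pi * us)))
}

# internal: derive the full 22-trait vector from the 12 base traits.
derive_traits <- function(b, prominence_ref = 0.5) {
  L0 <- b[["initial_spindle_length_um"]]
  Lf <- b[["elongation_fold"]] * L0
  ra <- b[["relative_asymmetry"]]
  p1 <- b[["cell_length_um"]] / (1 + ra)
  Mp <- b[["osc_max_amplitude_post_um"]]
  Ma <- b[["osc_max_amplitude_ant_um"]]
  oscillating <- Mp > 0
  mean_p <- if (oscillating) Mp * envelope_mean_factor(Mp, prominence_ref) else 0
  mean_a <- if (oscillating && Ma > 0) Ma * envelope_mean_factor(Ma, prominence_ref) else 0
  c(cell_length_um = unname(b[["cell_length_um"]]),
    cell_width_um = unname(b[["cell_width_um"]]),
    aspect_ratio = unname(b[["cell_length_um"]] / b[["cell_width_um"]]),
    division_plane_position_um = unname(p1),
    relative_asymmetry = unname(ra),
    initial_spindle_position_um = unname(b[["initial_spindle_position_um"]]),
    final_spindle_position_um = unname(b[["final_spindle_position_um"]]),
    spindle_displacement_um = unname(b[["final_spindle_position_um"]] -
                                       b[["initial_spindle_position_um"]]),
    initial_spindle_length_um = unname(L0),
    final_spindle_length_um = unname(Lf),
    elongation_fold = unname(b[["elongation_fold"]]),
    elongation_duration_s = unname(b[["elongation_duration_s"]]),
    elongation_speed_um_s = unname((Lf - L0) / b[["elongation_duration_s"]]),
    osc_max_amplitude_ant_um = unname(if (oscillating) Ma else 0),
    osc_max_amplitude_post_um = unname(if (oscillating) Mp else 0),
    osc_mean_amplitude_ant_um = unname(mean_a),
    osc_mean_amplitude_post_um = unname(mean_p),
    osc_frequency_ant_mhz = unname(if (oscillating) b[["osc_frequency_mhz"]] else 0),
    osc_frequency_post_mhz = unname(if (oscillating) b[["osc_frequency_mhz"]] else 0),
    osc_duration_s = unname(if (oscillating) b[["osc_duration_s"]] else 0),
    osc_asymmetry_max = unname(if (oscillating && Ma > 0) Mp / Ma else NA_real_),
    osc_asymmetry_mean = unname(if (oscillating && mean_a > 0) mean_p / mean_a else NA_real_))
}

# internal: one Gaussian draw per base trait around `center`, truncated to the
# physical bounds by resampling; joint consistency (final spindle length
# inside the cell) enforced the same way.
draw_base_traits <- function(center, sds, bounds, oscillating,
                             max_resample = 100L) {
  out <- center
  for (nm in names(center)) {
    if (!oscillating && startsWith(nm, "osc")) { out[nm] <- 0; next }
    lo <- bounds[[nm]][1L]; hi <- bounds[[nm]][2L]
    v <- stats::rnorm(1, center[[nm]], sds[[nm]])
    tries <- 0L
    while ((v < lo || v > hi) && tries < max_resample) {
      v <- stats::rnorm(1, center[[nm]], sds[[nm]])
      tries <- tries + 1L
    }
    if (v < lo || v > hi) v <- min(max(v, lo), hi)   # last-resort clip, logged upstream
    out[nm] <- v
  }
  # keep the rendered geometry feasible
  max_fold <- 0.9 * out[["cell_length_um"]] / out[["initial_spindle_length_um"]]
  if (out[["elongation_fold"]] > max_fold) out[["elongation_fold"]] <- max_fold
  half <- 0.45 * out[["cell_length_um"]]
  out[["initial_spindle_position_um"]] <- min(max(out[["initial_spindle_position_um"]], -half), half)
  out[["final_spindle_position_um"]] <- min(max(out[["final_spindle_position_um"]], -half), half)
  out
}

#' Hierarchical sampling of a cohort's true trait values
#'
#' Strain values are Normal(species value, sigma_strain) and embryo values
#' Normal(strain value, sigma_embryo), per base trait, truncated to physical
#' bounds by resampling; derived traits (ratios, displacement, speed, mean
#' amplitudes) are computed from the base values at each level.
#'
#' @param species_traits Data frame of species-level base traits (rows:
#'   species, columns: `species` + the 12 base traits).
#' @param oscillating Character vector of oscillating species.
#' @param config A `"generator_config"`.
#' @return List of data frames `species`, `strain`, `embryo` (22 derived
#'   traits each, plus label columns).
#' @export
sample_cohort <- function(species_traits, oscillating, config) {
  set.seed(config$seed + 1L)
  base <- config$base_traits
  sp_rows <- lapply(seq_len(nrow(species_traits)), function(i) {
    b <- unlist(species_traits[i, base])
    data.frame(species = species_traits$species[i],
               t(derive_traits(b, config$prominence_ref)))
  })
  strain_rows <- list(); embryo_rows <- list()
  for (i in seq_len(nrow(species_traits))) {
    sp <- species_traits$species[i]
    osc <- sp %in% oscillating
    sp_base <- unlist(species_traits[i, base])
    for (s in seq_len(config$strains_per_species)) {
      st_base <- draw_base_traits(sp_base, config$sigma_strain, config$bounds,
                                  osc, config$max_resample)
      st_name <- sprintf("%s_st%d", sp, s)
      strain_rows[[length(strain_rows) + 1L]] <-
        data.frame(species = sp, strain = st_name,
                   t(derive_traits(st_base, config$prominence_ref)))
      for (e in seq_len(config$embryos_per_strain)) {
        em_base <- draw_base_traits(st_base, config$sigma_embryo,
                                    config$bounds, osc, config$max_resample)
        embryo_rows[[length(embryo_rows) + 1L]] <-
          data.frame(species = sp, strain = st_name, embryo = e,
                     t(derive_traits(em_base, config$prominence_ref)))
      }
    }
  }
  list(species = do.call(rbind, sp_rows),
       strain = do.call(rbind, strain_rows),
       embryo = do.call(rbind, embryo_rows))
}

#' Render one embryo's centrosome trajectories from true trait values
#'
#' Kinematic model: spindle-center position and spindle length follow
#' logistic ramps whose 2.5%-97.5% rise spans the elongation-duration trait;
#' the two centrosomes sit at center -/+ length/2 on the antero/posterior
#' axis; transverse positions are antiphase sinusoids (posterior positive
#' first) under a raised-cosine envelope whose support is sized so that the
#' span of detectable extrema (excursion above `prominence_ref`) matches the
#' oscillation-duration trait; i.i.d. Gaussian tracking noise is added to
#' every coordinate.
#'
#' @param true_traits Named numeric vector holding at least the 22 derived
#'   traits (as produced by [sample_cohort()]).
#' @param config A `"generator_config"`.
#' @param seed Integer seed for the tracking noise.
#' @param strain,species Labels stored in the recording.
#' @return An `"embryo_recording"`.
#' @export
render_trajectory <- function(true_traits, config = generator_config(),
                              seed = 1L, strain = "synthetic",
                              species = "synthetic") {
  tt <- true_traits
  L0 <- tt[["initial_spindle_length_um"]]
  Lf <- tt[["final_spindle_length_um"]]
  if (Lf >= tt[["cell_length_um"]]) {
    stop("inconsistent traits: final spindle length (", signif(Lf, 4),
         ") must be smaller than cell length (",
         signif(tt[["cell_length_um"]], 4), ")", call. = FALSE)
  }
  dt <- config$dt
  D_e <- max(tt[["elongation_duration_s"]], dt)
  Mp <- tt[["osc_max_amplitude_post_um"]]
  Ma <- tt[["osc_max_amplitude_ant_um"]]
  f <- tt[["osc_frequency_post_mhz"]] / 1000            # Hz
  D_osc <- tt[["osc_duration_s"]]
  oscillating <- Mp > 0 && f > 0 && D_osc > 0
  D_support <- if (oscillating) {
    u_star <- envelope_u_star(Mp, config$prominence_ref)
    D_osc / (1 - 2 * u_star)
  } else 0
  # keep the whole envelope and ramp inside the recording window
  t_mid <- max(config$t_mid,
               max(D_e, D_support) / 2 - config$pre_time + 20)
  t_end <- t_mid + max(D_e, D_support) / 2 + config$post_time
  time <- seq(-config$pre_time, t_end, by = dt)
  # logistic ramp whose 2.5%-97.5% rise spans D_e
  tau <- D_e / (2 * stats::qlogis(0.975))
  S <- stats::plogis((time - t_mid) / tau)
  center <- tt[["initial_spindle_position_um"]] +
    (tt[["final_spindle_position_um"]] - tt[["initial_spindle_position_um"]]) * S
  len <- L0 + (Lf - L0) * S
  if (oscillating) {
    t0 <- t_mid - D_support / 2
    u <- (time - t0) / D_support
    env <- ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
    carrier <- sin(2 * pi * f * (time - t0))
    y_post <- (Mp / 2) * env * carrier
    y_ant <- -(Ma / 2) * env * carrier
  } else {
    y_post <- y_ant <- numeric(length(time))
  }
  set.seed(seed)
  noise <- function() stats::rnorm(length(time), 0, config$tracking_noise_sd)
  ant <- cbind(x = center - len / 2 + noise(), y = y_ant + noise())
  post <- cbind(x = center + len / 2 + noise(), y = y_post + noise())
  ra <- tt[["relative_asymmetry"]]
  cl <- tt[["cell_length_um"]]
  embryo_recording(time, ant, post,
                   cell_length = cl, cell_width = tt[["cell_width_um"]],
                   ab_length = cl * ra / (1 + ra), p1_length = cl / (1 + ra),
                   neb_frame = which.min(abs(time)),
                   strain = strain, species = species)
}

#' Generate a full synthetic cohort
#'
#' Simulates species trait means on the tree, picks the oscillating clade
#' (the clade whose tip count is closest to `oscillating_fraction` of the
#' tips, emulating the genus-level innovation of transverse oscillations),
#' samples strain- and embryo-level values, and renders one recording per
#' embryo. Deterministic for a fixed master seed; per-embryo noise streams
#' derive from the seed by embryo counter, not iteration order.
#'
#' @param config A `"generator_config"`.
#' @return List: `recordings` (list of `"embryo_recording"`), `ground_truth`
#'   (species/strain/embryo trait tables), `tree`, `oscillating_species`,
#'   `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  tree <- config$tree
  if (is.null(tree)) {
    tree <- random_ultrametric_tree(config$n_species, depth = 1,
                                    seed = config$seed)
  }
  oscillating <- oscillating_clade(tree, config$oscillating_fraction)
  sp_list <- lapply(seq_along(config$base_traits), function(k) {
    nm <- config$base_traits[k]
    simulate_trait_evolution(tree, config$trait_models[[nm]],
                             seed = config$seed + 1000L * k)
  })
  names(sp_list) <- config$base_traits
  species_traits <- data.frame(species = tree$tip.label,
                               as.data.frame(sp_list)[tree$tip.label, ])
  # enforce bounds on the species means themselves (kept biologically sane)
  for (nm in config$base_traits) {
    b <- config$bounds[[nm]]
    species_traits[[nm]] <- pmin(pmax(species_traits[[nm]], b[1L]), b[2L])
  }
  gt <- sample_cohort(species_traits, oscillating, config)
  recs <- vector("list", nrow(gt$embryo))
  for (i in seq_len(nrow(gt$embryo))) {
    tt <- unlist(gt$embryo[i, trait_names()])
    recs[[i]] <- render_trajectory(tt, config,
                                   seed = config$seed + 100000L + i,
                                   strain = gt$embryo$strain[i],
                                   species = gt$embryo$species[i])
  }
  list(recordings = recs, ground_truth = gt, tree = tree,
       oscillating_species = oscillating, config = config)
}

#' Pick the oscillating clade
#'
#' Returns the tips of the internal node whose descendant tip count is
#' closest to `fraction` of all tips (a monophyletic stand-in for the
#' oscillating genus).
#'
#' @param tree A `"phylo"` object.
#' @param fraction Target tip share.
#' @return Character vector of tip labels.
#' @export
oscillating_clade <- function(tree, fraction = 0.62) {
  n <- ape::Ntip(tree)
  target <- fraction * n
  internal <- (n + 1L):(n + tree$Nnode)
  sizes <- vapply(internal, function(nd)
    length(tip_descendants(tree, nd)), integer(1))
  best <- internal[which.min(abs(sizes - target))]
  tree$tip.label[tip_descendants(tree, best)]
}

# internal: tip indices descending from a node
tip_descendants <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  sort(unlist(lapply(kids, tip_descendants, tree = tree)))
}
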