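# Extraction of the 22 quantitative spindle traits from centrosome
# trajectories. The oscillation amplitude convention is the peak-to-valley
# excursion in micrometres; elongation plateaus replace the manual
# first-plateau / final-plateau reading with a slope-threshold rule, and the
# elongation interval is the 2.5%-97.5% rise of the smoothed length curve.

#' Default extraction settings
#'
#' @return Named list of extraction parameters: `smooth_window` (frames,
#'   centered moving average), `prominence` (micrometres, minimum qualifying
#'   oscillation excursion), `slope_window` (frames for the plateau slope),
#'   `slope_min` (micrometres/s, absolute plateau slope threshold),
#'   `slope_rel` (fraction of the peak slope used as an adaptive plateau
#'   threshold), `level_frac` (rise fraction bounding the elongation
#'   interval), `min_rise` (micrometres below which a length change counts as
#'   no elongation), `max_gap` (frames, longest track gap filled by linear
#'   interpolation).
#' @export
extraction_settings <- function() {
  list(smooth_window = 5L, prominence = 0.5, slope_window = 10L,
       slope_min = 0.01, slope_rel = 0.05, level_frac = 0.02,
       min_rise = 0.5, max_gap = 5L)
}

# internal: centered moving average with shrinking windows at the edges.
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  h <- window %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# internal: linear interpolation of NA runs up to max_gap frames.
fill_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  if (max(r$lengths[r$values]) > max_gap) {
    stop("track gap longer than ", max_gap, " frames", call. = FALSE)
  }
  idx <- which(!is.na(v))
  if (length(idx) < 2L) stop("track has too few observed frames", call. = FALSE)
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Spindle length over time
#'
#' Per-frame Euclidean distance between the two centrosomes; track gaps of up
#' to `max_gap` frames are filled by linear interpolation.
#'
#' @param rec An `"embryo_recording"`.
#' @param max_gap Longest interpolatable gap (frames).
#' @return Numeric vector (micrometres), one value per frame.
#' @export
spindle_length_series <- function(rec, max_gap = extraction_settings()$max_gap) {
  ax <- fill_gaps(rec$ant[, "x"], max_gap); ay <- fill_gaps(rec$ant[, "y"], max_gap)
  px <- fill_gaps(rec$post[, "x"], max_gap); py <- fill_gaps(rec$post[, "y"], max_gap)
  sqrt((px - ax)^2 + (py - ay)^2)
}

#' Detect elongation plateaus of a spindle-length series
#'
#' Automated replacement for the manual plateau reading: the initial plateau
#' is the longest prefix, and the final plateau the longest suffix, over which
#' the smoothed slope stays below `max(slope_min, slope_rel * peak slope)`.
#' `L0` and `Lf` are the plateau means; the elongation interval is bounded by
#' the 2.5% and 97.5% crossings of the total rise, and the elongation speed is
#' `(Lf - L0) / duration`.
#'
#' @param length_series Numeric vector of spindle lengths (micrometres).
#' @param dt Frame step (s).
#' @param settings See [extraction_settings()].
#' @return List: `L0`, `Lf` (micrometres), `t_start`, `t_end`, `duration` (s,
#'   from the start of the series), `speed` (micrometres/s), frame indices
#'   `start_frame`/`end_frame`, plateau index sets, and `flags`.
#' @export
detect_plateaus <- function(length_series, dt, settings = extraction_settings()) {
  n <- length(length_series)
  if (n < 20L) stop("need at least 20 frames", call. = FALSE)
  s <- moving_average(length_series, settings$smooth_window)
  h <- max(1L, settings$slope_window %/% 2L)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  slope <- (s[hi] - s[lo]) / ((hi - lo) * dt)
  thr <- max(settings$slope_min, settings$slope_rel * max(abs(slope)))
  flags <- character(0)
  flat <- abs(slope) < thr
  i0 <- if (flat[1L]) {
    end0 <- if (all(flat)) n else which(!flat)[1L] - 1L
    seq_len(end0)
  } else integer(0)
  jf <- if (flat[n]) {
    startf <- if (all(flat)) 1L else max(which(!flat)) + 1L
    startf:n
  } else integer(0)
  if (length(i0) == 0L) {
    flags <- c(flags, "no_initial_plateau")
    i0 <- seq_len(min(10L, n))
  }
  truncated <- length(jf) < 5L
  if (truncated) {
    flags <- c(flags, "truncated_no_final_plateau")
    jf <- (n - min(9L, n - 1L)):n
  }
  L0 <- mean(s[i0]); Lf <- mean(s[jf])
  rise <- Lf - L0
  if (abs(rise) < settings$min_rise) {
    return(list(L0 = L0, Lf = Lf, t_start = NA_real_, t_end = NA_real_,
                duration = 0, speed = 0,
                start_frame = NA_integer_, end_frame = NA_integer_,
                initial_idx = i0, final_idx = jf,
                flags = c(flags, "no_elongation")))
  }
  mid <- which.max(abs(slope))
  lev_lo <- L0 + settings$level_frac * rise
  lev_hi <- Lf - settings$level_frac * rise
  below <- if (rise > 0) which(s[seq_len(mid)] <= lev_lo) else which(s[seq_len(mid)] >= lev_lo)
  start_frame <- if (length(below)) max(below) else 1L
  above <- if (rise > 0) which(s[mid:n] >= lev_hi) else which(s[mid:n] <= lev_hi)
  end_frame <- if (length(above)) mid + min(above) - 1L else n
  duration <- (end_frame - start_frame) * dt
  list(L0 = L0, Lf = Lf,
       t_start = (start_frame - 1L) * dt, t_end = (end_frame - 1L) * dt,
       duration = duration,
       speed = if (duration > 0) rise / duration else 0,
       start_frame = start_frame, end_frame = end_frame,
       initial_idx = i0, final_idx = jf, flags = flags)
}

#' Spindle position traits
#'
#' The spindle (or nuclei-centrosome complex) center is the midpoint of the
#' two centrosomes. The initial position is its most anterior excursion (the
#' minimum of the smoothed center x, negative values meaning anterior
#' overshoot past the cell center) over the window preceding elongation
#' onset; the final position is the mean over the terminal plateau; the
#' displacement is final minus initial.
#'
#' @param rec An `"embryo_recording"`.
#' @param plateaus Optional result of [detect_plateaus()] on the spindle
#'   length series (computed if missing).
#' @param settings See [extraction_settings()].
#' @return List: `initial_position`, `final_position`, `displacement`
#'   (micrometres, signed along the antero/posterior axis), `flags` (contains
#'   `"started_after_rotation"` when the anterior-most position is not
#'   detectable because it falls on the first frame).
#' @export
positional_traits <- function(rec, plateaus = NULL,
                              settings = extraction_settings()) {
  rec <- dedupe_frames(rec)
  dt <- rec_dt(rec)
  if (is.null(plateaus)) {
    plateaus <- detect_plateaus(spindle_length_series(rec, settings$max_gap),
                                dt, settings)
  }
  cx_raw <- (fill_gaps(rec$ant[, "x"], settings$max_gap) +
               fill_gaps(rec$post[, "x"], settings$max_gap)) / 2
  cx <- moving_average(cx_raw, settings$smooth_window)
  n <- length(cx)
  flags <- character(0)
  pre_end <- if (!is.na(plateaus$start_frame)) plateaus$start_frame else n
  pre <- seq_len(max(pre_end, 2L))
  imin <- pre[which.min(cx[pre])]
  # the final position is read off the terminal plateau of the center series
  # itself (the spindle can still be settling when elongation has finished)
  pl_center <- detect_plateaus(cx_raw, dt, settings)
  # a minimum pinned to the very first frames of a posteriorly moving center
  # means the recording started after the anterior-most excursion
  k <- min(20L, length(pre))
  init_slope <- (cx[k] - cx[1L]) / ((k - 1L) * dt)
  if (imin <= 2L && init_slope > 0.02) {
    flags <- c(flags, "started_after_rotation")
  }
  initial <- cx[imin]
  final <- mean(cx[pl_center$final_idx])
  list(initial_position = initial, final_position = final,
       displacement = final - initial, flags = flags)
}

#' Detect transverse oscillation extrema
#'
#' Smooths the transverse position with a centered moving average, collects
#' alternating local peaks and valleys, and prunes extrema until every
#' successive peak-valley excursion is at least `prominence` micrometres. A
#' series that never qualifies yields an empty profile.
#'
#' @param y Numeric vector, transverse centrosome position (micrometres,
#'   relative to the cell equator).
#' @param dt Frame step (s).
#' @param smoothing_window Frames in the centered moving average.
#' @param prominence Minimum peak-to-valley excursion (micrometres).
#' @return An `"oscillation_profile"`: data frame with columns `frame`,
#'   `value`, `kind` (`"peak"`/`"valley"`), plus the settings as attributes.
#' @export
detect_oscillations <- function(y, dt,
                                smoothing_window = extraction_settings()$smooth_window,
                                prominence = extraction_settings()$prominence) {
  if (length(y) < 40L) stop("need at least 40 frames", call. = FALSE)
  s <- moving_average(y, smoothing_window)
  d <- diff(s)
  # ties at the ulp level would make extremum positions depend on a constant
  # offset of y; treat near-zero slopes as flat
  eps <- 1e-9 * diff(range(s))
  d[abs(d) < eps] <- 0
  sgn <- sign(d)
  # carry the previous sign through flat stretches
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  turns <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0) + 1L
  if (!length(turns)) {
    return(empty_profile(dt, smoothing_window, prominence))
  }
  kind <- ifelse(sgn[turns - 1L] > 0, "peak", "valley")
  frame <- turns
  value <- s[turns]
  # collapse consecutive extrema of the same kind to the most extreme one
  keep <- rep(TRUE, length(frame))
  for (i in seq_along(frame)[-1L]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (kind[i] == kind[j]) {
      if ((kind[i] == "peak") == (value[i] >= value[j])) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  frame <- frame[keep]; value <- value[keep]; kind <- kind[keep]
  # prune until all successive excursions reach the prominence threshold
  repeat {
    if (length(frame) < 2L) {
      if (length(frame) == 1L) frame <- integer(0)
      break
    }
    exc <- abs(diff(value))
    if (all(exc >= prominence)) break
    w <- which.min(exc)
    if (w == 1L) {
      drop <- 1L                                  # weak leading extremum
    } else if (w == length(exc)) {
      drop <- length(frame)                       # weak trailing extremum
    } else {
      drop <- c(w, w + 1L)                        # weak interior pair
    }
    frame <- frame[-drop]; value <- value[-drop]; kind <- kind[-drop]
  }
  if (!length(frame)) return(empty_profile(dt, smoothing_window, prominence))
  prof <- data.frame(frame = frame, value = value, kind = kind)
  structure(prof, class = c("oscillation_profile", "data.frame"),
            dt = dt, smoothing_window = smoothing_window,
            prominence = prominence)
}

empty_profile <- function(dt, smoothing_window, prominence) {
  structure(data.frame(frame = integer(0), value = numeric(0),
                       kind = character(0)),
            class = c("oscillation_profile", "data.frame"),
            dt = dt, smoothing_window = smoothing_window,
            prominence = prominence)
}

#' Oscillation traits from an extrema profile
#'
#' The amplitude of one oscillation is the absolute value difference between
#' a successive peak/valley pair (peak-to-valley excursion, micrometres); the
#' traits are the maximum and mean over all successive pairs, the total
#' duration (time between first and last extremum, s), and the frequency in
#' millihertz. The frequency uses the mean interval between successive
#' same-kind extrema (one full cycle) when at least three same-kind extrema
#' exist, and the full-cycle count divided by the duration otherwise; the
#' rule applied is recorded in the `frequency_rule` element.
#'
#' @param profile An `"oscillation_profile"`.
#' @param dt Frame step (s); defaults to the profile's.
#' @return List: `max_amplitude`, `mean_amplitude` (micrometres), `frequency`
#'   (mHz), `duration` (s), `n_extrema`, `frequency_rule`, `flags`. An empty
#'   profile gives all zeros.
#' @export
oscillation_traits <- function(profile, dt = attr(profile, "dt")) {
  m <- nrow(profile)
  if (m < 2L) {
    return(list(max_amplitude = 0, mean_amplitude = 0, frequency = 0,
                duration = 0, n_extrema = m, frequency_rule = "none",
                flags = if (m == 1L) "single_extremum_unreliable" else character(0)))
  }
  exc <- abs(diff(profile$value))
  duration <- (profile$frame[m] - profile$frame[1L]) * dt
  pk <- profile$frame[profile$kind == "peak"]
  vl <- profile$frame[profile$kind == "valley"]
  cycles <- c(diff(pk), diff(vl)) * dt
  if (max(length(pk), length(vl)) >= 3L) {
    freq <- 1000 / mean(cycles)
    rule <- "mean_cycle_length"
  } else if (duration > 0) {
    freq <- 1000 * ((m - 1) / 2) / duration
    rule <- "count_over_duration"
  } else {
    freq <- 0; rule <- "none"
  }
  list(max_amplitude = max(exc), mean_amplitude = mean(exc),
       frequency = freq, duration = duration, n_extrema = m,
       frequency_rule = rule, flags = character(0))
}

#' Geometry and asymmetry traits
#'
#' @param rec An `"embryo_recording"`.
#' @param post_traits,ant_traits Results of [oscillation_traits()] for the
#'   posterior and anterior centrosome.
#' @return List: `aspect_ratio` (cell length / cell width),
#'   `division_plane_position` (P1 length, micrometres), `relative_asymmetry`
#'   (AB / P1), `osc_asymmetry_max`, `osc_asymmetry_mean` (posterior /
#'   anterior amplitude ratios, `NA` and flagged when the anterior amplitude
#'   is zero), `flags`.
#' @export
asymmetry_traits <- function(rec, post_traits, ant_traits) {
  if (rec$p1_length <= 0) stop("P1 length must be > 0", call. = FALSE)
  flags <- character(0)
  if (ant_traits$max_amplitude > 0) {
    asym_max <- post_traits$max_amplitude / ant_traits$max_amplitude
    asym_mean <- post_traits$mean_amplitude / ant_traits$mean_amplitude
  } else {
    asym_max <- asym_mean <- NA_real_
    flags <- "osc_asymmetry_undefined_zero_anterior"
  }
  list(aspect_ratio = rec$cell_length / rec$cell_width,
       division_plane_position = rec$p1_length,
       relative_asymmetry = rec$ab_length / rec$p1_length,
       osc_asymmetry_max = asym_max, osc_asymmetry_mean = asym_mean,
       flags = flags)
}

#' Names of the 22 quantitative traits
#' @return Character vector of trait column names (units encoded in names).
#' @export
trait_names <- function() {
  c("cell_length_um", "cell_width_um", "aspect_ratio",
    "division_plane_position_um", "relative_asymmetry",
    "initial_spindle_position_um", "final_spindle_position_um",
    "spindle_displacement_um", "initial_spindle_length_um",
    "final_spindle_length_um", "elongation_fold", "elongation_duration_s",
    "elongation_speed_um_s",
    "osc_max_amplitude_ant_um", "osc_max_amplitude_post_um",
    "osc_mean_amplitude_ant_um", "osc_mean_amplitude_post_um",
    "osc_frequency_ant_mhz", "osc_frequency_post_mhz",
    "osc_duration_s", "osc_asymmetry_max", "osc_asymmetry_mean")
}

#' Extract all 22 traits from one embryo recording
#'
#' Deterministic for fixed settings; traits that cannot be computed are set
#' to `NA` with a named flag, never silently.
#'
#' @param rec An `"embryo_recording"`.
#' @param settings See [extraction_settings()].
#' @return A `"trait_set"`: list with `traits` (named numeric vector of
#'   length 22), `flags` (character vector), `strain`, `species`.
#' @export
extract_all <- function(rec, settings = extraction_settings()) {
  rec <- dedupe_frames(rec)
  dt <- rec_dt(rec)
  len <- spindle_length_series(rec, settings$max_gap)
  pl <- detect_plateaus(len, dt, settings)
  pos <- positional_traits(rec, pl, settings)
  prof_a <- detect_oscillations(fill_gaps(rec$ant[, "y"], settings$max_gap), dt,
                                settings$smooth_window, settings$prominence)
  prof_p <- detect_oscillations(fill_gaps(rec$post[, "y"], settings$max_gap), dt,
                                settings$smooth_window, settings$prominence)
  osc_a <- oscillation_traits(prof_a, dt)
  osc_p <- oscillation_traits(prof_p, dt)
  asym <- asymmetry_traits(rec, osc_p, osc_a)
  traits <- c(
    cell_length_um = rec$cell_length,
    cell_width_um = rec$cell_width,
    aspect_ratio = asym$aspect_ratio,
    division_plane_position_um = asym$division_plane_position,
    relative_asymmetry = asym$relative_asymmetry,
    initial_spindle_position_um = pos$initial_position,
    final_spindle_position_um = pos$final_position,
    spindle_displacement_um = pos$displacement,
    initial_spindle_length_um = pl$L0,
    final_spindle_length_um = pl$Lf,
    elongation_fold = pl$Lf / pl$L0,
    elongation_duration_s = pl$duration,
    elongation_speed_um_s = pl$speed,
    osc_max_amplitude_ant_um = osc_a$max_amplitude,
    osc_max_amplitude_post_um = osc_p$max_amplitude,
    osc_mean_amplitude_ant_um = osc_a$mean_amplitude,
    osc_mean_amplitude_post_um = osc_p$mean_amplitude,
    osc_frequency_ant_mhz = osc_a$frequency,
    osc_frequency_post_mhz = osc_p$frequency,
    osc_duration_s = max(osc_a$duration, osc_p$duration),
    osc_asymmetry_max = asym$osc_asymmetry_max,
    osc_asymmetry_mean = asym$osc_asymmetry_mean)
  flags <- c(pl$flags, pos$flags, osc_a$flags, osc_p$flags, asym$flags)
  structure(list(traits = traits, flags = flags,
                 strain = rec$strain, species = rec$species),
            class = "trait_set")
}

#' Extract traits for a list of recordings into a trait table
#'
#' @param recordings List of `"embryo_recording"` objects.
#' @param settings See [extraction_settings()].
#' @return Data frame: `species`, `strain`, `embryo`, the 22 trait columns,
#'   and a `qc_flags` column (`;`-separated).
#' @export
extract_cohort <- function(recordings, settings = extraction_settings()) {
  rows <- lapply(seq_along(recordings), function(i) {
    ts <- extract_all(recordings[[i]], settings)
    cbind(data.frame(species = ts$species, strain = ts$strain, embryo = i),
          as.data.frame(as.list(ts$traits)),
          data.frame(qc_flags = paste(ts$flags, collapse = ";")))
  })
  do.call(rbind, rows)
}
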