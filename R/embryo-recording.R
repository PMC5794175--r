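#' Construct an embryo recording
#'
#' One embryo's centrosome trajectories on a uniform time grid plus cell
#' geometry. Coordinates follow the convention used throughout the package:
#' the x axis is antero/posterior with origin at the cell center and positive
#' toward the posterior, the y axis is transverse with origin at the cell
#' equator, and t = 0 is the onset of nuclear envelope breakdown (NEB).
#'
#' @param time Numeric vector of frame times (s), uniform step (nominally
#'   0.5 s).
#' @param ant,post Two-column matrices (or data frames) of anterior /
#'   posterior centrosome `x`, `y` positions in micrometres, one row per frame.
#' @param cell_length,cell_width Cell dimensions (micrometres).
#' @param ab_length,p1_length Lengths of the anterior (AB) and posterior (P1)
#'   daughter cells at division (micrometres); their sum must match
#'   `cell_length` within 5%.
#' @param neb_frame Frame index (1-based) of NEB; `time[neb_frame]` must be 0.
#' @param strain,species Labels.
#' @return An object of class `"embryo_recording"`.
#' @export
embryo_recording <- function(time, ant, post, cell_length, cell_width,
                             ab_length, p1_length, neb_frame = which.min(abs(time)),
                             strain = "synthetic", species = "synthetic") {
  ant <- as.matrix(ant); post <- as.matrix(post)
  stopifnot(ncol(ant) == 2L, ncol(post) == 2L,
            nrow(ant) == length(time), nrow(post) == length(time))
  colnames(ant) <- colnames(post) <- c("x", "y")
  if (length(time) >= 2L) {
    dts <- diff(time)
    if (diff(range(dts)) > 1e-6 * stats::median(dts)) {
      stop("time grid is not uniform", call. = FALSE)
    }
  }
  if (p1_length <= 0) stop("P1 length must be > 0", call. = FALSE)
  if (abs(ab_length + p1_length - cell_length) > 0.05 * cell_length) {
    stop("AB + P1 lengths deviate from cell length by more than 5%",
         call. = FALSE)
  }
  structure(list(time = as.numeric(time), ant = ant, post = post,
                 cell_length = cell_length, cell_width = cell_width,
                 ab_length = ab_length, p1_length = p1_length,
                 neb_frame = as.integer(neb_frame),
                 strain = strain, species = species),
            class = "embryo_recording")
}

#' @export
print.embryo_recording <- function(x, ...) {
  cat(sprintf("embryo recording: %s (%s), %d frames at %.3g s, cell %.3g x %.3g um\n",
              x$strain, x$species, length(x$time),
              if (length(x$time) > 1) x$time[2] - x$time[1] else NA_real_,
              x$cell_length, x$cell_width))
  invisible(x)
}

# internal: drop duplicated frames (identical time stamps), keeping the first.
dedupe_frames <- function(rec) {
  keep <- !duplicated(rec$time)
  if (all(keep)) return(rec)
  rec$time <- rec$time[keep]
  rec$ant <- rec$ant[keep, , drop = FALSE]
  rec$post <- rec$post[keep, , drop = FALSE]
  rec
}

# internal: frame step (s)
rec_dt <- function(rec) rec$time[2L] - rec$time[1L]
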