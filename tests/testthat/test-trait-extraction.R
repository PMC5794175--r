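make_rec <- function(time, ant, post, L = 50, W = 30, ra = 1.29) {
  embryo_recording(time, ant, post, cell_length = L, cell_width = W,
                   ab_length = L * ra / (1 + ra), p1_length = L / (1 + ra))
}

test_that("spindle length is the centrosome distance, with gap filling", {
  t <- seq(0, 50, 0.5)
  n <- length(t)
  ant <- cbind(x = rep(-7, n), y = rep(0, n))
  post <- cbind(x = rep(7, n), y = rep(0, n))
  rec <- make_rec(t, ant, post)
  expect_equal(spindle_length_series(rec), rep(14, n))
  post2 <- post; post2[10, ] <- c(7, 3)
  expect_equal(spindle_length_series(make_rec(t, ant, post2))[10],
               sqrt(14^2 + 3^2))
  post3 <- post; post3[20:23, "x"] <- NA      # 4-frame gap: interpolated
  expect_equal(spindle_length_series(make_rec(t, ant, post3)), rep(14, n))
  post4 <- post; post4[20:27, "x"] <- NA      # 8-frame gap: too long
  expect_error(spindle_length_series(make_rec(t, ant, post4)), "gap")
})

test_that("plateau detection handles constant and ramped series", {
  dt <- 0.5
  const <- rep(14, 200)
  pl <- detect_plateaus(const, dt)
  expect_equal(pl$L0, 14)
  expect_equal(pl$Lf, 14)
  expect_equal(pl$duration, 0)
  expect_equal(pl$speed, 0)
  # noise-free logistic ramp 14 -> 26 centered at 100 s, 1%-99% width ~20 s
  t <- seq(0, 200, dt)
  tau <- 20 / (2 * log(99))
  L <- 14 + 12 * stats::plogis((t - 100) / tau)
  pl2 <- detect_plateaus(L, dt)
  expect_equal(pl2$L0, 14, tolerance = 0.1 / 14)
  expect_equal(pl2$Lf, 26, tolerance = 0.1 / 26)
  expect_lt(abs(pl2$duration - 2 * log(99) * tau), 10)
  expect_equal(pl2$speed, (pl2$Lf - pl2$L0) / pl2$duration, tolerance = 1e-9)
  expect_equal(pl2$speed, 12 / pl2$duration, tolerance = 1e-3)
  # the reported mean elongation fold of the reference lab strain
  expect_equal(19.2 / 10, 1.92)
})

test_that("truncated recordings fall back to the last frames with a flag", {
  dt <- 0.5
  t <- seq(0, 100, dt)
  L <- 14 + 12 * stats::plogis((t - 95) / 8)   # still rising at the end
  pl <- detect_plateaus(L, dt)
  expect_true("truncated_no_final_plateau" %in% pl$flags)
})

test_that("positional traits: constant, ramp, and rotation flag", {
  dt <- 0.5
  t <- seq(0, 150, dt); n <- length(t)
  # constant center at +3
  ant <- cbind(x = 3 - 7, y = numeric(n)); post <- cbind(x = 3 + 7, y = numeric(n))
  pos <- positional_traits(make_rec(t, ant, post))
  expect_equal(pos$initial_position, 3, tolerance = 1e-6)
  expect_equal(pos$final_position, 3, tolerance = 1e-6)
  expect_equal(pos$displacement, 0, tolerance = 1e-6)
  # ramp -2 -> +6 from the first frame: displacement 8, flagged undetectable
  cx <- -2 + 8 * stats::plogis((t - 75) / 10)
  pos2 <- positional_traits(make_rec(t, cbind(x = cx - 7, y = numeric(n)),
                                     cbind(x = cx + 7, y = numeric(n))))
  expect_equal(pos2$displacement, 8, tolerance = 0.1)
  cx3 <- seq(-2, 6, length.out = n)          # moving from the very start
  pos3 <- positional_traits(make_rec(t, cbind(x = cx3 - 7, y = numeric(n)),
                                     cbind(x = cx3 + 7, y = numeric(n))))
  expect_true("started_after_rotation" %in% pos3$flags)
})

test_that("oscillation extrema of a pure sine are counted exactly", {
  t <- seq(0, 200, 0.5)
  prof <- detect_oscillations(3 * sin(2 * pi * 0.04 * t), 0.5)
  expect_equal(sum(prof$kind == "peak"), 8L)
  expect_equal(sum(prof$kind == "valley"), 8L)
  expect_true(all(prof$kind[-1] != prof$kind[-nrow(prof)]))  # alternation
})

test_that("flat noisy series yield an empty profile below prominence", {
  set.seed(51)
  prof <- detect_oscillations(rnorm(400, 0, 0.05), 0.5, prominence = 0.5)
  expect_equal(nrow(prof), 0L)
  expect_equal(oscillation_traits(prof)[c("max_amplitude", "mean_amplitude",
                                          "frequency", "duration")],
               list(max_amplitude = 0, mean_amplitude = 0, frequency = 0,
                    duration = 0))
})

test_that("extrema counts survive tracking noise in >= 95% of runs", {
  t <- seq(0, 200, 0.5)
  clean <- 3 * sin(2 * pi * 0.04 * t)
  ok <- vapply(1:100, function(i) {
    set.seed(5200 + i)
    prof <- detect_oscillations(clean + rnorm(length(t), 0, 0.2), 0.5)
    nrow(prof) == 16L
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("sine oscillation traits: 6 um excursion at 40 mHz", {
  t <- seq(0, 200, 0.5)
  ot <- oscillation_traits(detect_oscillations(3 * sin(2 * pi * 0.04 * t), 0.5))
  expect_equal(ot$max_amplitude, 6, tolerance = 0.025)
  expect_equal(ot$mean_amplitude, 6, tolerance = 0.025)
  expect_equal(ot$frequency, 40, tolerance = 0.025)
  expect_equal(ot$frequency_rule, "mean_cycle_length")
})

test_that("oscillation traits are invariant to offset and reflection", {
  t <- seq(0, 200, 0.5)
  y <- 3 * sin(2 * pi * 0.04 * t)
  base <- oscillation_traits(detect_oscillations(y, 0.5))
  off <- oscillation_traits(detect_oscillations(y + 2.4, 0.5))
  refl <- oscillation_traits(detect_oscillations(-y, 0.5))
  for (f in c("max_amplitude", "mean_amplitude", "frequency", "duration")) {
    expect_equal(off[[f]], base[[f]])
    expect_equal(refl[[f]], base[[f]])
  }
})

test_that("asymmetry ratios reproduce the reported reference values", {
  t <- seq(0, 50, 0.5); n <- length(t)
  rec <- embryo_recording(t, cbind(x = rep(-7, n), y = numeric(n)),
                          cbind(x = rep(7, n), y = numeric(n)),
                          cell_length = 51.48, cell_width = 30,
                          ab_length = 29.0, p1_length = 22.48)
  osc_p <- list(max_amplitude = 6.32, mean_amplitude = 4)
  osc_a <- list(max_amplitude = 3.674, mean_amplitude = 2.5)
  asym <- asymmetry_traits(rec, osc_p, osc_a)
  expect_equal(asym$relative_asymmetry, 29.0 / 22.48, tolerance = 1e-9)
  expect_equal(round(asym$relative_asymmetry, 2), 1.29)
  expect_equal(round(asym$osc_asymmetry_max, 2), 1.72)
  zero_a <- asymmetry_traits(rec, osc_p, list(max_amplitude = 0,
                                              mean_amplitude = 0))
  expect_true(is.na(zero_a$osc_asymmetry_max))
  expect_match(zero_a$flags, "undefined")
})

test_that("noise-free rendered embryos round-trip every recoverable trait", {
  tt <- demo_true_traits(osc = TRUE)
  rec <- render_trajectory(tt, noise_free_config(), seed = 1)
  ex <- extract_all(rec)
  for (tr in trait_names()) {
    truth <- tt[[tr]]
    est <- ex$traits[[tr]]
    expect_true(abs(est - truth) <= max(0.05 * abs(truth), 0.25),
                label = sprintf("%s: est %.3f vs truth %.3f", tr, est, truth))
  }
})

test_that("recordings without transverse motion score zero oscillation traits", {
  tt <- demo_true_traits(osc = FALSE)
  rec <- render_trajectory(tt, noise_free_config(), seed = 2)
  ex <- extract_all(rec)
  osc_zero <- c("osc_max_amplitude_ant_um", "osc_max_amplitude_post_um",
                "osc_mean_amplitude_ant_um", "osc_mean_amplitude_post_um",
                "osc_frequency_ant_mhz", "osc_frequency_post_mhz",
                "osc_duration_s")
  expect_equal(unname(ex$traits[osc_zero]), rep(0, length(osc_zero)))
  expect_true(is.na(ex$traits[["osc_asymmetry_max"]]))
  expect_equal(ex$traits[["elongation_fold"]], tt[["elongation_fold"]],
               tolerance = 0.01)
})

test_that("duplicated frames do not change the extracted traits", {
  tt <- demo_true_traits(osc = TRUE)
  rec <- render_trajectory(tt, noise_free_config(), seed = 3)
  dup <- rec
  idx <- rep(seq_along(rec$time), each = 2)
  dup$time <- rec$time[idx]; dup$ant <- rec$ant[idx, ]; dup$post <- rec$post[idx, ]
  expect_equal(extract_all(dup)$traits, extract_all(rec)$traits)
})
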