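test_that("zero-rate evolution leaves every tip at the root state", {
  tr <- random_ultrametric_tree(10, seed = 61)
  x <- simulate_trait_evolution(tr, list(type = "BM", sigma2 = 0, root = 3.3),
                                seed = 62)
  expect_equal(unname(x), rep(3.3, 10))
})

test_that("BM tip variance on a star tree matches sigma2 * depth", {
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, 10)
  star$tip.label <- paste0("s", 1:10)
  tips <- vapply(1:1000, function(i) {
    simulate_trait_evolution(star, list(type = "BM", sigma2 = 2, root = 0),
                             seed = 6300 + i)
  }, numeric(10))
  expect_equal(stats::var(as.numeric(tips)), 2, tolerance = 0.05)
})

test_that("strong-attraction OU reaches its stationary distribution", {
  tr <- random_ultrametric_tree(12, depth = 1, seed = 64)
  alpha <- 30; s2 <- 4
  tips <- t(vapply(1:800, function(i) {
    simulate_trait_evolution(tr, list(type = "OU", alpha = alpha, sigma2 = s2,
                                      root = 1), seed = 6500 + i)
  }, numeric(12)))
  v <- apply(tips, 2L, stats::var)
  expect_equal(mean(v), s2 / (2 * alpha), tolerance = 0.1)
  cors <- stats::cor(tips)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.15)
})

test_that("simulated contrasts behave as i.i.d. Normal(0, sigma2)", {
  tr <- random_ultrametric_tree(30, depth = 1, seed = 66)
  cons <- unlist(lapply(1:30, function(i) {
    x <- simulate_trait_evolution(tr, list(type = "BM", sigma2 = 1.5, root = 0),
                                  seed = 6700 + i)
    pic_contrasts(tr, x)$contrast
  }))
  ks <- stats::ks.test(cons, "pnorm", 0, sqrt(1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("hierarchical sampling collapses when dispersions vanish", {
  cfg <- generator_config(n_species = 5L, strains_per_species = 2L,
                          embryos_per_strain = 2L, seed = 68)
  cfg$sigma_strain[] <- 0
  cfg$sigma_embryo[] <- 0
  tr <- random_ultrametric_tree(5, seed = 68)
  sp_traits <- data.frame(species = tr$tip.label)
  for (nm in cfg$base_traits) sp_traits[[nm]] <- cfg$trait_models[[nm]]$root
  gt <- sample_cohort(sp_traits, oscillating = tr$tip.label, cfg)
  for (tr_nm in setdiff(trait_names(), c("osc_asymmetry_max", "osc_asymmetry_mean"))) {
    expect_equal(gt$embryo[[tr_nm]],
                 rep(gt$species[[tr_nm]][1], nrow(gt$embryo)),
                 tolerance = 1e-12, label = tr_nm)
  }
})

test_that("strain-level dispersion matches the configured SD", {
  cfg <- generator_config(n_species = 40L, strains_per_species = 8L,
                          embryos_per_strain = 1L, seed = 69)
  tr <- random_ultrametric_tree(40, seed = 69)
  sp_traits <- data.frame(species = tr$tip.label)
  for (nm in cfg$base_traits) sp_traits[[nm]] <- cfg$trait_models[[nm]]$root
  gt <- sample_cohort(sp_traits, oscillating = tr$tip.label, cfg)
  dev <- gt$strain$cell_length_um - 50
  expect_equal(sd(dev), cfg$sigma_strain[["cell_length_um"]], tolerance = 0.15)
})

test_that("truncation keeps every sampled trait inside physical bounds", {
  cfg <- generator_config(n_species = 20L, strains_per_species = 5L,
                          embryos_per_strain = 5L, seed = 70)
  coh_gt <- sample_cohort({
    tr <- random_ultrametric_tree(20, seed = 70)
    sp <- data.frame(species = tr$tip.label)
    for (nm in cfg$base_traits) sp[[nm]] <- cfg$trait_models[[nm]]$root
    sp
  }, oscillating = paste0("s", 1:12), cfg)
  emb <- coh_gt$embryo
  expect_true(all(emb$cell_length_um > 0))
  expect_true(all(emb$initial_spindle_length_um > 0))
  expect_true(all(emb$division_plane_position_um > 0))
  expect_true(all(emb$elongation_fold >= 1))
  expect_true(all(emb$relative_asymmetry >= 1))
  expect_true(all(emb$osc_max_amplitude_post_um >= 0))
})

test_that("rendered centrosome transverse tracks are antiphase", {
  tt <- demo_true_traits(osc = TRUE)
  rec <- render_trajectory(tt, noise_free_config(), seed = 71)
  active <- abs(rec$post[, "y"]) > 0.2
  expect_lt(stats::cor(rec$ant[active, "y"], rec$post[active, "y"]), -0.9)
})

test_that("rendering refuses physically inconsistent traits", {
  tt <- demo_true_traits()
  tt[["final_spindle_length_um"]] <- tt[["cell_length_um"]] + 5
  expect_error(render_trajectory(tt, noise_free_config(), seed = 1),
               "smaller than cell length")
})

test_that("cohorts are byte-identical under the same master seed", {
  cfg <- generator_config(n_species = 6L, strains_per_species = 2L,
                          embryos_per_strain = 2L, seed = 73)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(c1$recordings[[5]], f1)
  write_trajectory_csv(c2$recordings[[5]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$ground_truth$embryo, c2$ground_truth$embryo)
})

test_that("disabling oscillations for a clade zeroes its extracted traits", {
  cfg <- generator_config(n_species = 8L, strains_per_species = 1L,
                          embryos_per_strain = 1L, seed = 74)
  coh <- generate_cohort(cfg)
  quiet <- setdiff(coh$tree$tip.label, coh$oscillating_species)
  expect_gt(length(quiet), 0L)
  tab <- extract_cohort(coh$recordings)
  for (sp in quiet) {
    rows <- tab[tab$species == sp, ]
    expect_equal(rows$osc_max_amplitude_post_um, rep(0, nrow(rows)))
    expect_equal(rows$osc_duration_s, rep(0, nrow(rows)))
  }
})
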