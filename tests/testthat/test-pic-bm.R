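test_that("contrasts on the worked three-tip tree match the hand recursion", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pc <- pic_contrasts(tr, c(A = 1, B = 3, C = 2))
  expect_equal(sort(abs(pc$contrast)), c(0, 2 / sqrt(2)), tolerance = 1e-12)
  # cherry variance 1+1; root contrast variance 2 + 1.5 (inflated branch)
  expect_setequal(pc$variance, c(2, 3.5))
  expect_true(all(pc$variance > 0))
  expect_equal(nrow(pc), ape::Ntip(tr) - 1L)
})

test_that("constant traits give all-zero contrasts", {
  set.seed(11)
  tr <- random_test_tree(12)
  pc <- pic_contrasts(tr, stats::setNames(rep(3.7, 12), tr$tip.label))
  expect_equal(pc$contrast, rep(0, 11))
})

test_that("contrasts agree with the ape implementation", {
  set.seed(12)
  for (i in 1:10) {
    tr <- random_test_tree(10)
    x <- random_tips(tr)
    ours <- sort(abs(pic_contrasts(tr, x)$contrast))
    theirs <- sort(abs(ape::pic(x[tr$tip.label], tr)))
    expect_equal(ours, unname(theirs), tolerance = 1e-10)
  }
})

test_that("PIC correlation equals dense GLS correlation on random trees", {
  set.seed(13)
  for (i in 1:50) {
    tr <- random_test_tree(8)
    x <- random_tips(tr); y <- random_tips(tr)
    expect_equal(pic_correlation(tr, x, y)$r, dense_gls_correlation(tr, x, y),
                 tolerance = 1e-8)
  }
})

test_that("two-tip BM log-likelihood matches the closed-form bivariate normal", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(bm_loglik(tr, c(A = 0, B = 2), sigma2 = 1, root_state = 1),
               -log(2 * pi) - 1, tolerance = 1e-9)
  expect_error(bm_loglik(tr, c(A = 0, B = 2), sigma2 = -1, root_state = 0),
               "sigma2")
})

test_that("likelihood is invariant to rescaling time and rate jointly", {
  set.seed(14)
  tr <- random_test_tree(10)
  x <- random_tips(tr)
  ll1 <- bm_loglik(tr, x, sigma2 = 1.3, root_state = 0.2)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 5
  expect_equal(bm_loglik(tr2, x, sigma2 = 1.3 / 5, root_state = 0.2), ll1,
               tolerance = 1e-10)
})

test_that("pruning log-likelihood equals the dense MVN oracle on 50 trees", {
  set.seed(15)
  for (i in 1:50) {
    tr <- random_test_tree(10)
    x <- random_tips(tr)
    s2 <- runif(1, 0.2, 3); z0 <- rnorm(1)
    expect_equal(bm_loglik(tr, x, s2, z0), dense_bm_loglik(tr, x, s2, z0),
                 tolerance = 1e-8)
  }
})

test_that("two-tip BM fit recovers the closed-form estimates", {
  fb <- fit_bm(parse_newick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(fb$root_state, 1)
  expect_equal(fb$sigma2, 1)
  expect_equal(fb$loglik, -log(2 * pi) - 1, tolerance = 1e-9)
  expect_equal(fb$method, "ML")
})

test_that("constant trait yields a flagged sigma2 = 0 boundary fit", {
  set.seed(16)
  tr <- random_test_tree(6)
  fb <- fit_bm(tr, stats::setNames(rep(2, 6), tr$tip.label))
  expect_equal(fb$sigma2, 0)
  expect_true(fb$boundary)
  expect_equal(fb$loglik, Inf)
})

test_that("BM rate is recovered in simulation and invariant to tip order", {
  tr <- random_ultrametric_tree(200, depth = 1, seed = 17)
  s2_hat <- vapply(1:100, function(i) {
    x <- simulate_trait_evolution(tr, list(type = "BM", sigma2 = 2, root = 0),
                                  seed = 1000 + i)
    fit_bm(tr, x)$sigma2
  }, numeric(1))
  expect_lt(abs(mean(s2_hat) - 2) / 2, 0.10)
  # permutation of the named vector must not change the estimate
  x <- simulate_trait_evolution(tr, list(type = "BM", sigma2 = 2, root = 0),
                                seed = 4242)
  expect_equal(fit_bm(tr, sample(x))$sigma2, fit_bm(tr, x)$sigma2)
})
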