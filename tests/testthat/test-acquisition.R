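test_that("improvement utility clamps at zero past the offset incumbent", {
  expect_equal(improvement_utility(5, 3, 0), 2)
  expect_equal(improvement_utility(2, 3, 0), 0)
  expect_equal(improvement_utility(5, 3, 3), 0)
  expect_equal(improvement_utility(c(5, 2, 4), 3, 0.5), c(1.5, 0, 0.5))
})

test_that("closed-form EI handles the degenerate sd and the analytic value", {
  expect_equal(expected_improvement(2, 0, 1, 0), 1)
  expect_equal(expected_improvement(0.5, 0, 1, 0), 0)
  # mu = incumbent, sd = 1: EI = dnorm(0) = 1/sqrt(2*pi)
  expect_equal(expected_improvement(1, 1, 1, 0), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_error(expected_improvement(1, -0.1, 0, 0), "negative")
})

test_that("closed-form EI equals Monte-Carlo integration of the utility", {
  cases <- expand.grid(mu = c(-0.5, 0.7), sd = c(0.3, 1.2),
                       inc = c(0, 0.5), delta = c(0, 0.2))
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    mc <- mc_expected_improvement(cc$mu, cc$sd, cc$inc, cc$delta,
                                  n = 2e5, seed = 100 + i)
    expect_lt(abs(expected_improvement(cc$mu, cc$sd, cc$inc, cc$delta) - mc),
              6e-3)
  }
})

test_that("EI is monotone in mean, anti-monotone in delta, with the sd->0 limit", {
  mus <- seq(-2, 2, by = 0.25)
  ei <- expected_improvement(mus, 0.7, 0.3, 0.1)
  expect_true(all(diff(ei) > 0))
  deltas <- seq(0, 2, by = 0.25)
  eid <- vapply(deltas, function(d) expected_improvement(0.8, 0.7, 0.3, d),
                numeric(1))
  expect_true(all(diff(eid) <= 1e-12))
  sds <- 10^seq(-1, -8, by = -1)
  lim <- vapply(sds, function(s) expected_improvement(1.4, s, 0.3, 0.1),
                numeric(1))
  expect_equal(lim[length(lim)], max(1.4 - 0.3 - 0.1, 0), tolerance = 1e-9)
})

test_that("rank-k incumbents are order statistics with multiplicity", {
  expect_equal(incumbent_for_rank(c(10, 50, 30, 20), 1), 50)
  expect_equal(incumbent_for_rank(c(10, 50, 30, 20), 2), 30)
  expect_equal(incumbent_for_rank(c(7, 7, 7), 3), 7)
  expect_error(incumbent_for_rank(c(1, 2), 3), "out of range")
})

test_that("E3I reduces to EI in the degenerate and single-sample cases", {
  dp <- degenerate_posterior(c(1, 3, 2))
  s <- e3i_score(dp, m = 20, seed = 8)
  expect_equal(s, rep(0, 3), tolerance = 1e-5)

  X <- matrix(c(0, 1, 2.5), ncol = 1)
  m <- gp_fit(X, c(5, 8, 6), lengthscale = 0.7, signal_var = 1,
              noise_var = 0.1)
  p <- gp_predict(m, matrix(c(0.5, 1.6, 3), ncol = 1), full_cov = TRUE)
  s1 <- e3i_score(p, m = 1, seed = 77)
  draw <- gp_sample(p, 1, seed = 77)
  expect_equal(s1, expected_improvement(p$mean, p$sd, max(draw), 0))
})

test_that("E3I matches a brute-force loop over the shared posterior samples", {
  X <- matrix(c(0, 1, 2.5), ncol = 1)
  m <- gp_fit(X, c(5, 8, 6), lengthscale = 0.7, signal_var = 1,
              noise_var = 0.1)
  p <- gp_predict(m, matrix(c(0.5, 1.6, 3), ncol = 1), full_cov = TRUE)
  n_s <- 1e4
  s <- e3i_score(p, m = n_s, seed = 5)
  draws <- gp_sample(p, n_s, seed = 5)
  brute <- rowMeans(vapply(seq_len(n_s), function(j) {
    xp <- max(draws[j, ])
    (p$mean - xp) * pnorm((p$mean - xp) / p$sd) +
      p$sd * dnorm((p$mean - xp) / p$sd)
  }, numeric(3)))
  expect_equal(s, brute, tolerance = 1e-9)
  expect_error(e3i_score(structure(list(mean = numeric(0)),
                                   class = "reactbo_posterior"), 5, 1),
               "empty")
})

test_that("E3I approaches plain EI as the posterior tightens", {
  X <- matrix(seq(0, 3, length.out = 6), ncol = 1)
  m <- gp_fit(X, c(2, 4, 9, 7, 3, 1), lengthscale = 0.6, signal_var = 1,
              noise_var = 1e-4)
  p <- gp_predict(m, matrix(seq(0.1, 2.9, length.out = 8), ncol = 1),
                  full_cov = TRUE)
  # shrink the posterior scale; E3I (large m) must converge to EI against
  # the posterior maximum, since every sample maximum collapses onto it
  err <- vapply(c(0.5, 0.1, 0.02), function(s) {
    ps <- p
    ps$sd <- s * p$sd
    ps$cov <- s^2 * p$cov
    ei <- expected_improvement(ps$mean, ps$sd, max(ps$mean), 0)
    max(abs(e3i_score(ps, m = 4096, seed = 3) - ei))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 2e-3) # residual is the finite-sample average noise
})

test_that("Thompson selection follows posterior maximum probabilities", {
  dp <- degenerate_posterior(c(1, 3, 2))
  picks <- vapply(1:20, function(s) thompson_select(dp, s), integer(1))
  expect_true(all(picks == 2L))

  # exchangeable two-candidate posterior: each picked about half the time
  X <- matrix(0, 1, 1)
  m <- gp_fit(X, 1, lengthscale = 1, signal_var = 1, noise_var = 0)
  p <- gp_predict(m, matrix(c(5, -5), ncol = 1), full_cov = TRUE)
  picks <- vapply(1:2000, function(s) thompson_select(p, s), integer(1))
  frac <- mean(picks == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("Thompson selection frequencies match probability-of-max", {
  # three nearly independent candidates (far apart under a short lengthscale)
  m <- gp_fit(matrix(100, 1, 1), 0, lengthscale = 0.5, signal_var = 1,
              noise_var = 0)
  p <- gp_predict(m, matrix(c(0, 30, 60), ncol = 1), full_cov = TRUE)
  p$mean <- c(0, 0.3, -0.2)
  n <- 3000
  picks <- vapply(seq_len(n), function(s) thompson_select(p, s), integer(1))
  prob_mc <- withr::with_seed(1, {
    draws <- matrix(rnorm(3 * 1e5, mean = rep(p$mean, each = 1e5),
                          sd = rep(p$sd, each = 1e5)), 1e5, 3)
    tabulate(apply(draws, 1, which.max), 3) / 1e5
  })
  for (j in 1:3) {
    se <- sqrt(prob_mc[j] * (1 - prob_mc[j]) / n)
    expect_lt(abs(mean(picks == j) - prob_mc[j]), 3 * se + 0.01)
  }
})

test_that("domain argmax respects exclusion, availability and tie-breaks", {
  expect_equal(argmax_over_domain(c(0.1, 0.9, 0.9)), 2L)
  expect_equal(argmax_over_domain(c(0.9, 0.1), exclude = 1L), 2L)
  expect_error(argmax_over_domain(c(1, 2), exclude = 1:2), "exhausted")
  withr::with_seed(8, {
    sc <- runif(100)
    ex <- sample(100, 20)
    best <- setdiff(order(sc, decreasing = TRUE), ex)[1]
    expect_equal(argmax_over_domain(sc, exclude = ex), best)
  })
  avail <- rep(c(TRUE, FALSE), 5)
  sc <- 1:10
  expect_equal(argmax_over_domain(sc, available = avail), 9L)
})

test_that("control scores are the advertised posterior statistics", {
  p <- structure(list(mean = c(1, 3, 2), sd = c(0.5, 0.1, 2)),
                 class = "reactbo_posterior")
  expect_equal(which.max(control_scores(p, "max_mean")), 2L)
  expect_equal(which.max(control_scores(p, "max_var")), 3L)
  expect_equal(control_scores(p, "mean_sd"), c(1.5, 3.1, 4))
  expect_error(control_scores(p, "nope"))
})

test_that("maximal-variance control prefers unexplored regions", {
  m <- gp_fit(matrix(c(0, 1), 2, 1), c(1, 2), lengthscale = 1,
              signal_var = 1)
  p <- gp_predict(m, matrix(c(0.5, 8), ncol = 1))
  expect_equal(which.max(control_scores(p, "max_var")), 2L)
})

test_that("random selection is seeded, exhaustive and calibrated", {
  pool <- 0:9
  sel <- random_select(pool, count = 10, seed = 3)
  expect_setequal(sel, pool)
  expect_identical(random_select(pool, count = 4, seed = 5),
                   random_select(pool, count = 4, seed = 5))
  expect_error(random_select(pool, exclude = 0:8, count = 2, seed = 1),
               "pool")
  # hypergeometric calibration: 50 of 100 contains a marked index half the time
  hits <- vapply(1:2000, function(s) {
    1L %in% random_select(1:100, count = 50, seed = s)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 2000))
})
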