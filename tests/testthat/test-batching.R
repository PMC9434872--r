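# shared toy problem: 10 candidates on a line, smooth objective
toy_setup <- function(n_obs = 4, seed = 2) {
  xs <- seq(0, 3, length.out = 10)
  f <- factor_def("x", paste0("x", 1:10), descriptors = matrix(xs, ncol = 1))
  space <- build_cartesian_space(list(f))
  y <- 50 + 20 * sin(2 * xs)
  obs <- withr::with_seed(seed, sample(10, n_obs))
  model <- gp_fit(space$encoding[obs, , drop = FALSE], y[obs],
                  lengthscale = 1, signal_var = 1, noise_var = 0.01)
  list(space = space, y = y, obs = obs, model = model)
}

test_that("a batch of one is exactly the sequential acquisition pick", {
  tt <- toy_setup()
  b <- kriging_believer_batch(tt$model, tt$space, acq_spec("ei"), q = 1,
                              observed_idx = tt$obs,
                              observed_values = tt$y[tt$obs])
  pool <- setdiff(1:10, tt$obs)
  p <- gp_predict(tt$model, tt$space$encoding[pool, , drop = FALSE])
  scores <- expected_improvement(p$mean, p$sd, max(tt$y[tt$obs]),
                                 0.01 * tt$model$y_sd)
  expect_equal(b$picks, pool[which.max(scores)])
})

test_that("the believer loop matches a hand-rolled condition-and-refit loop", {
  tt <- toy_setup()
  q <- 3
  b <- kriging_believer_batch(tt$model, tt$space, acq_spec("ei"), q = q,
                              observed_idx = tt$obs,
                              observed_values = tt$y[tt$obs])
  # manual loop through the surrogate module
  model <- tt$model
  obs_vals <- tt$y[tt$obs]
  taken <- tt$obs
  manual <- integer(0)
  for (j in 1:q) {
    pool <- setdiff(1:10, taken)
    p <- gp_predict(model, tt$space$encoding[pool, , drop = FALSE])
    sc <- expected_improvement(p$mean, p$sd,
                               incumbent_for_rank(obs_vals, 1),
                               0.01 * model$y_sd)
    pick <- pool[which.max(sc)]
    mu <- gp_predict(model, tt$space$encoding[pick, , drop = FALSE])$mean
    manual <- c(manual, pick)
    taken <- c(taken, pick)
    model <- gp_condition(model, tt$space$encoding[pick, , drop = FALSE], mu)
    obs_vals <- c(obs_vals, mu)
  }
  expect_equal(b$picks, manual)
})

test_that("believed values are predictive means and are not re-observed", {
  tt <- toy_setup()
  b <- kriging_believer_batch(tt$model, tt$space, acq_spec("ei"), q = 3,
                              observed_idx = tt$obs,
                              observed_values = tt$y[tt$obs])
  p1 <- gp_predict(tt$model,
                   tt$space$encoding[b$picks[1], , drop = FALSE])$mean
  expect_equal(b$believed[1], p1)
  expect_equal(anyDuplicated(b$picks), 0L)
  expect_true(all(!(b$picks %in% tt$obs)))
})

test_that("with a zero-variance posterior the believer picks top-q by mean", {
  # candidates whose encodings coincide with fully observed locations
  xs <- matrix(1:6, ncol = 1)
  means <- c(3, 9, 5, 7, 1, 8)
  model <- gp_fit(xs, means, lengthscale = 1, signal_var = 1, noise_var = 0,
                  jitter_rel = 1e-12)
  f <- factor_def("x", paste0("x", 1:6), descriptors = xs)
  space <- build_cartesian_space(list(f), standardize = FALSE)
  b <- kriging_believer_batch(model, space, acq_spec("max_mean"), q = 3,
                              observed_idx = integer(0),
                              observed_values = means)
  expect_equal(b$picks, order(means, decreasing = TRUE)[1:3])

  tb <- thompson_batch(model, space, q = 3, observed_idx = integer(0),
                       seed = 1)
  expect_equal(sort(tb$picks), sort(order(means, decreasing = TRUE)[1:3]))
})

test_that("domain exhaustion mid-batch names the picks already made", {
  tt <- toy_setup(n_obs = 8)
  expect_error(
    kriging_believer_batch(tt$model, tt$space, acq_spec("ei"), q = 3,
                           observed_idx = tt$obs,
                           observed_values = tt$y[tt$obs]),
    "domain exhausted")
  # the generic (joint-sampling) path reports the picks made so far
  expect_error(
    kriging_believer_batch(tt$model, tt$space, acq_spec("e3i"), q = 3,
                           observed_idx = tt$obs,
                           observed_values = tt$y[tt$obs], seed = 1),
    "picks")
})

test_that("thompson batches are seeded, distinct and model-consistent", {
  tt <- toy_setup()
  b1 <- thompson_batch(tt$model, tt$space, q = 3, observed_idx = tt$obs,
                       seed = 7)
  b2 <- thompson_batch(tt$model, tt$space, q = 3, observed_idx = tt$obs,
                       seed = 7)
  expect_identical(b1$picks, b2$picks)
  expect_equal(anyDuplicated(b1$picks), 0L)
  expect_true(all(!(b1$picks %in% tt$obs)))

  # q = 1 equals a single Thompson selection at the derived sub-seed
  pool <- setdiff(1:10, tt$obs)
  post <- gp_predict(tt$model, tt$space$encoding[pool, , drop = FALSE],
                     full_cov = TRUE)
  b <- thompson_batch(tt$model, tt$space, q = 1, observed_idx = tt$obs,
                      seed = 13)
  expect_equal(b$picks,
               pool[thompson_select(post, seed = derive_seed(13, 1, 0))])
})

test_that("random batches are uniform over unordered pairs", {
  f <- factor_def("x", paste0("x", 1:10),
                  descriptors = matrix(1:10, ncol = 1))
  space <- build_cartesian_space(list(f))
  b <- random_batch(space, q = 10, observed_idx = integer(0), seed = 1)
  expect_setequal(b$picks, 1:10)
  expect_error(random_batch(space, q = 11, observed_idx = integer(0),
                            seed = 1), "pool")

  n <- 1e4
  pairs <- vapply(seq_len(n), function(s) {
    paste(sort(random_batch(space, 2, integer(0), seed = s)$picks),
          collapse = "-")
  }, character(1))
  freq <- table(pairs) / n
  expect_equal(length(freq), 45L)
  se <- sqrt((1 / 45) * (44 / 45) / n)
  expect_true(all(abs(freq - 1 / 45) < 3.5 * se + 0.002))
})

test_that("all batch constructors stay inside the available unobserved pool", {
  withr::with_seed(99, {
    for (rep in 1:4) {
      surf <- generate_yield_surface(c(4, 4), noise_sd = 2,
                                     seed = sample(1e4, 1))
      space <- restrict_domain(surf$space, sort(sample(16, 12)))
      obs <- sample(which(space$available), 4)
      model <- gp_fit(space$encoding[obs, , drop = FALSE],
                      surf$objective$values[obs])
      pool <- setdiff(which(space$available), obs)
      for (b in list(
        kriging_believer_batch(model, space, acq_spec("ei"), 3, obs,
                               surf$objective$values[obs]),
        thompson_batch(model, space, 3, obs, seed = rep),
        random_batch(space, 3, obs, seed = rep))) {
        expect_equal(anyDuplicated(b$picks), 0L)
        expect_true(all(b$picks %in% pool))
      }
    }
  })
})
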