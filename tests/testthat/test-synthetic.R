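test_that("additive noiseless surfaces peak at the per-factor best levels", {
  surf <- generate_yield_surface(c(4, 4), interaction = 0, noise_sd = 0,
                                 informativeness = 1, seed = 11)
  v <- surf$objective$values
  best <- surf$space$candidates[surf$global_max_index, ]
  # marginal argmax per factor (mean objective over candidates at each level)
  for (f in 1:2) {
    marg <- tapply(v, surf$space$candidates[, f], mean)
    expect_equal(unname(best[f]), as.integer(which.max(marg)))
  }
})

test_that("surfaces regenerate bit-identically from (parameters, seed)", {
  a <- generate_yield_surface(c(3, 4, 5), interaction = 0.3, noise_sd = 4,
                              seed = 77)
  b <- generate_yield_surface(c(3, 4, 5), interaction = 0.3, noise_sd = 4,
                              seed = 77)
  expect_identical(a$objective$values, b$objective$values)
  expect_identical(a$space$encoding, b$space$encoding)
  c <- generate_yield_surface(c(3, 4, 5), interaction = 0.3, noise_sd = 4,
                              seed = 78)
  expect_false(identical(a$objective$values, c$objective$values))
})

test_that("surface values respect bounds and ground-truth bookkeeping", {
  withr::with_seed(3, {
    for (rep in 1:4) {
      surf <- generate_yield_surface(sample(2:6, 3, replace = TRUE),
                                     noise_sd = runif(1, 0, 10),
                                     seed = sample(1e5, 1))
      v <- surf$objective$values
      expect_true(all(v >= 0 & v <= 100))
      expect_equal(surf$global_max_index, which.max(v))
      expect_equal(v[surf$global_max_index] >= v[surf$second_max_index], TRUE)
      expect_equal(sort(v, decreasing = TRUE)[2], v[surf$second_max_index])
    }
  })
  expect_error(generate_yield_surface(c(1, 4)), "at least 2")
})

test_that("the coupling-style benchmark shapes are reproduced", {
  surf <- generate_yield_surface(c(6, 11, 6, 8), noise_sd = 0, seed = 1)
  expect_equal(surf$space$n_candidates, 3168L)
  dropped <- drop_combinations(surf, keep_pairs = 32L, seed = 5)
  expect_equal(length(dropped$allowed), 1536L)
  expect_equal(nrow(dropped$kept_pairs), 32L)
  # block arithmetic: each kept (f1, f2) pair spans all 6 x 8 = 48 downstream
  expect_equal(length(dropped$allowed), 32L * 48L)
  expect_equal(sum(!is.na(dropped$partial$values)), 1536L)
})

test_that("dropping combinations keeps the global optimum unless allowed", {
  surf <- generate_yield_surface(c(6, 11, 6, 8), noise_sd = 2, seed = 2)
  for (s in 1:5) {
    dropped <- drop_combinations(surf, keep_pairs = 10L, seed = s)
    expect_true(surf$global_max_index %in% dropped$allowed)
  }
  id <- drop_combinations(surf, keep_fraction = 1, seed = 1)
  expect_equal(length(id$allowed), 3168L)
  expect_equal(id$partial$values, surf$objective$values)
  expect_error(drop_combinations(surf, keep_pairs = 0L), "keep_pairs")
  expect_error(drop_combinations(surf, keep_fraction = 0), "keep_fraction|keep_pairs")
})

test_that("library surfaces follow their declared sparse linear model", {
  surf <- generate_library_surface(200, bits = 64, sparsity = 0.1,
                                   n_active = 8, n_epistatic = 3,
                                   noise_sd = 0, seed = 9)
  fp <- surf$space$factors[[1]]$descriptors
  co <- surf$coefficients
  manual <- as.numeric(fp[, co$active, drop = FALSE] %*% co$w)
  for (t in seq_len(nrow(co$epi))) {
    manual <- manual + co$epi[t, 3] * fp[, co$epi[t, 1]] * fp[, co$epi[t, 2]]
  }
  manual <- manual - min(manual) + 1
  expect_equal(surf$objective$values, unname(manual))
  expect_true(all(surf$objective$values > 0))

  # no epistasis, no noise: the argmax maximizes the linear score
  s2 <- generate_library_surface(150, bits = 64, sparsity = 0.1,
                                 n_active = 8, n_epistatic = 0,
                                 noise_sd = 0, seed = 10)
  fp2 <- s2$space$factors[[1]]$descriptors
  lin <- as.numeric(fp2[, s2$coefficients$active, drop = FALSE] %*%
                      s2$coefficients$w)
  expect_equal(s2$global_max_index, which.max(lin))
})

test_that("the library scales to 10000 x 512 fingerprints", {
  surf <- generate_library_surface(10000, bits = 512, seed = 3)
  expect_equal(dim(surf$space$factors[[1]]$descriptors), c(10000L, 512L))
  expect_equal(surf$space$n_candidates, 10000L)
  expect_equal(length(surf$objective$values), 10000L)
})

test_that("bottom-decile pools take the lowest tenth with boundary ties", {
  expect_equal(sort(bottom_decile_pool(20:1)), c(19L, 20L))
  expect_equal(length(bottom_decile_pool(rep(5, 12))), 12L)
  withr::with_seed(6, v <- runif(83))
  pool <- bottom_decile_pool(v)
  n_pool <- ceiling(83 / 10)
  expect_equal(sort(v[pool])[seq_len(n_pool)],
               sort(v)[seq_len(n_pool)])
  expect_true(all(v[pool] <= sort(v)[n_pool]))
})

test_that("ground truth is invariant to candidate reordering", {
  surf <- generate_yield_surface(c(4, 5), noise_sd = 3, seed = 15)
  v <- surf$objective$values
  perm <- withr::with_seed(2, sample(length(v)))
  ot <- objective_table(v[perm])
  expect_equal(v[perm][ot$global_max_index], v[surf$global_max_index])
})

test_that("packaged benchmarks have the documented structure", {
  s1 <- benchmark_surface("synth-suzuki")
  expect_equal(s1$space$n_candidates, 5760L)
  expect_equal(s1$params$shape, c(4L, 3L, 12L, 8L, 5L))
  expect_equal(s1$params$seed, 20220901L)
  s2 <- benchmark_surface("synth-pd")
  expect_equal(s2$space$n_candidates, 3168L)
  expect_equal(length(s2$allowed), 1536L)
  s3 <- benchmark_surface("synth-cep", n_molecules = 500)
  expect_equal(s3$space$n_candidates, 500L)
  expect_equal(ncol(s3$space$factors[[1]]$descriptors), 512L)
})

test_that("descriptor informativeness modulates the optimizer advantage", {
  cfg <- function(a) run_config(a, q = 5, rounds = 4)
  # perfect descriptors, no noise: EI clearly ahead of random at budget ~N/10
  s1 <- generate_yield_surface(c(6, 6, 6), interaction = 0, noise_sd = 0,
                               informativeness = 1, seed = 11)
  e1 <- replicate_runs(s1$space, s1$objective, cfg("ei"), n_runs = 20,
                       seed_base = 1)
  r1 <- replicate_runs(s1$space, s1$objective, cfg("random"), n_runs = 20,
                       seed_base = 1)
  expect_gt(e1$mean_best, r1$mean_best)

  # uninformative descriptors: statistically indistinguishable from random
  s0 <- generate_yield_surface(c(6, 6, 6), interaction = 0, noise_sd = 0,
                               informativeness = 0, seed = 11)
  e0 <- replicate_runs(s0$space, s0$objective, cfg("ei"), n_runs = 50,
                       seed_base = 1)
  r0 <- replicate_runs(s0$space, s0$objective, cfg("random"), n_runs = 50,
                       seed_base = 1)
  expect_gt(welch_t_test(e0$best, r0$best)$p, 0.05)
})
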