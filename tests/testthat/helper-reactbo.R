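# Shared fixtures, built in code.

# small two-factor space with hand-set descriptors
tiny_space <- function(prune = NULL) {
  fA <- factor_def("A", c("a1", "a2", "a3"),
                   descriptors = cbind(d1 = c(0, 1, 2), d2 = c(1, 0, -1)))
  fB <- factor_def("B", c("b1", "b2"),
                   descriptors = cbind(e1 = c(-1, 1)))
  build_cartesian_space(list(fA, fB), prune_threshold = prune)
}

# 1-D grid space over x in [0, 10] with the x*sin(x) objective
grid_space_1d <- function(n = 51L) {
  xs <- seq(0, 10, length.out = n)
  f <- factor_def("x", levels = sprintf("x%03d", seq_len(n)),
                  descriptors = matrix(xs, ncol = 1,
                                       dimnames = list(NULL, "x")))
  list(space = build_cartesian_space(list(f)), x = xs,
       objective = objective_table(xs * sin(xs)))
}

# independent dense GP posterior oracle: plain matrix algebra, no reuse of
# package internals beyond the kernel definition written out longhand
oracle_gp_posterior <- function(X, y, Xnew, lengthscale, signal_var,
                                noise_var = 0, jitter = 1e-6) {
  matk <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      r <- sqrt(sum((A[i, ] - B[j, ])^2)) / lengthscale
      K[i, j] <- signal_var * (1 + sqrt(5) * r + 5 * r^2 / 3) *
        exp(-sqrt(5) * r)
    }
    K
  }
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (is.na(sd_y) || sd_y == 0) sd_y <- 1
  yn <- (y - mu_y) / sd_y
  K <- matk(X, X) + diag(noise_var + jitter * signal_var, nrow(X))
  Ks <- matk(Xnew, X)
  Kss <- matk(Xnew, Xnew)
  Kinv <- solve(K)
  mu <- as.numeric(Ks %*% Kinv %*% yn)
  S <- Kss - Ks %*% Kinv %*% t(Ks)
  list(mean = mu_y + sd_y * mu,
       sd = sd_y * sqrt(pmax(diag(S), 0)),
       cov = sd_y^2 * S)
}

# a posterior with (near-)zero variance and chosen means: a GP conditioned
# on every candidate's encoding, then queried at those same encodings
degenerate_posterior <- function(means) {
  X <- matrix(seq_along(means), ncol = 1)
  m <- gp_fit(X, means, lengthscale = 1, signal_var = 1, noise_var = 0,
              jitter_rel = 1e-12)
  gp_predict(m, X, full_cov = TRUE)
}

# Monte-Carlo EI oracle by direct integration of the improvement utility
mc_expected_improvement <- function(mu, sd, incumbent, delta, n = 1e6,
                                    seed = 42) {
  draws <- withr::with_seed(seed, stats::rnorm(n, mu, sd))
  mean(improvement_utility(draws, incumbent, delta))
}
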