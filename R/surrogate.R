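# Gaussian-process surrogate over encoded candidates.
#
# Dense exact GP with a Matern-5/2 kernel, one shared length-scale, signal
# variance, and a fixed small jitter in place of learned noise: observations
# in the retrospective setting are exact table lookups, so the posterior must
# interpolate them (zero uncertainty at evaluated points). Targets are
# z-scored before fitting and predictions inverse-transformed.

# squared Euclidean cross-distances, clamped at zero against rounding
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

matern52_kernel <- function(d2, lengthscale, signal_var) {
  r <- sqrt(d2) / lengthscale
  s5r <- sqrt(5) * r
  signal_var * (1 + s5r + (5 / 3) * r^2) * exp(-s5r)
}

# negative log (unnormalized) posterior of the standardized targets; d2 is
# the precomputed squared-distance matrix; theta = (log ls, log sv, log
# noise). Weak log-normal priors on the length-scale and noise regularize
# the small-sample fits seen early in a run, where the bare marginal
# likelihood collapses to zero noise and a short length-scale.
gp_nll <- function(theta, d2, y, jitter_rel, prior = NULL) {
  ls <- exp(theta[1]); sv <- exp(theta[2]); nv <- exp(theta[3])
  n <- length(y)
  K <- matern52_kernel(d2, ls, sv)
  diag(K) <- diag(K) + nv + jitter_rel * sv
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) +
                      0.5 * n * log(2 * pi))
  if (!is.null(prior)) {
    nll <- nll + 0.5 * ((theta[1] - prior$ls_mean) / prior$ls_sd)^2 +
      0.5 * (theta[2] / prior$sv_sd)^2 +
      0.5 * ((theta[3] - prior$nv_mean) / prior$nv_sd)^2
  }
  nll
}

# analytic gradient of gp_nll w.r.t. (log ls, log sv, log noise); the jitter
# scales with the signal variance, so dK_y/dlog(sv) = K_f + jitter * sv * I
gp_nll_grad <- function(theta, d2, y, jitter_rel, prior = NULL) {
  ls <- exp(theta[1]); sv <- exp(theta[2]); nv <- exp(theta[3])
  n <- length(y)
  Kf <- matern52_kernel(d2, ls, sv)
  K <- Kf
  diag(K) <- diag(K) + nv + jitter_rel * sv
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(c(0, 0, 0))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha) # 0.5 tr(W dK) is the NLL derivative
  t_mat <- sqrt(5 * d2) / ls
  dK_dlogls <- sv * exp(-t_mat) * t_mat^2 * (1 + t_mat) / 3
  g <- c(0.5 * sum(W * dK_dlogls),
         0.5 * (sum(W * Kf) + jitter_rel * sv * sum(diag(W))),
         0.5 * nv * sum(diag(W)))
  if (!is.null(prior)) {
    g[1] <- g[1] + (theta[1] - prior$ls_mean) / prior$ls_sd^2
    g[2] <- g[2] + theta[2] / prior$sv_sd^2
    g[3] <- g[3] + (theta[3] - prior$nv_mean) / prior$nv_sd^2
  }
  g
}

#' Fit a Gaussian-process surrogate
#'
#' Fits an exact GP regression model with a Matern-5/2 kernel and a single
#' shared length-scale to the observed candidates. Hyperparameters
#' (length-scale, signal variance) maximize the log marginal likelihood from a
#' fixed set of deterministic multi-start initializations, so refitting the
#' same data reproduces the same fit. Targets are z-scored internally; a fixed
#' jitter (\code{jitter_rel} times the signal variance) stands in for
#' observation noise, keeping posterior uncertainty at observed points
#' negligible.
#'
#' @param X numeric matrix of encoded inputs, one row per observation.
#' @param y numeric vector of observed objective values.
#' @param noise noise model: \code{"learned"} (default) estimates a Gaussian
#'   noise variance alongside the kernel hyperparameters, so the surrogate
#'   need not interpolate irreducible scatter; \code{"fixed"} uses only the
#'   small jitter, forcing near-zero posterior uncertainty at observations
#'   (appropriate for exactly reproducible lookups).
#' @param lengthscale,signal_var,noise_var optional fixed hyperparameters (on
#'   the standardized-target scale); when \code{lengthscale} and
#'   \code{signal_var} are both supplied, marginal-likelihood optimization is
#'   skipped.
#' @param ls_prior_sd,sv_prior_sd,nv_prior weak log-normal regularization of
#'   the hyperparameter fit: sd of the log length-scale prior (centered on
#'   the median pairwise training distance), sd of the log signal-variance
#'   prior (centered on 1), and (mean, sd) of the log noise prior. Set a
#'   component to \code{NULL} (or a huge sd) for a flat prior.
#' @param fallback_lengthscale length-scale used while fewer than 3
#'   observations exist; sensibly, about half the median pairwise distance
#'   of the candidate set.
#' @param learn_signal_var also optimize the signal variance (outputscale).
#'   Off by default: targets are already standardized, and a freely learned
#'   outputscale tends to inflate extrapolative uncertainty on the small
#'   noisy designs seen early in a run.
#' @param jitter_rel jitter variance relative to the signal variance.
#' @param n_starts number of deterministic length-scale starts for the
#'   marginal-likelihood optimization.
#' @return An object of class \code{"reactbo_gp"}.
#' @export
gp_fit <- function(X, y, noise = c("learned", "fixed"), lengthscale = NULL,
                   signal_var = NULL, noise_var = NULL,
                   learn_signal_var = TRUE,
                   jitter_rel = 1e-6, n_starts = 5L,
                   ls_prior_sd = 0.75, sv_prior_sd = 0.75,
                   nv_prior = c(log(0.05), 1.5),
                   fallback_lengthscale = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  noise <- match.arg(noise)
  if (nrow(X) < 1L) stop("at least one observation is required")
  if (nrow(X) != length(y)) stop("row count of X must equal length of y")

  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (is.na(y_sd) || y_sd == 0) y_sd <- 1 # single or constant observations
  yn <- (y - y_mean) / y_sd

  if (is.null(noise_var)) noise_var <- if (noise == "fixed") 0 else NULL
  if (is.null(lengthscale) || is.null(signal_var)) {
    d2 <- cross_dist2(X, X)
    med <- stats::median(sqrt(d2[upper.tri(d2)]))
    if (!is.finite(med) || med == 0) {
      med <- if (!is.null(fallback_lengthscale)) 2 * fallback_lengthscale
             else sqrt(max(1, ncol(X)))
    }
    if (nrow(X) < 3L) {
      # too little data to estimate hyperparameters: fall back to a
      # domain-scale length-scale so uncertainty still grows with distance
      ls <- if (!is.null(fallback_lengthscale)) fallback_lengthscale
            else med / 2
      sv <- 1
      nv <- if (noise == "fixed") 0 else 1e-4
    } else {
      learn_noise <- is.null(noise_var)
      nv_fix <- if (learn_noise) NULL else max(noise_var, 1e-8)
      # deterministic multi-start grid over (lengthscale multiple, noise0)
      mults <- c(1, 0.25, 0.5, 2, 4)[seq_len(max(1L, n_starts))]
      noise0 <- c(0.05, 0.05, 0.2, 0.05, 0.2)[seq_len(max(1L, n_starts))]
      lower_nv <- if (learn_noise) log(1e-6) else log(nv_fix)
      upper_nv <- if (learn_noise) log(2) else log(nv_fix)
      # outputscale fixed at 1 on standardized targets unless asked for:
      # a freely learned signal variance inflates extrapolative uncertainty
      # on small noisy designs
      sv_bounds <- if (learn_signal_var) c(-6, 6) else c(0, 0)
      # weak log-normal MAP priors: length-scale centered on the median
      # pairwise distance, noise centered on 5% of the target variance
      prior <- list(ls_mean = log(med),
                    ls_sd = if (is.null(ls_prior_sd)) 1e6 else ls_prior_sd,
                    sv_sd = if (is.null(sv_prior_sd)) 1e6 else sv_prior_sd,
                    nv_mean = nv_prior[1], nv_sd = nv_prior[2])
      best <- NULL
      for (i in seq_along(mults)) {
        start_nv <- if (learn_noise) log(noise0[i]) else log(nv_fix)
        fit <- stats::optim(c(log(med * mults[i]), 0, start_nv),
                            gp_nll, gr = gp_nll_grad, d2 = d2, y = yn,
                            jitter_rel = jitter_rel, prior = prior,
                            method = "L-BFGS-B",
                            lower = c(log(med) - 6, sv_bounds[1], lower_nv),
                            upper = c(log(med) + 6, sv_bounds[2], upper_nv),
                            control = list(maxit = 100))
        if (is.null(best) || fit$value < best$value) best <- fit
      }
      ls <- exp(best$par[1]); sv <- exp(best$par[2])
      nv <- if (learn_noise) exp(best$par[3]) else noise_var
    }
  } else {
    ls <- lengthscale; sv <- signal_var
    nv <- if (is.null(noise_var)) 0 else noise_var
  }
  stopifnot(ls > 0, sv > 0, nv >= 0)

  model <- structure(list(X = X, y = y, y_mean = y_mean, y_sd = y_sd,
                          yn = yn, lengthscale = ls, signal_var = sv,
                          noise_var = nv, diag_noise = rep(nv, nrow(X)),
                          jitter_rel = jitter_rel),
                     class = "reactbo_gp")
  gp_factorize(model)
}

# cache the Cholesky factor and weight vector for the current training set
gp_factorize <- function(model) {
  K <- matern52_kernel(cross_dist2(model$X, model$X),
                       model$lengthscale, model$signal_var)
  diag(K) <- diag(K) + model$diag_noise + model$jitter_rel * model$signal_var
  L <- tryCatch(chol(K), error = function(e) {
    warning("ill-conditioned kernel matrix (duplicate inputs with ",
            "conflicting targets?); inflating jitter")
    diag(K) <- diag(K) + 1e-4 * model$signal_var
    chol(K)
  })
  model$L <- L
  model$alpha <- backsolve(L, forwardsolve(t(L), model$yn))
  model
}

#' @export
print.reactbo_gp <- function(x, ...) {
  cat("reactbo GP surrogate:", nrow(x$X), "observations,", ncol(x$X),
      "descriptor columns; Matern-5/2 lengthscale",
      format(x$lengthscale, digits = 4), ", signal variance",
      format(x$signal_var, digits = 4), ", noise variance",
      format(x$noise_var, digits = 4), "\n")
  invisible(x)
}

#' Condition a fitted GP on additional (possibly believed) observations
#'
#' Appends observations without re-optimizing kernel hyperparameters — the
#' Kriging-Believer loop conditions on fabricated predictive means, which must
#' not move the kernel estimates.
#'
#' @param model a fitted \code{reactbo_gp}.
#' @param X_add,y_add observations to append.
#' @param believed treat the appended values as known (no observation noise,
#'   only jitter), as the Kriging-Believer loop requires; \code{FALSE} gives
#'   them the model's learned noise variance.
#' @return The conditioned \code{reactbo_gp}.
#' @export
gp_condition <- function(model, X_add, y_add, believed = TRUE) {
  X_add <- matrix(X_add, ncol = ncol(model$X))
  model$X <- rbind(model$X, X_add)
  model$y <- c(model$y, y_add)
  model$yn <- (model$y - model$y_mean) / model$y_sd
  model$diag_noise <- c(model$diag_noise,
                        rep(if (believed) 0 else model$noise_var,
                            nrow(X_add)))
  gp_factorize(model)
}

#' Posterior predictive distribution at new candidates
#'
#' Exact GP posterior algebra: predictive mean and standard deviation per
#' candidate on the original objective scale, optionally with the full joint
#' posterior covariance (needed for Thompson sampling and E3I).
#'
#' @param model a fitted \code{reactbo_gp}.
#' @param Xnew numeric matrix of candidate encodings.
#' @param full_cov also return the joint posterior covariance matrix.
#' @return An object of class \code{"reactbo_posterior"}: list with
#'   \code{mean}, \code{sd}, and (if requested) \code{cov}, all on the
#'   objective scale.
#' @export
gp_predict <- function(model, Xnew, full_cov = FALSE) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(model$X)) {
    stop("candidate dimensionality (", ncol(Xnew),
         ") does not match the training inputs (", ncol(model$X), ")")
  }
  Ks <- matern52_kernel(cross_dist2(Xnew, model$X),
                        model$lengthscale, model$signal_var)
  mu_n <- as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$L), t(Ks))
  if (full_cov) {
    Kss <- matern52_kernel(cross_dist2(Xnew, Xnew),
                           model$lengthscale, model$signal_var)
    cov_n <- Kss - crossprod(V)
    cov_n <- (cov_n + t(cov_n)) / 2
    var_n <- pmax(diag(cov_n), 0)
  } else {
    cov_n <- NULL
    var_n <- pmax(model$signal_var - colSums(V^2), 0)
  }
  out <- list(mean = model$y_mean + model$y_sd * mu_n,
              sd = model$y_sd * sqrt(var_n))
  if (full_cov) out$cov <- model$y_sd^2 * cov_n
  structure(out, class = "reactbo_posterior")
}

#' @export
print.reactbo_posterior <- function(x, ...) {
  cat("reactbo GP posterior over", length(x$mean), "candidates",
      if (!is.null(x$cov)) "(joint covariance attached)", "\n")
  invisible(x)
}

#' Draw joint samples from a GP posterior
#'
#' Samples from the joint multivariate normal posterior (full covariance, not
#' independent marginals) with a supplied seed; the same seed always yields
#' the same draws.
#'
#' @param posterior a \code{reactbo_posterior} carrying \code{cov} (from
#'   \code{gp_predict(..., full_cov = TRUE)}).
#' @param n_samples number of joint draws.
#' @param seed integer seed.
#' @return numeric matrix, \code{n_samples} rows by candidates columns.
#' @export
gp_sample <- function(posterior, n_samples, seed) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  if (is.null(posterior$cov)) {
    stop("joint sampling requires a posterior with full covariance")
  }
  S <- posterior$cov
  m <- length(posterior$mean)
  eps <- 1e-10 * max(diag(S), 1e-30)
  L <- NULL
  for (i in 1:6) {
    L <- tryCatch(chol(S + diag(eps, m)), error = function(e) NULL)
    if (!is.null(L)) break
    eps <- eps * 100
  }
  if (is.null(L)) stop("posterior covariance is not factorizable")
  Z <- with_seed(seed, matrix(stats::rnorm(n_samples * m), n_samples, m))
  sweep(Z %*% L, 2, posterior$mean, "+")
}
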