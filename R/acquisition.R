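# Acquisition functions over a finite candidate set.
#
# All acquisitions are maximized by scoring every available, unobserved
# candidate and taking the argmax (the domain is a finite table, so no
# continuous optimization is involved). Ties break to the lowest candidate
# index for seeded reproducibility.

ACQ_NAMES <- c("ei", "ei_k", "e3i", "ts", "max_mean", "max_var", "mean_sd",
               "random")

#' Specify an acquisition function and its parameters
#'
#' @param name one of \code{"ei"}, \code{"ei_k"}, \code{"e3i"}, \code{"ts"},
#'   \code{"max_mean"}, \code{"max_var"}, \code{"mean_sd"}, \code{"random"}.
#' @param delta exploration offset subtracted from the improvement before
#'   scoring, in standardized-target units (EI family). Discourages chasing
#'   tiny incremental gains near an incumbent.
#' @param k incumbent rank for EI-k; \code{k = 1} is plain EI.
#' @param e3i_samples number of joint posterior samples E3I averages over.
#' @return An object of class \code{"reactbo_acq"}.
#' @export
acq_spec <- function(name = "ei", delta = 0.01, k = 1L, e3i_samples = 64L) {
  name <- match.arg(tolower(name), ACQ_NAMES)
  stopifnot(delta >= 0, k >= 1, e3i_samples >= 1)
  structure(list(name = name, delta = delta, k = as.integer(k),
                 e3i_samples = as.integer(e3i_samples)),
            class = "reactbo_acq")
}

#' @export
print.reactbo_acq <- function(x, ...) {
  cat("reactbo acquisition:", x$name,
      if (x$name %in% c("ei", "ei_k")) paste0("(delta = ", x$delta,
                                              ", k = ", x$k, ")"),
      if (x$name == "e3i") paste0("(m = ", x$e3i_samples, ")"), "\n")
  invisible(x)
}

#' Improvement utility
#'
#' The improvement of a value over the incumbent, reduced by the exploration
#' offset and clamped at zero: \code{max(value - incumbent - delta, 0)}.
#'
#' @param value objective value(s).
#' @param incumbent incumbent objective value.
#' @param delta exploration offset (same units as the objective).
#' @return Non-negative improvement, vectorized over \code{value}.
#' @export
improvement_utility <- function(value, incumbent, delta = 0) {
  pmax(value - incumbent - delta, 0)
}

#' Closed-form Expected Improvement
#'
#' Expectation of \code{\link{improvement_utility}} under a Normal(mu, sd^2)
#' posterior: with \code{z = (mu - incumbent - delta) / sd},
#' \code{EI = (mu - incumbent - delta) * pnorm(z) + sd * dnorm(z)}; at
#' \code{sd = 0} it degenerates to the plain clamped improvement.
#'
#' @param mu posterior predictive mean(s).
#' @param sd posterior predictive standard deviation(s), non-negative.
#' @param incumbent incumbent objective value.
#' @param delta exploration offset.
#' @return Non-negative EI score, vectorized.
#' @export
expected_improvement <- function(mu, sd, incumbent, delta = 0) {
  if (any(sd < 0)) stop("negative posterior standard deviation")
  diff <- mu - incumbent - delta
  out <- pmax(diff, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- diff[pos] / sd[pos]
    out[pos] <- diff[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Incumbent value for a given rank
#'
#' The kth highest observed objective value, counting duplicates with
#' multiplicity; rank 1 gives the ordinary EI incumbent.
#'
#' @param observations observed objective values.
#' @param k rank, \code{1 <= k <= length(observations)}.
#' @return The kth largest observed value.
#' @export
incumbent_for_rank <- function(observations, k = 1L) {
  n <- length(observations)
  if (k < 1 || k > n) {
    stop("incumbent rank k = ", k, " out of range for ", n, " observations")
  }
  sort(observations, decreasing = TRUE)[k]
}

#' Exploration-enhanced Expected Improvement (E3I) scores
#'
#' Draws \code{m} joint posterior samples over the candidates; for each
#' sample, scores every candidate by EI with the incumbent set to that
#' sample's maximum (delta = 0), then averages the per-candidate scores over
#' the samples. With a tight posterior and many samples this approaches plain
#' EI against the posterior maximum.
#'
#' @param posterior a \code{reactbo_posterior} with full covariance over the
#'   scored candidates.
#' @param m number of joint posterior samples.
#' @param seed integer seed for the sample draws.
#' @return Numeric score per candidate.
#' @export
e3i_score <- function(posterior, m, seed) {
  if (length(posterior$mean) == 0) stop("empty candidate set")
  stopifnot(m >= 1)
  draws <- gp_sample(posterior, n_samples = m, seed = seed)
  incumbents <- apply(draws, 1, max)
  scores <- numeric(length(posterior$mean))
  for (j in seq_len(m)) {
    scores <- scores + expected_improvement(posterior$mean, posterior$sd,
                                            incumbents[j], delta = 0)
  }
  scores / m
}

#' Thompson sampling selection
#'
#' Draws one joint posterior sample over the candidates and returns the index
#' of its maximum (ties to the lowest index).
#'
#' @param posterior a \code{reactbo_posterior} with full covariance.
#' @param seed integer seed.
#' @return Index into the scored candidate set.
#' @export
thompson_select <- function(posterior, seed) {
  if (length(posterior$mean) < 1) stop("empty candidate set")
  if (all(posterior$sd == 0)) {
    return(which.max(posterior$mean))
  }
  draw <- gp_sample(posterior, n_samples = 1L, seed = seed)
  which.max(draw[1, ])
}

#' Argmax over the available, unexcluded domain
#'
#' @param scores numeric score per candidate.
#' @param exclude candidate indices to exclude (already observed).
#' @param available optional logical availability mask.
#' @return Index of the highest-scoring unexcluded available candidate, ties
#'   broken by lowest index.
#' @export
argmax_over_domain <- function(scores, exclude = integer(0),
                               available = NULL) {
  ok <- rep(TRUE, length(scores))
  if (!is.null(available)) ok <- ok & available
  ok[exclude] <- FALSE
  if (!any(ok)) stop("domain exhausted: no unexcluded available candidate")
  idx <- which(ok)
  idx[which.max(scores[idx])]
}

#' Simple posterior-statistic control scores
#'
#' The three baseline selection rules: maximal predictive mean, maximal
#' predictive uncertainty, or their sum.
#'
#' @param posterior a \code{reactbo_posterior}.
#' @param mode \code{"max_mean"}, \code{"max_var"}, or \code{"mean_sd"}.
#' @return Numeric score per candidate.
#' @export
control_scores <- function(posterior, mode) {
  switch(match.arg(mode, c("max_mean", "max_var", "mean_sd")),
         max_mean = posterior$mean,
         max_var = posterior$sd,
         mean_sd = posterior$mean + posterior$sd)
}

#' Seeded uniform random selection without replacement
#'
#' @param available candidate index pool.
#' @param exclude indices to remove from the pool first.
#' @param count number of picks.
#' @param seed integer seed.
#' @return Integer vector of \code{count} distinct indices.
#' @export
random_select <- function(available, exclude = integer(0), count, seed) {
  pool <- setdiff(available, exclude)
  if (count > length(pool)) {
    stop("requested ", count, " picks from a pool of ", length(pool))
  }
  with_seed(seed, pool[sample.int(length(pool), count)])
}
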