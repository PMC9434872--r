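# Batch construction: q points per round.
#
# Deterministic acquisitions (EI family, controls) use the Kriging-Believer
# loop: pick, believe the predictive mean, condition, repeat. Thompson
# sampling draws q joint posterior samples in parallel with no model updates.
# Random ignores the model. Believed observations never move kernel
# hyperparameters and are discarded once the batch is assembled.

# Candidate pool (indices into the space) an acquisition may score: available
# and unobserved. For joint-sampling acquisitions the pool may be subsampled
# (seeded) to keep the posterior covariance factorizable at scale.
candidate_pool <- function(space, observed_idx, max_pool = NULL, seed = NULL) {
  pool <- setdiff(which(space$available), observed_idx)
  if (length(pool) == 0) stop("domain exhausted: no unobserved candidates")
  if (!is.null(max_pool) && length(pool) > max_pool) {
    pool <- sort(with_seed(seed, pool[sample.int(length(pool), max_pool)]))
  }
  pool
}

# EI-family / control scores for a pool, given the fitted model and the true
# observed values (incumbent and delta live on the standardized-target scale).
score_pool <- function(model, space, spec, pool, observed_values, seed) {
  post_needed <- spec$name %in% c("e3i")
  posterior <- gp_predict(model, space$encoding[pool, , drop = FALSE],
                          full_cov = post_needed)
  delta_obj <- spec$delta * model$y_sd # delta is on the normalized scale
  switch(spec$name,
    ei = ,
    ei_k = {
      incumbent <- incumbent_for_rank(observed_values, spec$k)
      expected_improvement(posterior$mean, posterior$sd, incumbent, delta_obj)
    },
    e3i = e3i_score(posterior, m = spec$e3i_samples, seed = seed),
    max_mean = ,
    max_var = ,
    mean_sd = control_scores(posterior, spec$name),
    stop("acquisition '", spec$name, "' is not scored via score_pool"))
}

#' Kriging-Believer batch selection
#'
#' Builds a batch of size \code{q} for a deterministic acquisition:
#' iteratively maximize the acquisition over the unobserved pool, record the
#' pick, append (pick, predictive mean) to the model as a believed
#' observation with hyperparameters frozen, and repeat.
#'
#' @param model fitted \code{reactbo_gp} on the true observations.
#' @param space a \code{reactbo_space}.
#' @param spec an \code{\link{acq_spec}} (EI family or a control).
#' @param q batch size.
#' @param observed_idx candidate indices already truly observed.
#' @param observed_values their objective values (incumbent source).
#' @param seed integer seed (consumed only by E3I's sample draws).
#' @param max_pool optional cap on the candidate pool scored by
#'   joint-sampling acquisitions.
#' @return An object of class \code{"reactbo_batch"}: list with \code{picks}
#'   (ordered candidate indices) and \code{believed} (the provisional means
#'   used during construction).
#' @export
kriging_believer_batch <- function(model, space, spec, q, observed_idx,
                                   observed_values, seed = 1L,
                                   max_pool = NULL) {
  stopifnot(q >= 1)
  if (spec$name %in% c("ei", "ei_k", "max_mean", "max_var", "mean_sd")) {
    # marginal acquisitions admit incremental conditioning: the believed
    # point extends the Cholesky factor and cross-kernel by one column
    return(kb_marginal_batch(model, space, spec, q, observed_idx,
                             observed_values))
  }
  picks <- integer(0)
  believed <- numeric(0)
  obs_vals <- observed_values
  for (j in seq_len(q)) {
    pool <- tryCatch(
      candidate_pool(space, c(observed_idx, picks),
                     max_pool = if (spec$name == "e3i") max_pool else NULL,
                     seed = if (!is.null(seed)) derive_seed(seed, 101L, j)),
      error = function(e) {
        stop("domain exhausted after picks [",
             paste(picks, collapse = ", "), "]: ", conditionMessage(e),
             call. = FALSE)
      })
    scores <- score_pool(model, space, spec, pool, obs_vals,
                         seed = derive_seed(seed, 7L, j))
    pick <- pool[argmax_over_domain(scores)]
    mu_pick <- gp_predict(model,
                          space$encoding[pick, , drop = FALSE])$mean
    picks <- c(picks, pick)
    believed <- c(believed, mu_pick)
    if (j < q) {
      model <- gp_condition(model, space$encoding[pick, , drop = FALSE],
                            mu_pick)
      obs_vals <- c(obs_vals, mu_pick)
    }
  }
  structure(list(picks = picks, believed = believed, strategy = "kriging_believer"),
            class = "reactbo_batch")
}

# Incremental Kriging-Believer loop for acquisitions that only need marginal
# posterior mean/sd. Equivalent to refitting with frozen hyperparameters
# after each believed observation, but the Cholesky factor, the pool
# cross-kernel solve and the predictive variance are extended one rank at a
# time instead of recomputed.
kb_marginal_batch <- function(model, space, spec, q, observed_idx,
                              observed_values) {
  pool <- candidate_pool(space, observed_idx)
  if (length(pool) < q) {
    stop("domain exhausted: pool of ", length(pool),
         " smaller than batch size ", q)
  }
  E_pool <- space$encoding[pool, , drop = FALSE]
  m <- length(pool)
  ls <- model$lengthscale; sv <- model$signal_var
  U <- model$L                              # upper Cholesky: K = U'U
  yn <- model$yn
  Ks <- matern52_kernel(cross_dist2(E_pool, model$X), ls, sv) # m x n
  V <- forwardsolve(t(U), t(Ks))            # n x m
  var_n <- pmax(sv - colSums(V^2), 0)
  obs_vals <- observed_values
  delta_obj <- spec$delta * model$y_sd

  picks <- integer(0)
  pick_pos <- integer(0)
  believed <- numeric(0)
  for (j in seq_len(q)) {
    beta <- forwardsolve(t(U), yn) # mu = Ks K^-1 y = V' (U')^-1 y
    mu <- model$y_mean + model$y_sd * as.numeric(crossprod(V, beta))
    sd_n <- model$y_sd * sqrt(var_n)
    scores <- switch(spec$name,
      ei = ,
      ei_k = expected_improvement(mu, sd_n,
                                  incumbent_for_rank(obs_vals, spec$k),
                                  delta_obj),
      max_mean = mu,
      max_var = sd_n,
      mean_sd = mu + sd_n)
    if (length(pick_pos)) scores[pick_pos] <- -Inf
    pos <- which.max(scores)
    picks <- c(picks, pool[pos])
    pick_pos <- c(pick_pos, pos)
    believed <- c(believed, mu[pos])
    if (j == q) break

    # extend the factorization with the believed observation
    k_new <- matern52_kernel(cross_dist2(E_pool[pos, , drop = FALSE],
                                         E_pool), ls, sv)[1, ]
    u <- V[, pos]
    s2 <- max(var_n[pos], 0) + model$jitter_rel * sv # believed: no obs noise
    s <- sqrt(s2)
    U <- cbind(rbind(U, 0), c(u, s))
    v_row <- (k_new - as.numeric(crossprod(u, V))) / s
    V <- rbind(V, v_row)
    var_n <- pmax(var_n - v_row^2, 0)
    yn <- c(yn, (believed[j] - model$y_mean) / model$y_sd)
    obs_vals <- c(obs_vals, believed[j])
  }
  structure(list(picks = picks, believed = believed,
                 strategy = "kriging_believer"),
            class = "reactbo_batch")
}

#' Parallel Thompson-sampling batch selection
#'
#' Draws \code{q} joint posterior samples (sub-seeds derived per pick) over
#' the unobserved pool; pick j is the argmax of sample j. No model refits
#' between picks. A pick duplicating an earlier one is redrawn with a fresh
#' sub-seed up to 10 times, then falls back to the best not-yet-picked
#' candidate in that sample.
#'
#' @param model fitted \code{reactbo_gp}.
#' @param space a \code{reactbo_space}.
#' @param q batch size.
#' @param observed_idx candidate indices already observed.
#' @param seed integer seed.
#' @param max_pool optional seeded cap on the jointly sampled pool.
#' @return A \code{reactbo_batch}.
#' @export
thompson_batch <- function(model, space, q, observed_idx, seed,
                           max_pool = NULL) {
  stopifnot(q >= 1)
  pool <- candidate_pool(space, observed_idx, max_pool = max_pool,
                         seed = derive_seed(seed, 101L, 0L))
  if (length(pool) < q) stop("domain exhausted: pool smaller than batch size")
  posterior <- gp_predict(model, space$encoding[pool, , drop = FALSE],
                          full_cov = TRUE)
  picks <- integer(0)
  for (j in seq_len(q)) {
    pick <- NA_integer_
    for (attempt in 0:10) {
      cand <- pool[thompson_select(posterior,
                                   seed = derive_seed(seed, j, attempt))]
      if (!(cand %in% picks)) { pick <- cand; break }
    }
    if (is.na(pick)) {
      # fall back to the best unpicked candidate of the last sample drawn
      draw <- gp_sample(posterior, 1L, seed = derive_seed(seed, j, 11L))[1, ]
      open <- which(!(pool %in% picks))
      pick <- pool[open[which.max(draw[open])]]
    }
    picks <- c(picks, pick)
  }
  structure(list(picks = picks, believed = rep(NA_real_, q),
                 strategy = "thompson"),
            class = "reactbo_batch")
}

#' Random batch selection
#'
#' Seeded uniform sample without replacement among available unobserved
#' candidates; the model-free control.
#'
#' @param space a \code{reactbo_space}.
#' @param q batch size.
#' @param observed_idx candidate indices already observed.
#' @param seed integer seed.
#' @return A \code{reactbo_batch}.
#' @export
random_batch <- function(space, q, observed_idx, seed) {
  stopifnot(q >= 1)
  pool <- candidate_pool(space, observed_idx)
  if (length(pool) < q) {
    stop("requested batch of ", q, " from a pool of ", length(pool))
  }
  picks <- random_select(pool, count = q, seed = seed)
  structure(list(picks = picks, believed = rep(NA_real_, q),
                 strategy = "random"),
            class = "reactbo_batch")
}

#' @export
print.reactbo_batch <- function(x, ...) {
  cat("reactbo batch (", x$strategy, "): ",
      paste(x$picks, collapse = ", "), "\n", sep = "")
  invisible(x)
}
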