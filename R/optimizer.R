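# Run orchestration: seeded initialization, rounds of propose - evaluate -
# update until the experiment budget, and top-n reporting.
#
# The budget counts every objective evaluation including the initial batch:
# a run with batch size q and R rounds performs exactly q * R evaluations,
# the first round being the random initialization.

#' Configure an optimization run
#'
#' @param acq an \code{\link{acq_spec}} or an acquisition name.
#' @param q batch size (evaluations per round).
#' @param budget total number of objective evaluations, including the initial
#'   batch; must equal \code{q * rounds}. Give either \code{budget} or
#'   \code{rounds} (or both, consistently).
#' @param rounds total number of rounds including initialization.
#' @param init initialization mode: \code{"uniform"} draws the first batch
#'   uniformly from the available candidates; \code{"bottom_decile"} draws it
#'   only from the lowest 10\% of candidates by objective value.
#' @param top_n how many top observations to report (typically 1 or 5).
#' @param seed master seed; every random stream in the run derives from it.
#' @param max_joint cap on the candidate pool jointly sampled by TS/E3I
#'   (exact joint sampling within a seeded subset); \code{NULL} for no cap.
#' @param allow_repeats permit re-evaluating observed candidates (off by
#'   default: a repeat wastes budget in the noiseless setting).
#' @param delta,k,e3i_samples convenience passthroughs to
#'   \code{\link{acq_spec}} when \code{acq} is a name.
#' @param gp_args named list of extra arguments for the per-round
#'   \code{\link{gp_fit}} calls (noise model, priors, ...).
#' @return An object of class \code{"reactbo_config"}.
#' @export
run_config <- function(acq = "ei", q = 5L, budget = NULL, rounds = NULL,
                       init = c("uniform", "bottom_decile"), top_n = 5L,
                       seed = 1L, max_joint = 1000L, allow_repeats = FALSE,
                       delta = 0.01, k = 1L, e3i_samples = 64L,
                       gp_args = list()) {
  if (!inherits(acq, "reactbo_acq")) {
    acq <- acq_spec(acq, delta = delta, k = k, e3i_samples = e3i_samples)
  }
  init <- match.arg(init)
  q <- as.integer(q)
  stopifnot(q >= 1, top_n >= 1)
  if (is.null(budget) && is.null(rounds)) {
    stop("give an experiment budget or a number of rounds")
  }
  if (is.null(rounds)) {
    if (budget %% q != 0) {
      stop("budget ", budget, " is not a multiple of the batch size ", q,
           "; give rounds explicitly")
    }
    rounds <- budget %/% q
  }
  rounds <- as.integer(rounds)
  if (is.null(budget)) budget <- q * rounds
  if (budget != q * rounds) {
    stop("inconsistent budget: ", budget, " != q * rounds = ", q * rounds)
  }
  stopifnot(rounds >= 1)
  structure(list(acq = acq, q = q, budget = as.integer(budget),
                 rounds = rounds, init = init, top_n = as.integer(top_n),
                 seed = as.integer(seed), max_joint = max_joint,
                 allow_repeats = isTRUE(allow_repeats), gp_args = gp_args),
            class = "reactbo_config")
}

#' @export
print.reactbo_config <- function(x, ...) {
  cat("reactbo run config:", x$acq$name, "| q =", x$q, "| rounds =",
      x$rounds, "| budget =", x$budget, "| init =", x$init, "| seed =",
      x$seed, "\n")
  invisible(x)
}

#' Initial batch of observations
#'
#' Draws the seeded first batch: uniform over available candidates, or
#' restricted to the bottom decile of the objective (the ceil(N/10) lowest
#' values, boundary ties included).
#'
#' @param space a \code{reactbo_space}.
#' @param objective a \code{reactbo_objective}.
#' @param config a \code{reactbo_config}.
#' @return Integer vector of \code{q} candidate indices.
#' @export
bo_initialize <- function(space, objective, config) {
  avail <- which(space$available)
  pool <- if (config$init == "bottom_decile") {
    intersect(avail, bottom_decile_pool(objective, available = space$available))
  } else {
    avail
  }
  if (length(pool) < config$q) {
    stop("initialization pool (", length(pool),
         ") smaller than the batch size (", config$q, ")")
  }
  random_select(pool, count = config$q, seed = derive_seed(config$seed, 0L))
}

#' Run a full batched Bayesian-optimization campaign
#'
#' Initializes with a seeded random batch, then repeats propose-batch /
#' look-up-true-values / refit for the remaining rounds. In simulation mode
#' the objective is an exact, noiseless table lookup. The run is
#' deterministic given (space, objective, config).
#'
#' @param space a \code{reactbo_space}.
#' @param objective a \code{reactbo_objective} (values for every available
#'   candidate).
#' @param config a \code{reactbo_config}.
#' @return An object of class \code{"reactbo_trace"}: data frame with columns
#'   \code{round}, \code{pick}, one column per factor, \code{objective} and
#'   \code{best_so_far}, plus attributes \code{config} and \code{top}.
#' @export
bo_run <- function(space, objective, config) {
  stopifnot(inherits(space, "reactbo_space"),
            inherits(objective, "reactbo_objective"),
            inherits(config, "reactbo_config"))
  values <- objective$values
  if (anyNA(values[space$available])) {
    stop("objective undefined for some available candidates")
  }
  if (is.null(config$gp_args$fallback_lengthscale)) {
    config$gp_args$fallback_lengthscale <- domain_scale(space) / 2
  }
  observed_idx <- bo_initialize(space, objective, config)
  observed_val <- values[observed_idx]
  rounds <- rep(1L, config$q)

  for (r in seq_len(config$rounds - 1L) + 1L) {
    batch <- propose_round(space, config, observed_idx, observed_val,
                           round = r)
    observed_idx <- c(observed_idx, batch$picks)
    observed_val <- c(observed_val, values[batch$picks])
    rounds <- c(rounds, rep(r, length(batch$picks)))
  }

  trace <- data.frame(round = rounds, pick = observed_idx,
                      candidate_labels(space, observed_idx),
                      objective = observed_val,
                      best_so_far = cummax(observed_val),
                      stringsAsFactors = FALSE)
  attr(trace, "config") <- config
  attr(trace, "top") <- top_n(trace, config$top_n)
  class(trace) <- c("reactbo_trace", "data.frame")
  trace
}

# median pairwise encoded distance of the available candidates, from a
# deterministic (seed-free) evenly spaced subsample
domain_scale <- function(space, max_points = 300L) {
  enc <- space$encoding[space$available, , drop = FALSE]
  if (nrow(enc) < 2L) return(sqrt(max(1, ncol(enc))))
  idx <- unique(round(seq(1, nrow(enc), length.out = min(max_points,
                                                         nrow(enc)))))
  d2 <- cross_dist2(enc[idx, , drop = FALSE], enc[idx, , drop = FALSE])
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med == 0) sqrt(max(1, ncol(enc))) else med
}

# one proposal round: fit the surrogate on the true observations, then build
# the batch with the strategy implied by the acquisition
propose_round <- function(space, config, observed_idx, observed_val, round) {
  acq <- config$acq
  exclude <- if (config$allow_repeats) integer(0) else observed_idx
  if (acq$name == "random") {
    return(random_batch(space, config$q, exclude,
                        seed = derive_seed(config$seed, round)))
  }
  model <- do.call(gp_fit,
                   c(list(space$encoding[observed_idx, , drop = FALSE],
                          observed_val), config$gp_args))
  if (acq$name == "ts") {
    thompson_batch(model, space, config$q, exclude,
                   seed = derive_seed(config$seed, round),
                   max_pool = config$max_joint)
  } else {
    kriging_believer_batch(model, space, acq, config$q, exclude,
                           observed_val,
                           seed = derive_seed(config$seed, round),
                           max_pool = config$max_joint)
  }
}

#' Top-n observed configurations of a run
#'
#' @param trace a \code{reactbo_trace}.
#' @param n report size; if fewer observations exist, all are returned.
#' @return data.frame of the n highest-valued observations, sorted
#'   descending, with their factor levels.
#' @export
top_n <- function(trace, n = 5L) {
  stopifnot(n >= 1)
  ord <- order(trace$objective, decreasing = TRUE)
  out <- as.data.frame(trace)[utils::head(ord, n),
                              setdiff(names(trace), "best_so_far"),
                              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.reactbo_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("reactbo run trace:", nrow(x), "evaluations in", max(x$round),
      "rounds (", cfg$acq$name, ", q =", cfg$q, ", seed =", cfg$seed,
      "); best =", format(max(x$objective), digits = 6), "\n")
  invisible(x)
}
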