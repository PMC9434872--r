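#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' previous RNG state afterwards, so seeded package internals never disturb a
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a master seed
#'
#' All randomness in a run flows from one master seed through named
#' sub-streams: each (round, pick, purpose) triple maps to its own seed, so
#' reproducibility does not depend on the order in which streams are consumed.
#' The map is a fixed multiplicative-congruential hash into [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param ... one or more non-negative integer stream labels.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- c(...)
  stopifnot(length(labs) >= 1, all(is.finite(labs)))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (lab in as.numeric(labs)) {
    h <- (h * 48271 + lab * 7919 + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
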