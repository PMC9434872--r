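# Multi-replicate evaluation: seeded replicate runs, hit counting, quartile
# summaries, Welch comparisons, batch-size sweeps and the missing-domain
# experiment.

#' Replicate a run configuration across seeds
#'
#' Runs the configuration with seeds \code{seed_base .. seed_base + n_runs -
#' 1} and aggregates the final best values and top-5 lists.
#'
#' @param space a \code{reactbo_space}.
#' @param objective a \code{reactbo_objective}.
#' @param config a \code{reactbo_config} (its \code{seed} is overridden per
#'   replicate).
#' @param n_runs number of replicates.
#' @param seed_base first seed.
#' @param keep_traces retain the individual run traces.
#' @return An object of class \code{"reactbo_replicates"}: per-seed best
#'   values, mean, standard error, quartiles, hit counts against the global
#'   and second-highest objective values, and the top-5 value matrix (one
#'   row per replicate).
#' @export
replicate_runs <- function(space, objective, config, n_runs = 50L,
                           seed_base = 1L, keep_traces = FALSE) {
  stopifnot(n_runs >= 1)
  seeds <- seq.int(seed_base, length.out = n_runs)
  best <- numeric(n_runs)
  top5 <- matrix(NA_real_, n_runs, 5L)
  traces <- if (keep_traces) vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    config$seed <- as.integer(seeds[i])
    trace <- tryCatch(bo_run(space, objective, config), error = function(e) {
      stop("replicate with seed ", seeds[i], " failed: ",
           conditionMessage(e), call. = FALSE)
    })
    best[i] <- max(trace$objective)
    tv <- sort(trace$objective, decreasing = TRUE)
    top5[i, seq_len(min(5L, length(tv)))] <- utils::head(tv, 5L)
    if (keep_traces) traces[[i]] <- trace
  }
  avail_vals <- objective$values[space$available]
  global_value <- max(avail_vals, na.rm = TRUE)
  second_value <- sort(avail_vals, decreasing = TRUE)[2]
  hits <- count_hits(best, global_value, second_value)
  q <- stats::quantile(best, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(best = best, seeds = seeds, mean_best = mean(best),
                 sem = stats::sd(best) / sqrt(n_runs),
                 q1 = q[1], median = q[2], q3 = q[3],
                 n_global = hits[["n_global"]],
                 n_second = hits[["n_second"]],
                 global_value = global_value, second_value = second_value,
                 top5 = top5, config = config, traces = traces),
            class = "reactbo_replicates")
}

#' @export
print.reactbo_replicates <- function(x, ...) {
  cat("reactbo replicate summary (", length(x$best), " runs, ",
      x$config$acq$name, ", q = ", x$config$q, ", budget = ",
      x$config$budget, "):\n", sep = "")
  cat(sprintf("  mean best %.3f (sem %.3f); quartiles %.3f / %.3f / %.3f\n",
              x$mean_best, x$sem, x$q1, x$median, x$q3))
  cat("  runs finding global maximum:", x$n_global,
      "; second-highest:", x$n_second, "\n")
  invisible(x)
}

#' Count replicates hitting the global and second-highest optimum
#'
#' Exact lookup equality (the retrospective setting is noiseless); a
#' tolerance is available for noisy objectives. A replicate is counted for
#' the second-highest value only when it missed the global maximum.
#'
#' @param best_values per-replicate final best values.
#' @param global_value,second_value the two highest objective values.
#' @param tol equality tolerance (default exact).
#' @return Named vector \code{c(n_global, n_second)}.
#' @export
count_hits <- function(best_values, global_value, second_value, tol = 0) {
  if (global_value < second_value) {
    stop("global value must be at least the second-highest value")
  }
  hit_g <- abs(best_values - global_value) <= tol
  hit_s <- !hit_g & abs(best_values - second_value) <= tol
  c(n_global = sum(hit_g), n_second = sum(hit_s))
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom, as
#' used for all optimizer comparisons.
#'
#' @param sample_a,sample_b numeric samples (each >= 2 values with nonzero
#'   variance).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 values")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    stop("degenerate samples: both variances are zero")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Batch-size sweep at (roughly) constant budget
#'
#' Replicates every (batch size, rounds) cell for every acquisition. The
#' default grid keeps the budget near 50: (3,17) (4,12) (5,10) (6,8) (7,7)
#' (8,6) (9,6) (10,5), i.e. budgets 51, 48, 50, 48, 49, 48, 54, 50.
#'
#' @param space,objective the benchmark.
#' @param sizes_and_rounds 2-column matrix / data.frame of (q, rounds).
#' @param acquisitions character vector of acquisition names.
#' @param n_runs replicates per cell.
#' @param seed_base first seed (shared across cells for pairing).
#' @param ... further arguments to \code{\link{run_config}}.
#' @return data.frame with one row per cell (acquisition, q, rounds, budget,
#'   mean_best, sem, q1, median, q3, n_global, n_second) and the underlying
#'   summaries in attribute \code{"summaries"}.
#' @export
batch_size_sweep <- function(space, objective,
                             sizes_and_rounds = default_sweep_grid(),
                             acquisitions = c("ei", "ts", "random"),
                             n_runs = 50L, seed_base = 1L, ...) {
  g <- as.matrix(sizes_and_rounds)
  stopifnot(ncol(g) == 2, nrow(g) >= 1)
  rows <- list()
  summaries <- list()
  for (acq in acquisitions) {
    for (i in seq_len(nrow(g))) {
      cfg <- run_config(acq = acq, q = g[i, 1], rounds = g[i, 2], ...)
      s <- replicate_runs(space, objective, cfg, n_runs = n_runs,
                          seed_base = seed_base)
      key <- paste0(acq, "_q", g[i, 1])
      summaries[[key]] <- s
      rows[[key]] <- data.frame(acquisition = acq, q = g[i, 1],
                                rounds = g[i, 2], budget = cfg$budget,
                                mean_best = s$mean_best, sem = s$sem,
                                q1 = s$q1, median = s$median, q3 = s$q3,
                                n_global = s$n_global, n_second = s$n_second,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}

#' Default constant-budget sweep grid
#'
#' @return data.frame of (q, rounds) pairs with budgets 51, 48, 50, 48, 49,
#'   48, 54, 50. The q = 9 cell uses 6 rounds (budget 54).
#' @export
default_sweep_grid <- function() {
  data.frame(q = c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
             rounds = c(17L, 12L, 10L, 8L, 7L, 6L, 6L, 5L))
}

#' Compare zero-fill and restricted handling of an incomplete domain
#'
#' Runs the same replicate protocol twice under identical seeds: once on the
#' complete space with missing candidates zero-filled (the flawed mode), once
#' on the space restricted to the candidates that actually exist.
#'
#' @param surface a \code{reactbo_surface} whose domain is complete.
#' @param partial a \code{reactbo_objective} with NA at missing candidates.
#' @param allowed candidate indices present in the data.
#' @param config a \code{reactbo_config}.
#' @param n_runs,seed_base replicate protocol.
#' @return list with \code{zero_fill} and \code{restricted} replicate
#'   summaries and \code{mean_diff} (restricted minus zero-fill mean best).
#' @export
missing_domain_experiment <- function(surface, partial, allowed, config,
                                      n_runs = 50L, seed_base = 1L) {
  space <- surface$space
  zf_objective <- zero_fill_domain(space, partial)
  zf <- replicate_runs(space, zf_objective, config, n_runs, seed_base)
  restricted_space <- restrict_domain(space, allowed)
  rs <- replicate_runs(restricted_space, partial, config, n_runs, seed_base)
  list(zero_fill = zf, restricted = rs,
       mean_diff = rs$mean_best - zf$mean_best)
}

#' Across-replicate distribution of the top-5 values by rank
#'
#' For ranks 1..5, the quartiles of the rank-r observed value across
#' replicates, per acquisition.
#'
#' @param summaries named list of \code{reactbo_replicates} (names =
#'   acquisition labels).
#' @return data.frame with columns acquisition, rank, q1, median, q3, mean.
#' @export
top5_rank_distribution <- function(summaries) {
  if (inherits(summaries, "reactbo_replicates")) {
    summaries <- list(run = summaries)
  }
  rows <- lapply(names(summaries), function(nm) {
    t5 <- summaries[[nm]]$top5
    do.call(rbind, lapply(1:5, function(r) {
      v <- t5[, r]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(acquisition = nm, rank = r, q1 = q[1], median = q[2],
                 q3 = q[3], mean = mean(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
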