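# Tabular I/O glue: factor CSVs, objective CSVs, trace round-trips, run
# manifests and YAML run configuration. All files are UTF-8 CSV with a
# header row, or JSON/YAML for structured records.

#' Write factor definitions as one CSV per factor
#'
#' Each file has a \code{level_label} column followed by the descriptor
#' columns (or a \code{smiles} column when levels are molecules).
#'
#' @param factors list of \code{\link{factor_def}} objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_factor_csvs <- function(factors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(factors, function(f) {
    d <- as.data.frame(f$descriptors)
    if (is.null(colnames(f$descriptors))) {
      names(d) <- paste0("d", seq_len(ncol(d)))
    }
    out <- cbind(data.frame(level_label = f$levels,
                            stringsAsFactors = FALSE), d)
    path <- file.path(dir, paste0("factor_", f$name, ".csv"))
    utils::write.csv(out, path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read a factor definition from CSV
#'
#' Expects a header row with \code{level_label} plus either descriptor
#' columns or a \code{smiles} column.
#'
#' @param path CSV path.
#' @param name factor name; defaults to the file name stem.
#' @param ... passed to \code{\link{factor_def}} (fingerprint options).
#' @return A \code{reactbo_factor}.
#' @export
read_factor_csv <- function(path, name = NULL, ...) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"level_label" %in% names(d)) {
    stop("factor CSV must have a 'level_label' column: ", path)
  }
  if (is.null(name)) name <- sub("^factor_", "", sub("\\.csv$", "", basename(path)))
  if ("smiles" %in% names(d)) {
    factor_def(name, d$level_label, smiles = d$smiles, ...)
  } else {
    desc <- as.matrix(d[setdiff(names(d), "level_label")])
    factor_def(name, d$level_label, descriptors = desc, ...)
  }
}

#' Write an objective table as CSV over a space
#'
#' One column of level labels per factor plus an \code{objective} column;
#' candidates with undefined objective are omitted (the missing-domain
#' convention).
#'
#' @param space a \code{reactbo_space}.
#' @param objective a \code{reactbo_objective} (NA = missing).
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_objective_csv <- function(space, objective, path) {
  keep <- which(!is.na(objective$values))
  out <- cbind(candidate_labels(space, keep),
               objective = objective$values[keep])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an objective table CSV against a space
#'
#' Rows are matched to candidates by their level labels; candidates absent
#' from the file get NA, to be handled by the chosen missing-domain mode
#' (\code{\link{zero_fill_domain}} or \code{\link{restrict_domain}}).
#'
#' @param space a \code{reactbo_space}.
#' @param path CSV path with one label column per factor plus
#'   \code{objective}.
#' @return A \code{reactbo_objective} (NA at missing candidates).
#' @export
read_objective_csv <- function(space, path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fac_names <- vapply(space$factors, `[[`, "", "name")
  missing_cols <- setdiff(c(fac_names, "objective"), names(d))
  if (length(missing_cols)) {
    stop("objective CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  idx <- resolve_candidates(space, d[fac_names])
  values <- rep(NA_real_, space$n_candidates)
  values[idx] <- d$objective
  objective_table(values)
}

#' Write / read a run trace (CSV round-trip)
#'
#' Columns: round, pick, one level-label column per factor, objective,
#' best_so_far. Numeric columns survive the round-trip at full precision.
#'
#' @param trace a \code{reactbo_trace}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_trace <- function(trace, path) {
  out <- as.data.frame(trace)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("round", "pick", "objective", "best_so_far")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("trace CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  d$round <- as.integer(d$round)
  d$pick <- as.integer(d$pick)
  d
}

#' Run manifest: everything needed to reproduce a run
#'
#' Serializes the fully resolved configuration (all defaults included), the
#' package version and the seeds to JSON; \code{read_manifest} restores a
#' \code{reactbo_config}.
#'
#' @param config a \code{reactbo_config}.
#' @param path JSON path.
#' @param inputs optional named character vector of input file paths to
#'   digest (size recorded).
#' @return Invisibly, \code{path}.
#' @export
write_manifest <- function(config, path, inputs = NULL) {
  m <- list(package = "reactbo",
            version = as.character(utils::packageVersion("reactbo")),
            acquisition = config$acq[c("name", "delta", "k", "e3i_samples")],
            q = config$q, rounds = config$rounds, budget = config$budget,
            init = config$init, top_n = config$top_n, seed = config$seed,
            max_joint = config$max_joint,
            allow_repeats = config$allow_repeats)
  if (!is.null(inputs)) {
    m$inputs <- lapply(inputs, function(p) {
      list(path = p, bytes = file.size(p))
    })
  }
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(acq = acq_spec(m$acquisition$name, delta = m$acquisition$delta,
                            k = m$acquisition$k,
                            e3i_samples = m$acquisition$e3i_samples),
             q = m$q, rounds = m$rounds, init = m$init, top_n = m$top_n,
             seed = m$seed,
             max_joint = if (is.null(m$max_joint)) NULL else m$max_joint,
             allow_repeats = isTRUE(m$allow_repeats))
}

#' Build a run configuration from a YAML file with overrides
#'
#' Reads keys (acq, delta, k, e3i_samples, q, budget, rounds, init, top_n,
#' seed, max_joint, allow_repeats) from YAML; arguments passed in \code{...}
#' override file values. Unknown keys raise an error naming the valid set.
#'
#' @param path YAML file path, or NULL for pure-default construction.
#' @param ... overrides, as for \code{\link{run_config}}.
#' @return A \code{reactbo_config}.
#' @export
read_run_config <- function(path = NULL, ...) {
  file_args <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (is.null(file_args)) file_args <- list()
  valid <- c("acq", "delta", "k", "e3i_samples", "q", "budget", "rounds",
             "init", "top_n", "seed", "max_joint", "allow_repeats")
  unknown <- setdiff(names(file_args), valid)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  }
  overrides <- list(...)
  file_args[names(overrides)] <- overrides
  do.call(run_config, file_args)
}
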