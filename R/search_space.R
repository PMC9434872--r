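#' Define a reaction factor and its candidate levels
#'
#' A factor is one categorical degree of freedom of the search space (a
#' reactant, ligand, catalyst, base, ...). Each level carries either a
#' fixed-length numeric descriptor vector or a SMILES string, which is
#' converted to a 512-bit circular fingerprint at encoding time.
#'
#' @param name factor name.
#' @param levels character vector of level labels, unique within the factor.
#' @param descriptors numeric matrix with one row per level (all rows the same
#'   length), or \code{NULL} when \code{smiles} is given.
#' @param smiles optional character vector of SMILES strings, one per level.
#' @param fingerprint_bits fingerprint length used when encoding SMILES.
#' @param fingerprint_radius circular-fingerprint radius used when encoding
#'   SMILES (radius 2 is the ECFP4-like default).
#' @return An object of class \code{"reactbo_factor"}.
#' @export
factor_def <- function(name, levels, descriptors = NULL, smiles = NULL,
                       fingerprint_bits = 512L, fingerprint_radius = 2L) {
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("factor '", name, "' needs at least one level")
  if (anyDuplicated(levels)) {
    stop("duplicate level labels in factor '", name, "'")
  }
  if (is.null(descriptors) && is.null(smiles)) {
    stop("factor '", name, "' needs descriptors or SMILES strings")
  }
  if (!is.null(smiles)) {
    if (length(smiles) != length(levels)) {
      stop("factor '", name, "': one SMILES string per level required")
    }
    descriptors <- fingerprint_encode(smiles, bits = fingerprint_bits,
                                      radius = fingerprint_radius)
  }
  descriptors <- as.matrix(descriptors)
  if (!is.numeric(descriptors)) {
    stop("factor '", name, "': descriptors must be numeric")
  }
  if (nrow(descriptors) != length(levels)) {
    stop("factor '", name, "': descriptor row count (", nrow(descriptors),
         ") does not match level count (", length(levels), ")")
  }
  rownames(descriptors) <- levels
  structure(list(name = name, levels = levels, descriptors = descriptors),
            class = "reactbo_factor")
}

#' Build the full cartesian search space from factor definitions
#'
#' Enumerates every combination of factor levels in deterministic
#' lexicographic order of level indices (first factor slowest), concatenates
#' the per-factor descriptor vectors into one encoding row per candidate,
#' prunes constant and highly correlated descriptor columns, and z-scores the
#' retained columns over the available candidates.
#'
#' @param factors list of \code{\link{factor_def}} objects.
#' @param prune_threshold drop a column whose absolute Pearson correlation
#'   with an already-retained column exceeds this; set \code{NULL} to skip
#'   pruning.
#' @param standardize z-score retained columns over available candidates
#'   before the surrogate sees them.
#' @return An object of class \code{"reactbo_space"} with elements
#'   \code{factors}, \code{candidates} (integer level-index matrix),
#'   \code{encoding_raw}, \code{encoding} (pruned, optionally standardized),
#'   \code{retained_cols}, \code{available} (logical mask), and
#'   \code{n_candidates}.
#' @export
build_cartesian_space <- function(factors, prune_threshold = 0.95,
                                  standardize = TRUE) {
  if (inherits(factors, "reactbo_factor")) factors <- list(factors)
  stopifnot(length(factors) >= 1)
  ok <- vapply(factors, inherits, logical(1), "reactbo_factor")
  if (!all(ok)) stop("all elements of 'factors' must come from factor_def()")
  n_levels <- vapply(factors, function(f) length(f$levels), integer(1))
  n <- prod(n_levels)

  # lexicographic order: first factor varies slowest, last factor fastest
  grids <- rev(lapply(rev(n_levels), seq_len))
  candidates <- as.matrix(rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)))
  dimnames(candidates) <- list(NULL, vapply(factors, `[[`, "", "name"))
  storage.mode(candidates) <- "integer"

  enc <- do.call(cbind, lapply(seq_along(factors), function(j) {
    factors[[j]]$descriptors[candidates[, j], , drop = FALSE]
  }))
  rownames(enc) <- NULL
  colnames(enc) <- make.unique(unlist(lapply(factors, function(f) {
    cn <- colnames(f$descriptors)
    if (is.null(cn)) cn <- paste0("d", seq_len(ncol(f$descriptors)))
    paste(f$name, cn, sep = ".")
  })), sep = "_")

  space <- structure(
    list(factors = factors, candidates = candidates, encoding_raw = enc,
         encoding = NULL, retained_cols = seq_len(ncol(enc)),
         available = rep(TRUE, n), n_candidates = n,
         prune_threshold = prune_threshold, standardize = standardize),
    class = "reactbo_space")
  reencode_space(space)
}

# Re-derive the working encoding (prune + standardize) from the raw encoding,
# using only the currently available candidates; called after restriction.
reencode_space <- function(space) {
  avail <- space$available
  raw <- space$encoding_raw
  if (!is.null(space$prune_threshold)) {
    pr <- prune_correlated_columns(raw[avail, , drop = FALSE],
                                   threshold = space$prune_threshold)
    space$retained_cols <- pr$retained
  } else {
    space$retained_cols <- seq_len(ncol(raw))
  }
  enc <- raw[, space$retained_cols, drop = FALSE]
  if (isTRUE(space$standardize)) {
    mu <- colMeans(enc[avail, , drop = FALSE])
    sd <- apply(enc[avail, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    enc <- sweep(sweep(enc, 2, mu, "-"), 2, sd, "/")
  }
  space$encoding <- enc
  space
}

#' @export
print.reactbo_space <- function(x, ...) {
  cat("reactbo search space:", x$n_candidates, "candidates,",
      length(x$factors), "factor(s) (",
      paste(vapply(x$factors, function(f) length(f$levels), integer(1)),
            collapse = " x "), "levels ),",
      sum(x$available), "available,",
      ncol(x$encoding), "of", ncol(x$encoding_raw), "descriptor columns\n")
  invisible(x)
}

#' Encode SMILES strings as folded circular fingerprints
#'
#' Computes a radius-2 (ECFP4-like) circular fingerprint for each molecule via
#' OpenBabel (ChemmineOB) and folds it to \code{bits} positions by OR-folding,
#' yielding a deterministic 0/1 vector per molecule.
#'
#' @param smiles character vector of SMILES strings.
#' @param bits folded fingerprint length (default 512).
#' @param radius circular-fingerprint radius; 1, 2 or 3 (ECFP2/4/6).
#' @return 0/1 integer matrix, one row per input SMILES, \code{bits} columns.
#' @export
fingerprint_encode <- function(smiles, bits = 512L, radius = 2L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint encoding requires the ChemmineOB package")
  }
  stopifnot(bits >= 1, radius %in% c(1L, 2L, 3L))
  fp_type <- paste0("ECFP", 2L * radius)
  out <- matrix(0L, nrow = length(smiles), ncol = bits)
  for (i in seq_along(smiles)) {
    s <- smiles[[i]]
    full <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::fingerprint_OB(mol, fp_type)
    }, error = function(e) {
      stop("cannot encode SMILES string '", s, "': ", conditionMessage(e),
           call. = FALSE)
    })
    if (length(full) == 0 || all(full == 0)) {
      stop("cannot encode SMILES string '", s,
           "': fingerprint computation returned no bits", call. = FALSE)
    }
    set_bits <- (which(full != 0) - 1L) %% as.integer(bits) + 1L
    out[i, unique(set_bits)] <- 1L
  }
  rownames(out) <- names(smiles)
  colnames(out) <- paste0("fp", seq_len(bits))
  out
}

#' Drop constant and highly correlated descriptor columns
#'
#' Scans columns left to right: zero-variance columns are dropped, and a
#' column is dropped when its absolute Pearson correlation with any
#' already-retained column exceeds \code{threshold}.
#'
#' @param x numeric matrix (candidates in rows).
#' @param threshold correlation cut-off in (0, 1].
#' @return list with \code{matrix} (retained columns) and \code{retained}
#'   (their indices in \code{x}).
#' @export
prune_correlated_columns <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty matrix")
  stopifnot(threshold > 0, threshold <= 1)
  sds <- apply(x, 2, stats::sd)
  varying <- which(sds > 0 & is.finite(sds))
  if (length(varying) == 0L) {
    return(list(matrix = x[, integer(0), drop = FALSE], retained = integer(0)))
  }
  if (nrow(x) < 3L) {
    # with < 3 rows every non-constant pair is perfectly correlated
    cm <- matrix(1, length(varying), length(varying))
  } else {
    cm <- abs(suppressWarnings(stats::cor(x[, varying, drop = FALSE])))
  }
  keep <- logical(length(varying))
  for (j in seq_along(varying)) {
    keep[j] <- !any(keep & cm[, j] > threshold, na.rm = TRUE)
  }
  retained <- varying[keep]
  list(matrix = x[, retained, drop = FALSE], retained = retained)
}

#' Restrict the search space to an allowed subset of configurations
#'
#' Marks every candidate outside \code{allowed} as unavailable; acquisition,
#' initialization and batching never see unavailable candidates. The working
#' encoding is re-pruned and re-standardized over the remaining candidates.
#'
#' @param space a \code{reactbo_space}.
#' @param allowed integer candidate indices, or a matrix/data.frame of level
#'   labels (one column per factor) naming the allowed configurations.
#' @return The restricted \code{reactbo_space}.
#' @export
restrict_domain <- function(space, allowed) {
  stopifnot(inherits(space, "reactbo_space"))
  idx <- resolve_candidates(space, allowed)
  mask <- rep(FALSE, space$n_candidates)
  mask[idx] <- TRUE
  space$available <- mask
  reencode_space(space)
}

# Map configurations given as level labels (or pass through integer indices)
# to candidate row indices; errors on configurations absent from the space.
resolve_candidates <- function(space, conf) {
  if (is.numeric(conf) && is.null(dim(conf))) {
    idx <- as.integer(conf)
    if (any(idx < 1L | idx > space$n_candidates)) {
      stop("candidate index out of range")
    }
    return(idx)
  }
  conf <- as.matrix(conf)
  if (ncol(conf) != length(space$factors)) {
    stop("configuration table must have one column per factor")
  }
  key_space <- apply(space$candidates, 1, paste, collapse = "\r")
  lev <- matrix(NA_integer_, nrow(conf), ncol(conf))
  for (j in seq_along(space$factors)) {
    lev[, j] <- match(as.character(conf[, j]), space$factors[[j]]$levels)
  }
  if (anyNA(lev)) stop("configuration refers to an unknown factor level")
  idx <- match(apply(lev, 1, paste, collapse = "\r"), key_space)
  if (anyNA(idx)) stop("configuration not present in the search space")
  idx
}

#' Label table for candidate indices
#'
#' @param space a \code{reactbo_space}.
#' @param idx candidate indices.
#' @return data.frame of level labels, one column per factor.
#' @export
candidate_labels <- function(space, idx = seq_len(space$n_candidates)) {
  out <- as.data.frame(lapply(seq_along(space$factors), function(j) {
    space$factors[[j]]$levels[space$candidates[idx, j]]
  }), stringsAsFactors = FALSE)
  names(out) <- vapply(space$factors, `[[`, "", "name")
  out
}

#' Objective lookup table over a search space
#'
#' Wraps per-candidate objective values (percent yield, PCE, ...) together
#' with the indices of the global maximum and of the second-highest value.
#'
#' @param values numeric vector, one value per candidate; \code{NA} where the
#'   objective is undefined.
#' @return An object of class \code{"reactbo_objective"}.
#' @export
objective_table <- function(values) {
  values <- as.numeric(values)
  if (all(is.na(values))) stop("objective table is entirely missing")
  ord <- order(values, decreasing = TRUE, na.last = TRUE)
  structure(list(values = values,
                 global_max_index = ord[1],
                 second_max_index = if (length(ord) >= 2) ord[2] else NA_integer_),
            class = "reactbo_objective")
}

#' @export
print.reactbo_objective <- function(x, ...) {
  cat("reactbo objective table:", length(x$values), "candidates,",
      sum(!is.na(x$values)), "defined; global max",
      format(x$values[x$global_max_index]), "at index", x$global_max_index,
      "\n")
  invisible(x)
}

#' Zero-fill a partial objective table over a complete domain
#'
#' The deliberately flawed missing-data mode: every candidate without a
#' recorded objective is assigned the value 0 and stays available, so the
#' optimizer can waste budget on configurations that do not exist.
#'
#' @param space a complete \code{reactbo_space}.
#' @param objective a \code{reactbo_objective} with \code{NA} at missing
#'   candidates, or a numeric vector with \code{NA}s.
#' @return A complete \code{reactbo_objective} with zeros filled in.
#' @export
zero_fill_domain <- function(space, objective) {
  values <- if (inherits(objective, "reactbo_objective")) objective$values
            else as.numeric(objective)
  if (length(values) != space$n_candidates) {
    stop("objective length does not match the candidate count")
  }
  values[is.na(values)] <- 0
  objective_table(values)
}
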