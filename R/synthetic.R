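# Synthetic objective surfaces with known ground truth.
#
# The generators emulate the structure of retrospective reaction-scope and
# molecular-library campaigns: multi-factor cartesian yield tables bounded in
# [0, 100], an incomplete-domain variant where whole reactant-pair blocks are
# missing, and a single-factor fingerprint-encoded library with a PCE-like
# positive response. Every surface records its global and second-best optima
# and regenerates bit-identically from (parameters, seed).

#' Generate a multi-factor synthetic yield surface
#'
#' Each factor level receives a latent quality score (standard normal) and a
#' descriptor vector correlated with it: each descriptor column equals
#' \code{informativeness * quality + sqrt(1 - informativeness^2) * noise}, so
#' \code{informativeness = 1} makes descriptors perfectly informative and 0
#' makes them useless. The latent response of a candidate is the sum of its
#' levels' quality scores plus pairwise interaction terms; it is mapped to
#' [0, 100] by a fixed logistic squashing of its standardized value, after
#' which Gaussian noise (sd in yield points) is added and clamped.
#'
#' @param shape integer vector of per-factor level counts (each >= 2).
#' @param interaction interaction strength: sd of the pairwise level-pair
#'   interaction effects relative to the unit main-effect sd.
#' @param noise_sd sd of the added noise, in points on the 0-100 yield scale.
#' @param informativeness correlation in [0, 1] between descriptors and
#'   latent level quality.
#' @param n_descriptors descriptor columns per factor level.
#' @param seed integer seed; regeneration is bit-identical.
#' @param prune_threshold passed to \code{\link{build_cartesian_space}}.
#' @return An object of class \code{"reactbo_surface"}: list with
#'   \code{space}, \code{objective}, \code{params}, and the ground-truth
#'   \code{global_max_index} / \code{second_max_index}.
#' @export
generate_yield_surface <- function(shape, interaction = 0.25, noise_sd = 5,
                                   informativeness = 0.8, n_descriptors = 3L,
                                   seed = 1L, prune_threshold = 0.95) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || any(shape < 2L)) {
    stop("each factor needs at least 2 levels")
  }
  stopifnot(interaction >= 0, noise_sd >= 0,
            informativeness >= 0, informativeness <= 1, n_descriptors >= 1)
  nf <- length(shape)

  dat <- with_seed(seed, {
    quality <- lapply(shape, stats::rnorm)
    desc <- lapply(seq_len(nf), function(f) {
      L <- shape[f]
      noise <- matrix(stats::rnorm(L * n_descriptors), L, n_descriptors)
      informativeness * matrix(quality[[f]], L, n_descriptors) +
        sqrt(1 - informativeness^2) * noise
    })
    # pairwise interactions between level pairs of every factor pair
    inter <- list()
    if (nf >= 2 && interaction > 0) {
      for (a in seq_len(nf - 1)) for (b in (a + 1):nf) {
        inter[[paste(a, b)]] <-
          matrix(stats::rnorm(shape[a] * shape[b], sd = interaction),
                 shape[a], shape[b])
      }
    }
    list(quality = quality, desc = desc, inter = inter)
  })

  factors <- lapply(seq_len(nf), function(f) {
    factor_def(paste0("factor", f),
               levels = paste0("f", f, "_l", seq_len(shape[f])),
               descriptors = dat$desc[[f]])
  })
  space <- build_cartesian_space(factors, prune_threshold = prune_threshold)

  raw <- rowSums(vapply(seq_len(nf), function(f) {
    dat$quality[[f]][space$candidates[, f]]
  }, numeric(space$n_candidates)))
  if (length(dat$inter)) {
    for (nm in names(dat$inter)) {
      ab <- as.integer(strsplit(nm, " ")[[1]])
      raw <- raw + dat$inter[[nm]][cbind(space$candidates[, ab[1]],
                                         space$candidates[, ab[2]])]
    }
  }
  # fixed monotone squashing: standardize by the theoretical latent sd, then
  # a logistic map onto (0, 100)
  sd_theory <- sqrt(nf + interaction^2 * choose(nf, 2))
  yield <- 100 * stats::plogis(1.5 * raw / sd_theory)
  if (noise_sd > 0) {
    yield <- with_seed(derive_seed(seed, 999L), {
      pmin(pmax(yield + stats::rnorm(length(yield), sd = noise_sd), 0), 100)
    })
  }

  objective <- objective_table(yield)
  structure(list(space = space, objective = objective,
                 params = list(shape = shape, interaction = interaction,
                               noise_sd = noise_sd,
                               informativeness = informativeness,
                               n_descriptors = n_descriptors, seed = seed),
                 global_max_index = objective$global_max_index,
                 second_max_index = objective$second_max_index,
                 latent = raw),
            class = "reactbo_surface")
}

#' @export
print.reactbo_surface <- function(x, ...) {
  cat("reactbo synthetic surface:", x$space$n_candidates, "candidates (",
      paste(x$params$shape %||% x$params$n_molecules, collapse = " x "),
      "); global max", format(x$objective$values[x$global_max_index],
                              digits = 5),
      "at index", x$global_max_index, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop whole level-pair blocks from a surface's domain
#'
#' Emulates an incomplete combinatorial data set: whole (factor 1, factor 2)
#' level-pair blocks are removed, as when only some electrophile-nucleophile
#' pairs were ever run. Returns the partial objective (NA on dropped
#' candidates) and the allowed candidate list. The block containing the
#' global maximum is retained unless \code{allow_drop_max}.
#'
#' @param surface a \code{reactbo_surface} with >= 2 factors.
#' @param keep_pairs number of (factor1, factor2) level pairs to keep; or
#' @param keep_fraction fraction of pairs to keep (used when
#'   \code{keep_pairs} is NULL).
#' @param seed integer seed for the choice of kept pairs.
#' @param allow_drop_max permit dropping the global maximum's block.
#' @return list with \code{partial} (a \code{reactbo_objective} with NAs),
#'   \code{allowed} (candidate indices), and \code{kept_pairs} (2-column
#'   matrix of kept level pairs).
#' @export
drop_combinations <- function(surface, keep_pairs = NULL,
                              keep_fraction = NULL, seed = 1L,
                              allow_drop_max = FALSE) {
  stopifnot(inherits(surface, "reactbo_surface"))
  space <- surface$space
  if (length(space$factors) < 2L) stop("needs at least two factors")
  L1 <- length(space$factors[[1]]$levels)
  L2 <- length(space$factors[[2]]$levels)
  n_pairs <- L1 * L2
  if (is.null(keep_pairs)) {
    if (is.null(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
      stop("give keep_pairs or a keep_fraction in (0, 1]")
    }
    keep_pairs <- max(1L, round(keep_fraction * n_pairs))
  }
  keep_pairs <- as.integer(keep_pairs)
  if (keep_pairs < 1L || keep_pairs > n_pairs) {
    stop("keep_pairs must be in 1..", n_pairs)
  }

  pair_id <- (space$candidates[, 1] - 1L) * L2 + space$candidates[, 2]
  max_pair <- pair_id[surface$global_max_index]
  kept <- with_seed(seed, {
    if (allow_drop_max) {
      sample.int(n_pairs, keep_pairs)
    } else {
      c(max_pair, sample(setdiff(seq_len(n_pairs), max_pair),
                         keep_pairs - 1L))
    }
  })
  allowed <- which(pair_id %in% kept)
  values <- surface$objective$values
  values[-allowed] <- NA_real_
  list(partial = objective_table(values), allowed = allowed,
       kept_pairs = cbind(level1 = (kept - 1L) %/% L2 + 1L,
                          level2 = (kept - 1L) %% L2 + 1L))
}

#' Generate a single-factor fingerprint-encoded library surface
#'
#' Emulates a molecular-library screen: one factor with \code{n_molecules}
#' items, each encoded as a sparse random binary fingerprint. The response is
#' a sparse linear function of the bits plus a few bit-pair epistatic terms
#' and Gaussian noise, shifted to a positive PCE-like scale.
#'
#' @param n_molecules library size (>= 10).
#' @param bits fingerprint length.
#' @param sparsity probability a bit is set.
#' @param n_active number of bits with nonzero linear weight.
#' @param n_epistatic number of bit-pair interaction terms.
#' @param noise_sd response noise sd (response units).
#' @param seed integer seed.
#' @return A \code{reactbo_surface} over a single-factor space.
#' @export
generate_library_surface <- function(n_molecules, bits = 512L,
                                     sparsity = 0.05, n_active = 20L,
                                     n_epistatic = 10L, noise_sd = 0.2,
                                     seed = 1L) {
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 10L) stop("n_molecules must be at least 10")
  stopifnot(bits >= 2, sparsity > 0, sparsity < 1, n_active >= 1,
            n_active <= bits, n_epistatic >= 0, noise_sd >= 0)

  gen <- with_seed(seed, {
    fp <- matrix(stats::rbinom(n_molecules * bits, 1L, sparsity),
                 n_molecules, bits)
    active <- sample.int(bits, n_active)
    w <- stats::rnorm(n_active, mean = 1, sd = 0.5)
    epi <- if (n_epistatic > 0) {
      cbind(sample.int(bits, n_epistatic, replace = TRUE),
            sample.int(bits, n_epistatic, replace = TRUE),
            stats::rnorm(n_epistatic, mean = 0.5, sd = 0.5))
    }
    noise <- stats::rnorm(n_molecules, sd = noise_sd)
    list(fp = fp, active = active, w = w, epi = epi, noise = noise)
  })

  raw <- as.numeric(gen$fp[, gen$active, drop = FALSE] %*% gen$w)
  if (!is.null(gen$epi)) {
    for (t in seq_len(nrow(gen$epi))) {
      raw <- raw + gen$epi[t, 3] * gen$fp[, gen$epi[t, 1]] *
        gen$fp[, gen$epi[t, 2]]
    }
  }
  response <- raw + gen$noise
  response <- response - min(response) + 1 # positive PCE-like scale

  f <- factor_def("molecule", levels = paste0("mol", seq_len(n_molecules)),
                  descriptors = gen$fp)
  space <- build_cartesian_space(list(f))
  objective <- objective_table(response)
  structure(list(space = space, objective = objective,
                 params = list(n_molecules = n_molecules, bits = bits,
                               sparsity = sparsity, n_active = n_active,
                               n_epistatic = n_epistatic,
                               noise_sd = noise_sd, seed = seed),
                 global_max_index = objective$global_max_index,
                 second_max_index = objective$second_max_index,
                 coefficients = list(active = gen$active, w = gen$w,
                                     epi = gen$epi)),
            class = "reactbo_surface")
}

#' Bottom-decile candidate pool
#'
#' Indices of the ceil(N/10) lowest-valued candidates (ties at the boundary
#' value included), used for the adversarial initialization mode.
#'
#' @param objective a \code{reactbo_objective}, \code{reactbo_surface}, or
#'   numeric vector of objective values.
#' @param available optional logical availability mask; unavailable
#'   candidates are ignored.
#' @return Integer vector of candidate indices.
#' @export
bottom_decile_pool <- function(objective, available = NULL) {
  values <- if (inherits(objective, "reactbo_surface")) {
    objective$objective$values
  } else if (inherits(objective, "reactbo_objective")) {
    objective$values
  } else {
    as.numeric(objective)
  }
  idx <- seq_along(values)
  keep <- !is.na(values)
  if (!is.null(available)) keep <- keep & available
  idx <- idx[keep]
  v <- values[idx]
  n_pool <- ceiling(length(idx) / 10)
  cut <- sort(v, partial = n_pool)[n_pool]
  idx[v <= cut] # boundary ties included
}

#' Packaged benchmark surfaces
#'
#' Fixed synthetic benchmarks used throughout the analyses and tests:
#' \describe{
#'   \item{synth-suzuki}{five-factor 4 x 3 x 12 x 8 x 5 yield table (5760
#'     candidates), moderate interactions, noise sd 5, informativeness 0.8.}
#'   \item{synth-pd}{four-factor 6 x 11 x 6 x 8 table (3168 candidates) with
#'     only 32 of the 66 (factor 1, factor 2) level pairs present (1536
#'     candidates), mirroring an incomplete coupling data set. Returned with
#'     the complete surface plus \code{partial} / \code{allowed} fields.}
#'   \item{synth-cep}{single-factor fingerprint library (default 10000
#'     molecules, 512 bits).}
#' }
#'
#' @param name one of \code{"synth-suzuki"}, \code{"synth-pd"},
#'   \code{"synth-cep"}.
#' @param n_molecules library size for \code{synth-cep}.
#' @return A \code{reactbo_surface}; for \code{synth-pd} with extra fields
#'   \code{partial} (objective with NAs) and \code{allowed} (indices).
#' @export
benchmark_surface <- function(name = c("synth-suzuki", "synth-pd",
                                       "synth-cep"),
                              n_molecules = 10000L) {
  name <- match.arg(name)
  switch(name,
    "synth-suzuki" = generate_yield_surface(
      shape = c(4L, 3L, 12L, 8L, 5L), interaction = 0.25, noise_sd = 5,
      informativeness = 0.8, seed = 20220901L),
    "synth-pd" = {
      surf <- generate_yield_surface(
        shape = c(6L, 11L, 6L, 8L), interaction = 0.25, noise_sd = 5,
        informativeness = 0.8, seed = 20220902L)
      dropped <- drop_combinations(surf, keep_pairs = 32L, seed = 20220902L)
      surf$partial <- dropped$partial
      surf$allowed <- dropped$allowed
      surf
    },
    "synth-cep" = generate_library_surface(
      n_molecules = n_molecules, bits = 512L, sparsity = 0.05,
      n_active = 20L, n_epistatic = 10L, noise_sd = 0.2, seed = 20220903L))
}
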