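# Per-region Viterbi decoding of the modified HMM and the iterative
# termination scheme choosing the number of subpopulations.
#
# A hidden state at one CpG is the length-d vector of binary methylation
# values of the d subpopulations. Transitions factorize over subpopulations
# (d identical distance-binned 2x2 matrices); emissions depend on the state
# only through p, the summed prevalence of subpopulations whose bit is 1.

# bit matrix for all 2^d states: rows = subpopulations, columns = states in
# lexicographic order of the bit vector (subpopulation 1 most significant),
# so that which.max ties resolve toward the lexicographically smallest state
state_bits <- function(d) {
  n_states <- 2L^d
  matrix(vapply(seq_len(n_states) - 1L, function(s) {
    as.integer(bitwAnd(bitwShiftR(s, (d - 1L):0L), 1L))
  }, integer(d)), nrow = d)
}

#' Viterbi decoding of one region
#'
#' Runs the max-product dynamic program over the 2^d joint methylation
#' states of `d` subpopulations across the CpGs of one region and returns
#' the most likely state sequence and its joint log probability. The initial
#' distribution is the product over subpopulations of the stationary
#' distribution of the long-range (open-ended) transition matrix; ties are
#' broken toward the lexicographically smallest state vector.
#'
#' @param region A [meth_region].
#' @param d Number of subpopulations.
#' @param prevalence Prevalence vector of length `d` (descending, sums
#'   to 1).
#' @param transitions A `transition_model` (see [train_transitions]).
#' @param prior A [beta_prior].
#' @param cache Optional environment for memoizing emission tables across
#'   regions sharing the same prior.
#' @return List with `profiles` (d x g binary matrix, one row per
#'   subpopulation), `states` (integer state index per CpG, 0-based) and
#'   `logprob` (joint Viterbi log probability).
#' @export
viterbi_region <- function(region, d, prevalence, transitions, prior,
                           cache = NULL) {
  stopifnot(inherits(region, "meth_region"), d >= 1,
            length(prevalence) == d)
  g <- region$g
  if (g == 0L) {
    warning("region '", region$region_id, "' has no CpGs")
    return(list(profiles = matrix(integer(0), d, 0), states = integer(0),
                logprob = NA_real_))
  }
  bits <- state_bits(d)               # d x S
  S <- ncol(bits)
  p_state <- as.numeric(crossprod(bits, prevalence))  # length S

  b_obs <- meth_count(region$meth_level, region$coverage)
  n_obs <- as.integer(region$coverage)

  log_emit <- matrix(0, g, S)
  for (k in seq_len(g)) {
    if (n_obs[k] < 1L) next  # uninformative CpG
    for (s in seq_len(S)) {
      tab <- emission_table(n_obs[k], p_state[s], prior, cache = cache)
      log_emit[k, s] <- tab[b_obs[k] + 1L]
    }
  }

  statio <- stationary_distribution(transitions)
  log_init <- as.numeric(crossprod(log(statio["M"]) * bits +
                                     log(statio["U"]) * (1 - bits),
                                   rep(1, d)))
  # joint state-to-state log transition matrix per distance bin in use
  bins <- if (g > 1) transition_bins(transitions, diff(region$start)) else integer(0)
  joint_by_bin <- new.env(parent = emptyenv())
  joint_trans <- function(bin) {
    key <- as.character(bin)
    jt <- joint_by_bin[[key]]
    if (is.null(jt)) {
      lT <- log(transitions$matrices[[bin]])
      jt <- matrix(0, S, S)
      for (a in seq_len(S)) for (b in seq_len(S)) {
        jt[a, b] <- sum(lT[cbind(bits[, a] + 1L, bits[, b] + 1L)])
      }
      joint_by_bin[[key]] <- jt
    }
    jt
  }

  V <- log_init + log_emit[1, ]
  back <- matrix(NA_integer_, g, S)
  if (g > 1) {
    for (k in 2:g) {
      jt <- joint_trans(bins[k - 1L])
      scores <- V + jt                 # S x S: rows = previous state
      prev_best <- apply(scores, 2, which.max)
      V <- scores[cbind(prev_best, seq_len(S))] + log_emit[k, ]
      back[k, ] <- prev_best
    }
  }
  last <- which.max(V)
  states <- integer(g)
  states[g] <- last
  if (g > 1) {
    for (k in g:2) states[k - 1L] <- back[k, states[k]]
  }
  profiles <- bits[, states, drop = FALSE]
  rownames(profiles) <- NULL
  list(profiles = profiles, states = states - 1L, logprob = max(V))
}

#' Solve one region: number of subpopulations, profiles, log probabilities
#'
#' Applies the iterative termination scheme: the region is decoded with
#' 1 subpopulation, then 2, and so on; a candidate `d + 1` is accepted only
#' if its Viterbi log probability strictly exceeds that of `d` (a uniform
#' prior on the number of subpopulations makes this the posterior
#' comparison). The scheme stops at the first non-improvement or at
#' `d_max`. Duplicating an existing profile leaves emissions unchanged but
#' adds transition mass, so the scheme always terminates.
#'
#' @param region A [meth_region].
#' @param prevalence_by_d List whose `d`-th element is the prevalence vector
#'   used for candidate `d`, or a function of `d` returning it.
#' @param transitions A `transition_model`.
#' @param prior A [beta_prior].
#' @param d_max Maximum number of subpopulations to consider (default 3).
#' @param cache Optional emission-table cache environment.
#' @return An object of class `region_solution`: region coordinates and
#'   data, `d_solved`, `profiles` (`d_solved` x g, rows ordered by
#'   descending prevalence, lexicographic within ties), `prevalence`, and
#'   `logprob_by_d` for every candidate evaluated.
#' @export
solve_region <- function(region, prevalence_by_d, transitions, prior,
                         d_max = 3, cache = NULL) {
  stopifnot(inherits(region, "meth_region"), d_max >= 1)
  get_prev <- if (is.function(prevalence_by_d)) {
    prevalence_by_d
  } else {
    function(d) prevalence_by_d[[d]]
  }
  if (region$g == 0L) {
    warning("region '", region$region_id, "' has no CpGs; null solution")
    return(structure(list(region_id = region$region_id, chrom = region$chrom,
                          start = region$start, end = region$end, g = 0L,
                          d_solved = 0L,
                          profiles = matrix(integer(0), 0, 0),
                          prevalence = numeric(0),
                          logprob_by_d = numeric(0),
                          meth_level = numeric(0), coverage = numeric(0)),
                     class = "region_solution"))
  }
  logprob_by_d <- numeric(0)
  kept <- NULL
  kept_prev <- NULL
  d_solved <- 0L
  for (d in seq_len(d_max)) {
    prev <- get_prev(d)
    stopifnot(length(prev) == d)
    vit <- viterbi_region(region, d, prev, transitions, prior, cache = cache)
    logprob_by_d[d] <- vit$logprob
    if (d > 1 && !(logprob_by_d[d] > logprob_by_d[d - 1])) break
    kept <- vit
    kept_prev <- prev
    d_solved <- d
  }
  ord <- order(-kept_prev,
               apply(kept$profiles, 1, paste, collapse = ""))
  structure(list(region_id = region$region_id, chrom = region$chrom,
                 start = region$start, end = region$end, g = region$g,
                 d_solved = d_solved,
                 profiles = kept$profiles[ord, , drop = FALSE],
                 prevalence = kept_prev[ord],
                 logprob_by_d = logprob_by_d,
                 meth_level = region$meth_level,
                 coverage = region$coverage),
            class = "region_solution")
}

#' @export
print.region_solution <- function(x, ...) {
  cat("<region_solution> ", x$region_id, ": ", x$d_solved,
      " subpopulation(s), ", x$g, " CpGs\n", sep = "")
  if (x$d_solved >= 1L) {
    for (k in seq_len(x$d_solved)) {
      cat(sprintf("  subpop %d (prevalence %.2f): %s\n", k, x$prevalence[k],
                  paste(x$profiles[k, ], collapse = "")))
    }
  }
  invisible(x)
}

#' Deconvolve methylation data into subpopulation profiles
#'
#' The main fitting function. Takes per-CpG methylation observations
#' grouped into regions, estimates subpopulation prevalences from the
#' sample-wide distribution of fractional methylation values (once per
#' candidate number of subpopulations), and solves every region
#' independently for its number of allelic subpopulations and their binary
#' methylation profiles. Intrasample differentially methylated regions
#' (i-DMRs) between solved profiles are called and ranked.
#'
#' @param data Methylation observations: a path to a 6-column tab-separated
#'   table (chrom, start, end, methylation level, coverage, region id), a
#'   data frame with those columns, or a list of [meth_region] objects.
#' @param regions Optional region definitions (data frame with `chrom`,
#'   `start`, `end`, `region_id`); when supplied, CpGs are re-assigned to
#'   the regions they fall in (a CpG inside several regions is used in
#'   each), replacing the table's own region ids.
#' @param transitions Transition model (default: shipped pre-trained model).
#' @param prior Measurement model (default: shipped fitted prior).
#' @param d_max Maximum number of subpopulations per region (default 3;
#'   promoter-scale regions rarely support four or more distinct profiles).
#' @param coverage_min,coverage_max Inclusive coverage filter applied when
#'   `data` is a file path (defaults 4 and 1000).
#' @param prevalence Optional prevalence override: a list whose `d`-th
#'   element is the length-`d` prevalence vector. When `NULL`, prevalences
#'   are estimated with [estimate_prevalence].
#' @param signature_ids Optional character vector of region ids whose CpG
#'   levels are pooled for prevalence estimation (a signature of regions
#'   known to discriminate the subpopulations); default: all regions.
#' @param grid_step Optional prevalence grid step passed to
#'   [estimate_prevalence].
#' @param quiet Suppress progress messages.
#' @return An object of class `methdecon`: list with `solutions` (one
#'   `region_solution` per region), `prevalence_by_d`, `idmrs` (ranked
#'   i-DMR data frame), `d_max` and the matched call. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`.
#' @examples
#' pos <- seq(0, 950, by = 50)
#' states <- rbind(rep(1, 20), rep(0, 20))
#' tab <- simulate_methylation_mixture(states, pos, prevalence = c(0.5, 0.5),
#'                                     coverage = 60, seed = 1)
#' fit <- methdecon(tab, d_max = 2)
#' fit
#' @export
methdecon <- function(data, regions = NULL,
                      transitions = default_transition_model(),
                      prior = default_beta_prior(), d_max = 3,
                      coverage_min = 4, coverage_max = 1000,
                      prevalence = NULL, signature_ids = NULL,
                      grid_step = NULL, quiet = FALSE) {
  cl <- match.call()
  if (is.character(data) && length(data) == 1L) {
    data <- read_methylation_table(data, coverage_min, coverage_max,
                                   quiet = quiet)
  }
  if (is.data.frame(data)) {
    if (!is.null(regions)) data <- assign_regions(data, regions)
    region_list <- as_meth_regions(data)
  } else {
    if (!is.null(regions)) {
      data <- assign_regions(regions_to_table(data), regions)
      region_list <- as_meth_regions(data)
    } else {
      region_list <- data
    }
  }
  stopifnot(length(region_list) >= 1)

  prevalence_by_d <- if (!is.null(prevalence)) {
    if (!is.list(prevalence)) prevalence <- list(prevalence)[rep(1, d_max)]
    prevalence
  } else {
    pool <- region_list
    if (!is.null(signature_ids)) {
      pool <- pool[vapply(pool, function(r) r$region_id %in% signature_ids,
                          logical(1))]
      if (length(pool) == 0L) stop("no regions match signature_ids")
    }
    levels <- unlist(lapply(pool, function(r) r$meth_level))
    lapply(seq_len(d_max), function(d) {
      if (is.null(grid_step)) {
        estimate_prevalence(levels, d)
      } else {
        estimate_prevalence(levels, d, grid_step)
      }
    })
  }

  cache <- new.env(parent = emptyenv())
  solutions <- lapply(region_list, function(r) {
    solve_region(r, prevalence_by_d, transitions, prior, d_max = d_max,
                 cache = cache)
  })
  names(solutions) <- vapply(solutions, function(s) s$region_id, character(1))
  idmrs <- rank_idmrs(solutions)
  structure(list(solutions = solutions, prevalence_by_d = prevalence_by_d,
                 idmrs = idmrs, d_max = d_max, call = cl),
            class = "methdecon")
}

#' Assign CpGs to region definitions
#'
#' Replaces the region id of each CpG record with the id(s) of the supplied
#' region window(s) containing it; a CpG falling in several windows is
#' duplicated into each. CpGs outside every window are dropped.
#'
#' @param table Methylation data frame (six standard columns).
#' @param regions Data frame `chrom`, `start`, `end`, `region_id`.
#' @return Re-assigned methylation data frame.
#' @export
assign_regions <- function(table, regions) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- table$chrom == regions$chrom[i] &
      table$start >= regions$start[i] & table$start < regions$end[i]
    if (!any(hit)) return(NULL)
    sub <- table[hit, , drop = FALSE]
    sub$region_id <- regions$region_id[i]
    sub
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no CpGs fall inside the supplied regions")
  res
}
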