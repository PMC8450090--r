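# Module estimating subpopulation prevalences from the sample-wide
# distribution of fractional methylation values.

#' Expected fractional methylation levels of a mixture
#'
#' Enumerates all 2^d binary methylation assignments of `d` subpopulations
#' and returns the distinct expected fractional methylation levels — the
#' subset sums of the prevalence vector — sorted ascending. For example,
#' prevalences (0.3, 0.7) yield levels \{0, 0.3, 0.7, 1\}. The empty subset
#' contributes 0 and the full subset 1, so both endpoints are always
#' present.
#'
#' @param prevalence Numeric vector of subpopulation fractions in (0, 1\]
#'   summing to 1.
#' @param tol Deduplication tolerance (default 1e-9).
#' @return Sorted numeric vector of distinct expected levels.
#' @export
expected_levels <- function(prevalence, tol = 1e-9) {
  stopifnot(length(prevalence) >= 1, all(prevalence > 0),
            all(prevalence <= 1))
  if (abs(sum(prevalence) - 1) > 1e-9) {
    stop("prevalences must sum to 1")
  }
  levels <- 0
  for (f in prevalence) levels <- c(levels, levels + f)
  levels <- sort(levels)
  # collapse values closer than tol; snap the endpoints exactly
  keep <- c(TRUE, diff(levels) > tol)
  levels <- levels[keep]
  levels[abs(levels) <= tol] <- 0
  levels[abs(levels - 1) <= tol] <- 1
  levels
}

#' Estimate subpopulation prevalences from methylation levels
#'
#' Searches all descending prevalence vectors of length `d` on a grid and
#' returns the one minimizing the mean absolute distance from each observed
#' fractional methylation value to its nearest expected mixture level (the
#' L1 distance between the observations and the set of subset-sum levels).
#' Among ties the vector whose smallest component is smallest is returned,
#' so that the least-committal extra subpopulation wins.
#'
#' @param meth_levels Numeric vector of observed fractional methylation
#'   values in \[0, 1\] (typically pooled over all regions, or over a
#'   signature region list known to separate the subpopulations).
#' @param d Number of subpopulations (>= 1).
#' @param grid_step Grid resolution; default 0.01 for `d <= 2` and 0.02
#'   otherwise. Must divide 1 exactly; the minimum component is one grid
#'   step.
#' @return Numeric vector of length `d`, descending, summing to 1, with an
#'   `objective` attribute giving the attained mean absolute deviation.
#' @export
estimate_prevalence <- function(meth_levels, d,
                                grid_step = if (d <= 2) 0.01 else 0.02) {
  stopifnot(d >= 1, length(meth_levels) >= 1)
  if (any(meth_levels < 0 | meth_levels > 1)) {
    stop("methylation levels must lie in [0, 1]")
  }
  n_units <- round(1 / grid_step)
  if (abs(n_units * grid_step - 1) > 1e-9) {
    stop("grid_step must divide 1 exactly")
  }
  if (d * grid_step > 1 + 1e-12) {
    stop("infeasible: d * grid_step exceeds 1")
  }
  if (d == 1) {
    out <- 1
    attr(out, "objective") <-
      mean(pmin(abs(meth_levels), abs(meth_levels - 1)))
    return(out)
  }
  cands <- descending_compositions(n_units, d)
  best <- NULL
  best_obj <- Inf
  best_min <- Inf
  for (ci in seq_len(nrow(cands))) {
    frac <- cands[ci, ] / n_units
    lev <- expected_levels(frac)
    nearest <- do.call(pmin, lapply(lev, function(l) abs(meth_levels - l)))
    obj <- mean(nearest)
    if (obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) < 1e-12 && frac[d] < best_min - 1e-12)) {
      best <- frac
      best_obj <- obj
      best_min <- frac[d]
    }
  }
  attr(best, "objective") <- best_obj
  best
}

# All descending integer compositions of n into d positive parts, as a
# matrix with one composition per row (parts in units of the grid step).
descending_compositions <- function(n, d) {
  if (d == 1) return(matrix(n, 1, 1))
  rows <- list()
  recurse <- function(remaining, parts_left, cap, prefix) {
    if (parts_left == 1) {
      if (remaining >= 1 && remaining <= cap) {
        rows[[length(rows) + 1L]] <<- c(prefix, remaining)
      }
      return(invisible(NULL))
    }
    # each part at most cap, at least ceil(remaining/parts_left) to stay
    # descending-feasible, and leave >= 1 per remaining part
    lo <- ceiling(remaining / parts_left)
    hi <- min(cap, remaining - (parts_left - 1L))
    if (hi < lo) return(invisible(NULL))
    for (v in hi:lo) recurse(remaining - v, parts_left - 1L, v, c(prefix, v))
  }
  recurse(n, d, n, integer(0))
  do.call(rbind, rows)
}
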