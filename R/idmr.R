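# Calling and ranking intrasample differentially methylated regions
# (i-DMRs) between solved subpopulation profiles.

#' Call i-DMRs within one solved region
#'
#' A CpG is differential when any two solved subpopulation profiles
#' disagree at it. Candidate intervals are grown greedily from seeds of
#' consecutive differential CpGs: adjacent seeds are merged (absorbing the
#' interior non-differential CpGs) while the differential fraction of the
#' merged interval stays at or above `min_frac`. Intervals must span at
#' least `min_len` bp (first CpG start to last CpG end, half-open), contain
#' at least `min_cpgs` CpGs, and keep a differential fraction of at least
#' `min_frac`; surviving intervals are disjoint. Intervals always begin and
#' end at differential CpGs.
#'
#' @param solution A `region_solution` (see [solve_region]).
#' @param min_len Minimum span in bp (default 50).
#' @param min_cpgs Minimum number of CpGs (default 3).
#' @param min_frac Minimum differential CpG fraction (default 0.9).
#' @return Data frame with columns `chrom`, `start`, `end`, `region_id`,
#'   `n_cpgs`, `fraction_differential` (empty when `d_solved < 2`).
#' @export
call_idmrs <- function(solution, min_len = 50, min_cpgs = 3,
                       min_frac = 0.9) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), region_id = character(),
                      n_cpgs = integer(), fraction_differential = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(solution) || solution$d_solved < 2L || solution$g == 0L) {
    return(empty)
  }
  prof <- solution$profiles
  diffcpg <- apply(prof, 2, function(col) any(col != col[1]))
  if (!any(diffcpg)) return(empty)

  # seeds: maximal runs of consecutive differential CpGs
  r <- rle(diffcpg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- cbind(starts[r$values], ends[r$values])

  # greedy left-to-right merging of seeds while the fraction constraint
  # holds for the merged interval
  merged <- list()
  cur <- seeds[1, ]
  if (nrow(seeds) > 1) {
    for (i in 2:nrow(seeds)) {
      cand <- c(cur[1], seeds[i, 2])
      frac <- sum(diffcpg[cand[1]:cand[2]]) / (cand[2] - cand[1] + 1L)
      if (frac >= min_frac) {
        cur <- cand
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- seeds[i, ]
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- lapply(merged, function(iv) {
    idx <- iv[1]:iv[2]
    n_cpg <- length(idx)
    span_start <- solution$start[iv[1]]
    span_end <- solution$end[iv[2]]
    frac <- sum(diffcpg[idx]) / n_cpg
    if (span_end - span_start < min_len) return(NULL)
    if (n_cpg < min_cpgs) return(NULL)
    if (frac < min_frac) return(NULL)
    data.frame(chrom = solution$chrom, start = span_start, end = span_end,
               region_id = solution$region_id, n_cpgs = n_cpg,
               fraction_differential = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Call and rank i-DMRs across solved regions
#'
#' Calls i-DMRs in every solution and attaches a rank score: the
#' improvement in Viterbi log probability of the parent region when modeled
#' with two subpopulations rather than one,
#' `logprob_by_d[2] - logprob_by_d[1]`. The list is sorted by descending
#' score, ties broken by genomic coordinate. i-DMRs from a region without
#' an evaluated two-subpopulation log probability get score `NA` and sort
#' last, with a warning.
#'
#' @param solutions A list of `region_solution` objects or a `methdecon`
#'   fit.
#' @param min_len,min_cpgs,min_frac Filters passed to [call_idmrs].
#' @return Data frame with columns `chrom`, `start`, `end`, `region_id`,
#'   `rank_score`, `n_cpgs`, `fraction_differential`, ordered by rank.
#' @export
rank_idmrs <- function(solutions, min_len = 50, min_cpgs = 3,
                       min_frac = 0.9) {
  if (inherits(solutions, "methdecon")) solutions <- solutions$solutions
  rows <- lapply(solutions, function(s) {
    calls <- call_idmrs(s, min_len = min_len, min_cpgs = min_cpgs,
                        min_frac = min_frac)
    if (nrow(calls) == 0L) return(NULL)
    if (length(s$logprob_by_d) >= 2L) {
      calls$rank_score <- s$logprob_by_d[2] - s$logprob_by_d[1]
    } else {
      warning("region '", s$region_id,
              "' has no 2-subpopulation log probability; rank undefined")
      calls$rank_score <- NA_real_
    }
    calls
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), region_id = character(),
                      rank_score = numeric(), n_cpgs = integer(),
                      fraction_differential = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(is.na(out$rank_score), -out$rank_score, out$chrom, out$start)
  out <- out[ord, c("chrom", "start", "end", "region_id", "rank_score",
                    "n_cpgs", "fraction_differential")]
  rownames(out) <- NULL
  out
}
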