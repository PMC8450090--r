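# Evaluation against reference cell-type profiles: closest-reference
# assignment, per-CpG accuracy, and major-subpopulation correctness.

#' Assign solved profiles to reference cell types
#'
#' Binarizes reference profiles (fractional methylation >= 0.5 rounds to
#' methylated) and assigns each solved profile independently to the
#' reference differing at the fewest CpGs (Hamming distance, equal to the
#' L1 norm for binary vectors). Two solved profiles may map to the same
#' reference, and assignment happens even when the disagreement exceeds
#' half the CpGs. Ties go to the first reference in input order.
#'
#' @param solved Binary matrix of solved profiles (rows = subpopulations)
#'   or a `region_solution`.
#' @param references Matrix of reference profiles (rows = references,
#'   possibly fractional) on the same CpG set.
#' @param ref_names Reference names (default: rownames or `ref1`, ...).
#' @return Data frame with one row per solved profile: `profile`,
#'   `reference`, `accuracy` (fraction of CpGs agreeing).
#' @export
assign_profiles <- function(solved, references, ref_names = NULL) {
  if (inherits(solved, "region_solution")) solved <- solved$profiles
  stopifnot(is.matrix(solved), is.matrix(references))
  if (ncol(solved) != ncol(references)) {
    stop("solved and reference profiles are on different CpG sets (",
         ncol(solved), " vs ", ncol(references), " CpGs)")
  }
  if (is.null(ref_names)) {
    ref_names <- rownames(references)
    if (is.null(ref_names)) {
      ref_names <- paste0("ref", seq_len(nrow(references)))
    }
  }
  refbin <- (references >= 0.5) * 1L
  g <- ncol(solved)
  rows <- lapply(seq_len(nrow(solved)), function(i) {
    dist <- rowSums(abs(sweep(refbin, 2, solved[i, ])))
    j <- which.min(dist)  # first minimum: documented tie-break
    data.frame(profile = i, reference = ref_names[j],
               accuracy = 1 - dist[j] / g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of regions whose major profile matches the expected major type
#'
#' The major solved profile of a region is the one with the highest
#' prevalence (the first row of a solution's profile matrix). This computes
#' the fraction of regions whose major profile was assigned to the expected
#' major reference cell type.
#'
#' @param assignments Character vector: the reference assigned to each
#'   region's major profile (e.g. the first row of [assign_profiles]
#'   output, per region).
#' @param expected_major Expected major reference name (single value or
#'   per-region vector).
#' @return Fraction in \[0, 1\].
#' @export
major_assignment_rate <- function(assignments, expected_major) {
  stopifnot(length(assignments) >= 1)
  mean(assignments == rep_len(expected_major, length(assignments)))
}
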