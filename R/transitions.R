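# Distance-binned 2x2 transition matrices for CpG-to-CpG methylation
# persistence. One shared model is used for every subpopulation: transitions
# are assumed independent and identically distributed across subpopulations.

#' Train distance-binned methylation transition matrices
#'
#' Counts transitions between binarized methylation states of adjacent CpGs,
#' binned by the genomic distance separating them, and converts the counts to
#' row-stochastic 2x2 matrices. Methylation correlation between neighbouring
#' CpGs decays with distance, so one matrix is kept per distance bin; all
#' transitions beyond the last bin edge share a single open-ended bin.
#'
#' Binarization rounds fractional methylation at or above 0.5 up to
#' methylated. A pseudocount is added to every cell before normalization so
#' that no transition has probability zero (Viterbi runs in log space).
#'
#' @param records Data frame with columns `chrom`, `start`, `meth_level`
#'   (extra columns ignored), or a list of [meth_region] objects. Records
#'   must be position-sorted within each chromosome; they are sorted here if
#'   not. Adjacent pairs are formed within a chromosome only.
#' @param bin_edges Increasing distance bin edges in bp; bins are
#'   `(0, e1], (e1, e2], ...` plus an open-ended bin beyond the last edge.
#'   Default `c(50, 100, 200, 500, 1000)`.
#' @param pseudocount Added to every count cell (default 1).
#' @return A `transition_model`: list with `bin_edges`, `matrices` (list of
#'   2x2 row-stochastic matrices, rows/cols named `U`, `M`), and `counts`
#'   (raw counts per bin, before pseudocounts).
#' @seealso [transition_lookup], [write_transition_model]
#' @export
train_transitions <- function(records, bin_edges = c(50, 100, 200, 500, 1000),
                              pseudocount = 1) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- regions_to_table(records)
  }
  stopifnot(is.data.frame(records),
            all(c("chrom", "start", "meth_level") %in% names(records)))
  stopifnot(length(bin_edges) >= 1, !is.unsorted(bin_edges, strictly = TRUE),
            all(bin_edges > 0), pseudocount >= 0)
  n_bins <- length(bin_edges) + 1L
  counts <- lapply(seq_len(n_bins), function(i) {
    matrix(0, 2, 2, dimnames = list(c("U", "M"), c("U", "M")))
  })
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  st <- as.numeric(records$start)
  state <- as.integer(records$meth_level >= 0.5)  # 0 = U, 1 = M
  same_chrom <- records$chrom[-nrow(records)] == records$chrom[-1]
  if (nrow(records) >= 2L) {
    dist <- st[-1] - st[-length(st)]
    from <- state[-length(state)]
    to <- state[-1]
    use <- same_chrom & dist > 0
    bin <- findInterval(dist[use], c(0, bin_edges), left.open = TRUE)
    from <- from[use]; to <- to[use]
    for (idx in seq_along(bin)) {
      b <- bin[idx]
      counts[[b]][from[idx] + 1L, to[idx] + 1L] <-
        counts[[b]][from[idx] + 1L, to[idx] + 1L] + 1
    }
  }
  matrices <- lapply(seq_len(n_bins), function(i) {
    cm <- counts[[i]]
    if (sum(cm) == 0) {
      warning("no transitions observed in distance bin ", i,
              "; using uniform matrix")
    }
    m <- cm + pseudocount
    if (any(rowSums(m) == 0)) m <- m + 1  # pseudocount 0 with empty rows
    sweep(m, 1, rowSums(m), "/")
  })
  structure(list(bin_edges = bin_edges, matrices = matrices, counts = counts),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$matrices), " distance bins (edges: ",
      paste(x$bin_edges, collapse = ", "), " bp, last bin open-ended)\n",
      sep = "")
  total <- sum(vapply(x$counts, sum, numeric(1)))
  cat("trained on ", format(total, big.mark = ","), " transitions\n", sep = "")
  invisible(x)
}

#' Look up the transition matrix for a CpG-to-CpG distance
#'
#' Bins are half-open `(lower, upper]`: a distance equal to a bin edge is
#' assigned to the lower bin. Distances beyond the last edge use the
#' open-ended bin.
#'
#' @param model A `transition_model`.
#' @param distance Distance in bp between adjacent CpG starts; must be >= 1.
#' @return The 2x2 row-stochastic matrix for the bin containing `distance`.
#' @export
transition_lookup <- function(model, distance) {
  stopifnot(inherits(model, "transition_model"))
  if (length(distance) != 1L || !is.finite(distance) || distance <= 0) {
    stop("distance must be a single positive number")
  }
  bin <- findInterval(distance, c(0, model$bin_edges), left.open = TRUE)
  model$matrices[[bin]]
}

# Bin index per distance, vectorized (internal).
transition_bins <- function(model, distances) {
  findInterval(distances, c(0, model$bin_edges), left.open = TRUE)
}

#' Stationary distribution of a transition matrix
#'
#' For the 2x2 chain with matrix `P`, returns `c(U, M)` solving `pi P = pi`.
#' Used as the per-subpopulation initial state distribution, taken from the
#' open-ended (long-range) bin so it matches the marginal trained methylation
#' frequency.
#'
#' @param model A `transition_model`.
#' @param bin Bin index (default: the open-ended last bin).
#' @return Named numeric vector `c(U = , M = )` summing to 1.
#' @export
stationary_distribution <- function(model, bin = length(model$matrices)) {
  P <- model$matrices[[bin]]
  pUM <- P[1, 2]; pMU <- P[2, 1]
  if (pUM + pMU == 0) return(c(U = 0.5, M = 0.5))
  piM <- pUM / (pUM + pMU)
  c(U = 1 - piM, M = piM)
}

#' Serialize / read a transition model
#'
#' Plain-JSON serialization: bin edges, matrices (row-major), raw counts.
#'
#' @param model A `transition_model`.
#' @param path Output (or input) file path.
#' @return `read_transition_model` returns the model; the writer returns the
#'   path invisibly.
#' @export
write_transition_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  obj <- list(bin_edges = model$bin_edges,
              matrices = lapply(model$matrices, function(m) as.vector(t(m))),
              counts = lapply(model$counts, function(m) as.vector(t(m))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(v) {
    matrix(as.numeric(v), 2, 2, byrow = TRUE,
           dimnames = list(c("U", "M"), c("U", "M")))
  }
  mats <- lapply(seq_len(nrow_or_len(obj$matrices)), function(i) {
    to_mat(slice_rows(obj$matrices, i))
  })
  cnts <- lapply(seq_len(nrow_or_len(obj$counts)), function(i) {
    to_mat(slice_rows(obj$counts, i))
  })
  structure(list(bin_edges = as.numeric(obj$bin_edges), matrices = mats,
                 counts = cnts),
            class = "transition_model")
}

# jsonlite may simplify a list of equal-length vectors to a matrix.
nrow_or_len <- function(x) if (is.matrix(x)) nrow(x) else length(x)
slice_rows <- function(x, i) if (is.matrix(x)) x[i, ] else x[[i]]

#' Default pre-trained transition model
#'
#' Returns the transition model shipped with the package, trained on a
#' genome-scale synthetic methylation corpus generated by
#' [simulate_training_corpus] with distance-dependent state persistence
#' matching the decay of CpG methylation correlation with distance. Intended
#' so the tool runs without any download; retrain on real data with
#' [train_transitions] when available.
#'
#' @return A `transition_model`.
#' @export
default_transition_model <- function() {
  if (is.null(.methdecon_cache$transitions)) {
    path <- system.file("extdata", "default_transitions.json",
                        package = "methdecon", mustWork = TRUE)
    .methdecon_cache$transitions <- read_transition_model(path)
  }
  .methdecon_cache$transitions
}

.methdecon_cache <- new.env(parent = emptyenv())
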