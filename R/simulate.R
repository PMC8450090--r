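# Synthetic heterogeneous methylation mixtures: methylation-level and
# read-level simulators, a partial-methylation read classifier, and the
# synthetic training corpus used for the shipped default models.

# run expr with a private, restorable RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic CpG positions
#'
#' Draws strictly increasing CpG positions whose spacings come from a
#' two-component mixture emulating CpG-island-dense stretches (short, tens
#' of bp) and open-sea stretches (exponential, hundreds of bp).
#'
#' @param n Number of CpGs.
#' @param start First position (default 1000).
#' @param cgi_weight Fraction of spacings drawn from the island component
#'   (default 0.3).
#' @param seed Optional RNG seed.
#' @return Integer vector of length `n`, strictly increasing.
#' @export
synthetic_cpg_positions <- function(n, start = 1000, cgi_weight = 0.3,
                                    seed = NULL) {
  with_seed(seed, {
    island <- stats::runif(n - 1) < cgi_weight
    gaps <- ifelse(island,
                   2 + stats::rgeom(n - 1, 1 / 20),
                   30 + round(stats::rexp(n - 1, 1 / 300)))
    as.integer(cumsum(c(start, gaps)))
  })
}

#' Simulate binary reference methylation profiles
#'
#' Generates per-subpopulation binary profiles over a shared set of CpG
#' positions with distance-dependent persistence: the state at the next CpG
#' is copied from the current CpG with probability `exp(-dist / corr_scale)`
#' and otherwise redrawn from a Bernoulli with methylated fraction `p_m` —
#' so nearby CpGs are strongly correlated and distant CpGs nearly
#' independent, mimicking the distance decay of methylation correlation.
#'
#' @param positions Increasing CpG positions.
#' @param n_profiles Number of profiles to draw.
#' @param p_m Marginal methylated fraction (default 0.5).
#' @param corr_scale Correlation length in bp (default 500).
#' @param seed Optional RNG seed.
#' @return Binary matrix, `n_profiles` rows by `length(positions)` columns.
#' @export
simulate_reference_profiles <- function(positions, n_profiles, p_m = 0.5,
                                        corr_scale = 500, seed = NULL) {
  g <- length(positions)
  with_seed(seed, {
    out <- matrix(0L, n_profiles, g)
    for (r in seq_len(n_profiles)) {
      s <- integer(g)
      s[1] <- stats::rbinom(1, 1, p_m)
      if (g > 1) {
        keep <- stats::runif(g - 1) < exp(-diff(positions) / corr_scale)
        redraw <- stats::rbinom(g - 1, 1, p_m)
        for (k in 2:g) s[k] <- if (keep[k - 1]) s[k - 1] else redraw[k - 1]
      }
      out[r, ] <- s
    }
    out
  })
}

# accept either a binary matrix (rows = subpopulations) or a list of
# profile objects with shared $positions and $states
normalize_profiles <- function(profiles, positions = NULL) {
  if (is.matrix(profiles)) {
    if (is.null(positions)) stop("positions required with a profile matrix")
    return(list(states = profiles, positions = as.integer(positions)))
  }
  pos <- profiles[[1]]$positions
  for (p in profiles) {
    if (!identical(as.integer(p$positions), as.integer(pos))) {
      stop("all profiles must share the same CpG positions")
    }
  }
  states <- do.call(rbind, lapply(profiles, function(p) as.integer(p$states)))
  list(states = states, positions = as.integer(pos))
}

#' Simulate a methylation-level mixture
#'
#' The expected methylation level of each CpG is the dot product of the
#' prevalences with the binary profile states; the observed methylated read
#' count is then a binomial draw at the given coverage, and the reported
#' level is count / coverage.
#'
#' @param profiles Binary profile matrix (rows = subpopulations) or a list
#'   of profile objects with `$positions` and `$states`.
#' @param positions CpG positions (required with a matrix).
#' @param prevalence Prevalence vector matching the profiles, summing to 1.
#' @param coverage Per-CpG read count (single value or per-CpG vector).
#' @param seed Optional RNG seed; the same seed reproduces the table.
#' @param chrom,region_id Labels for the emitted records.
#' @return Methylation data frame with the six standard columns.
#' @export
simulate_methylation_mixture <- function(profiles, positions = NULL,
                                         prevalence, coverage, seed = NULL,
                                         chrom = "chrS", region_id = "sim") {
  pr <- normalize_profiles(profiles, positions)
  d <- nrow(pr$states)
  stopifnot(length(prevalence) == d, all(coverage >= 1))
  expected <- as.numeric(crossprod(pr$states, prevalence))
  g <- length(expected)
  cov <- rep_len(coverage, g)
  counts <- with_seed(seed, stats::rbinom(g, cov, expected))
  data.frame(chrom = chrom, start = pr$positions, end = pr$positions + 1L,
             meth_level = counts / cov, coverage = cov,
             region_id = region_id, stringsAsFactors = FALSE)
}

#' Simulate a read-level mixture over one region
#'
#' Emulates subsampling single-end bisulfite reads from a mixture of cell
#' types: the total read count is `round(coverage * region_size /
#' read_length)`; read start positions are uniform over the region; each
#' read's source subpopulation is drawn independently with probability equal
#' to its prevalence (so realized per-region proportions fluctuate); CpG
#' calls are copied from the source profile and flipped independently with
#' probability `meas_error` to emulate measurement noise.
#'
#' @inheritParams simulate_methylation_mixture
#' @param region Length-2 vector `c(start, end)`; must be at least
#'   `read_length` wide and contain the CpG positions of interest.
#' @param read_length Read length in bp (default 100).
#' @param meas_error Per-CpG call flip probability (default 0.01).
#' @return List with `reads` (list of reads, each with `start`, `end`,
#'   `positions`, `calls`, `source`) and `table` (collapsed per-CpG
#'   methylation data frame over CpGs with nonzero coverage).
#' @export
simulate_read_mixture <- function(profiles, positions = NULL, prevalence,
                                  coverage, read_length = 100, region,
                                  meas_error = 0.01, seed = NULL,
                                  chrom = "chrS", region_id = "sim") {
  pr <- normalize_profiles(profiles, positions)
  d <- nrow(pr$states)
  stopifnot(length(prevalence) == d, length(region) == 2)
  domain <- region[2] - region[1]
  if (domain < read_length) stop("region shorter than read_length")
  n_reads <- round(coverage * domain / read_length)
  with_seed(seed, {
    starts <- region[1] + floor(stats::runif(n_reads) * (domain - read_length + 1))
    sources <- sample.int(d, n_reads, replace = TRUE, prob = prevalence)
    reads <- vector("list", n_reads)
    g <- length(pr$positions)
    n_meth <- integer(g)
    n_cov <- integer(g)
    for (i in seq_len(n_reads)) {
      s <- starts[i]
      idx <- which(pr$positions >= s & pr$positions < s + read_length)
      calls <- pr$states[sources[i], idx]
      if (meas_error > 0 && length(calls) > 0) {
        flip <- stats::runif(length(calls)) < meas_error
        calls <- ifelse(flip, 1L - calls, calls)
      }
      reads[[i]] <- list(start = s, end = s + read_length,
                         positions = pr$positions[idx],
                         calls = as.integer(calls), source = sources[i])
      n_meth[idx] <- n_meth[idx] + calls
      n_cov[idx] <- n_cov[idx] + 1L
    }
    keep <- n_cov > 0L
    table <- data.frame(chrom = chrom, start = pr$positions[keep],
                        end = pr$positions[keep] + 1L,
                        meth_level = n_meth[keep] / n_cov[keep],
                        coverage = n_cov[keep], region_id = region_id,
                        stringsAsFactors = FALSE)
    list(reads = reads, table = table)
  })
}

#' Classify partially methylated reads over a region
#'
#' A read is partially methylated when its CpG calls inside the region
#' contain both methylated and unmethylated values. Only the part of a read
#' overlapping the region is considered; reads with fewer than two in-region
#' CpG calls are counted as non-partial.
#'
#' @param reads List of reads as produced by [simulate_read_mixture].
#' @param region Length-2 vector `c(start, end)` (half-open).
#' @return List with `n_partial` and `n_total` (reads overlapping the
#'   region by at least 1 bp).
#' @export
classify_partial_reads <- function(reads, region) {
  stopifnot(length(region) == 2)
  n_partial <- 0L
  n_total <- 0L
  for (rd in reads) {
    if (rd$end <= region[1] || rd$start >= region[2]) next
    n_total <- n_total + 1L
    inreg <- rd$positions >= region[1] & rd$positions < region[2]
    calls <- rd$calls[inreg]
    if (length(calls) >= 2L && any(calls == 1L) && any(calls == 0L)) {
      n_partial <- n_partial + 1L
    }
  }
  list(n_partial = n_partial, n_total = n_total)
}

#' Count distinct methylation patterns among cell types
#'
#' Given which pairs of cell types have a differentially methylated region
#' (DMR) within a window, counts the distinct methylation patterns the
#' window can distinguish: cell types not separated by any DMR are grouped
#' together, and the count is the number of groups (connected components of
#' the no-DMR similarity graph). With a DMR between every pair of three
#' cell types the window has three distinct patterns.
#'
#' @param dmr Logical square matrix where `dmr[a, b]` is `TRUE` when a DMR
#'   separates cell types `a` and `b` (diagonal ignored), or a data frame
#'   with columns `a`, `b`, `dmr`.
#' @return Integer number of distinct patterns.
#' @export
count_distinct_patterns <- function(dmr) {
  if (is.data.frame(dmr)) {
    types <- sort(unique(c(dmr$a, dmr$b)))
    m <- matrix(FALSE, length(types), length(types),
                dimnames = list(types, types))
    for (i in seq_len(nrow(dmr))) {
      m[dmr$a[i], dmr$b[i]] <- m[dmr$b[i], dmr$a[i]] <- isTRUE(dmr$dmr[i])
    }
    dmr <- m
  }
  stopifnot(is.matrix(dmr), nrow(dmr) == ncol(dmr))
  k <- nrow(dmr)
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && !dmr[a, b]) {  # similar: merge
      ra <- find(a); rb <- find(b)
      if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Synthetic genome-scale training corpus
#'
#' Generates a per-CpG methylation table emulating a homogeneous training
#' dataset: CpG positions from the island/open-sea spacing mixture, a
#' binary underlying profile with distance-dependent persistence, and
#' observed methylation drawn by sampling each CpG's read calls from a
#' mixture of beta distributions around the underlying state (sharp edge
#' component, broader shoulder, and a small mid component emulating
#' imprinted or allele-specific CpGs). Used to train the shipped default
#' transition model and fit the default beta prior.
#'
#' @param n_cpgs Number of CpGs (default 50000).
#' @param mean_coverage Mean per-CpG coverage (Poisson, default 30; floored
#'   at 4).
#' @param p_m Marginal methylated fraction of the underlying profile.
#' @param corr_scale Persistence correlation length in bp.
#' @param seed Optional RNG seed.
#' @return Methylation data frame with the six standard columns (one region
#'   per synthetic chromosome).
#' @export
simulate_training_corpus <- function(n_cpgs = 50000, mean_coverage = 30,
                                     p_m = 0.5, corr_scale = 500,
                                     seed = NULL) {
  with_seed(seed, {
    half <- ceiling(n_cpgs / 2)
    pos1 <- synthetic_cpg_positions(half)
    pos2 <- synthetic_cpg_positions(n_cpgs - half)
    chrom <- rep(c("chrS1", "chrS2"), c(half, n_cpgs - half))
    pos <- c(pos1, pos2)
    state <- c(simulate_reference_profiles(pos1, 1, p_m, corr_scale)[1, ],
               simulate_reference_profiles(pos2, 1, p_m, corr_scale)[1, ])
    cov <- pmax(stats::rpois(n_cpgs, mean_coverage), 4)
    # per-CpG read-level methylation probability: mixture of betas around
    # the underlying state, mirrored for the methylated state
    comp <- sample.int(3, n_cpgs, replace = TRUE, prob = c(0.88, 0.09, 0.03))
    a <- c(1, 2, 10)[comp]
    b <- c(40, 14, 10)[comp]
    q <- stats::rbeta(n_cpgs, a, b)
    q <- ifelse(state == 1L, 1 - q, q)
    counts <- stats::rbinom(n_cpgs, cov, q)
    data.frame(chrom = chrom, start = pos, end = pos + 1L,
               meth_level = counts / cov, coverage = cov,
               region_id = chrom, stringsAsFactors = FALSE)
  })
}
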