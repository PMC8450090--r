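#' Read a per-CpG methylation table
#'
#' Reads a BED-like tab-delimited table of per-CpG methylation observations
#' with six columns: chromosome, start (0-based), end (exclusive), fractional
#' methylation (mCG/CG), sequencing coverage, and region id. Records are
#' grouped by region id, sorted by position, and filtered by coverage.
#'
#' Coverage filtering follows common practice for bisulfite data: CpGs with
#' very few reads carry unreliable methylation estimates, and CpGs with
#' extreme coverage are likely mapping artefacts. Both bounds are inclusive.
#'
#' @param path Path to a 6-column tab-separated file (no header).
#' @param coverage_min,coverage_max Inclusive coverage bounds; records outside
#'   the bounds are dropped (defaults 4 and 1000).
#' @param quiet If `TRUE`, suppress the message reporting dropped records.
#' @return A list of [meth_region] objects, one per region id, in order of
#'   first appearance in the file.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t100\t101\t0.5\t20\tgeneA",
#'              "chr1\t150\t151\t1\t30\tgeneA"), tf)
#' regs <- read_methylation_table(tf)
#' regs[[1]]$g
#' @export
read_methylation_table <- function(path, coverage_min = 4, coverage_max = 1000,
                                   quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != 6L)
  if (length(bad) > 0L) {
    stop("malformed line ", bad[1], ": expected 6 tab-separated columns, got ",
         nfield[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  meth <- suppressWarnings(as.numeric(m[, 4]))
  cov <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(meth) | is.na(cov))
  if (length(bad) > 0L) stop("malformed line ", bad[1], ": non-numeric field")
  bad <- which(meth < 0 | meth > 1)
  if (length(bad) > 0L) {
    stop("line ", bad[1], ": methylation level ", meth[bad[1]],
         " outside [0, 1]")
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) stop("line ", bad[1], ": end must exceed start")
  bad <- which(cov < 0)
  if (length(bad) > 0L) stop("line ", bad[1], ": negative coverage")
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   meth_level = meth, coverage = cov, region_id = m[, 6],
                   stringsAsFactors = FALSE)
  keep <- df$coverage >= coverage_min & df$coverage <= coverage_max
  n_dropped <- sum(!keep)
  if (n_dropped > 0L && !quiet) {
    message(n_dropped, " record(s) dropped by coverage filter [",
            coverage_min, ", ", coverage_max, "]")
  }
  as_meth_regions(df[keep, , drop = FALSE])
}

#' Group a methylation data frame into regions
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `meth_level`,
#'   `coverage`, `region_id`.
#' @return List of [meth_region] objects in order of first appearance.
#' @export
as_meth_regions <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "meth_level", "coverage", "region_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(df$region_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$region_id == id, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L) {
      stop("region '", id, "' spans multiple chromosomes")
    }
    ord <- order(sub$start)
    sub <- sub[ord, , drop = FALSE]
    if (anyDuplicated(sub$start)) {
      stop("region '", id, "' has duplicate CpG start positions; ",
           "collapse strands upstream or split the region")
    }
    meth_region(region_id = id, chrom = sub$chrom[1], start = sub$start,
                end = sub$end, meth_level = sub$meth_level,
                coverage = sub$coverage)
  })
  names(out) <- ids
  out
}

#' Construct a methylation region
#'
#' A region is an ordered set of per-CpG observations sharing one region id
#' and chromosome. `g` is the number of CpGs.
#'
#' @param region_id Region identifier.
#' @param chrom Chromosome name.
#' @param start,end Integer vectors of 0-based half-open CpG coordinates.
#' @param meth_level Fractional methylation per CpG, in \[0, 1\].
#' @param coverage Read counts per CpG.
#' @return An object of class `meth_region`.
#' @export
meth_region <- function(region_id, chrom, start, end, meth_level, coverage) {
  g <- length(start)
  stopifnot(length(end) == g, length(meth_level) == g, length(coverage) == g)
  if (g > 0) {
    stopifnot(all(end > start), all(meth_level >= 0 & meth_level <= 1),
              all(coverage >= 0), !is.unsorted(start, strictly = TRUE))
  }
  structure(list(region_id = region_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 meth_level = as.numeric(meth_level),
                 coverage = as.numeric(coverage), g = g),
            class = "meth_region")
}

#' @export
print.meth_region <- function(x, ...) {
  cat("<meth_region> ", x$region_id, ": ", x$chrom, ":",
      if (x$g > 0) paste0(min(x$start), "-", max(x$end)) else "(empty)",
      ", ", x$g, " CpGs\n", sep = "")
  invisible(x)
}

#' Convert regions back to a flat methylation data frame
#'
#' @param regions List of [meth_region] objects.
#' @return Data frame with the six standard columns.
#' @export
regions_to_table <- function(regions) {
  if (inherits(regions, "meth_region")) regions <- list(regions)
  do.call(rbind, lapply(regions, function(r) {
    if (r$g == 0) return(NULL)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               meth_level = r$meth_level, coverage = r$coverage,
               region_id = r$region_id, stringsAsFactors = FALSE)
  }))
}

#' Write a methylation table
#'
#' @param x Data frame (six standard columns) or list of [meth_region].
#' @param path Output path; tab-separated, no header.
#' @export
write_methylation_table <- function(x, path) {
  if (!is.data.frame(x)) x <- regions_to_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED region-definition file
#'
#' @param path BED3+name file (chrom, start, end, name), tab-separated.
#' @return Data frame with columns `chrom`, `start`, `end`, `region_id`.
#' @export
read_region_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("region BED needs at least 4 columns (BED3+name)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "region_id")
  df
}

#' Build promoter windows around annotated TSSs
#'
#' Builds one fixed-width window per gene, centred on the transcription start
#' site: `[TSS - flank, TSS + flank)`. Only autosomal genes with complete
#' coding annotations (`cmpl` at both CDS start and end) are used; for genes
#' with several transcripts only the first is considered. The TSS is
#' `txStart` on the + strand and `txEnd` on the - strand.
#'
#' @param annotation Data frame in refGene style with columns `name2` (gene
#'   symbol), `chrom`, `strand`, `txStart`, `txEnd`, `cdsStartStat`,
#'   `cdsEndStat`.
#' @param flank Half-width of the window in bp (default 5000).
#' @return Data frame `chrom`, `start`, `end`, `region_id` (BED-style).
#' @export
make_promoter_windows <- function(annotation, flank = 5000) {
  need <- c("name2", "chrom", "strand", "txStart", "txEnd",
            "cdsStartStat", "cdsEndStat")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  a <- annotation
  a <- a[a$cdsStartStat == "cmpl" & a$cdsEndStat == "cmpl", , drop = FALSE]
  autosomal <- grepl("^(chr)?[0-9]+$", a$chrom)
  a <- a[autosomal, , drop = FALSE]
  a <- a[!duplicated(a$name2), , drop = FALSE]  # first transcript per gene
  if (nrow(a) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), region_id = character()))
  }
  tss <- ifelse(a$strand == "-", a$txEnd, a$txStart)
  start <- tss - flank
  if (any(start < 0)) {
    warning(sum(start < 0), " window(s) clipped at position 0")
    start <- pmax(start, 0)
  }
  data.frame(chrom = a$chrom, start = start, end = tss + flank,
             region_id = a$name2, stringsAsFactors = FALSE)
}

#' Write solved regions to disk
#'
#' Writes three files: `<prefix>_profiles.tsv` with one row per CpG per
#' subpopulation (chrom, start, end, binary state, subpopulation index,
#' prevalence, region id); `<prefix>_summary.tsv` with one row per region
#' (region id, number of subpopulations solved, Viterbi log-probability per
#' candidate); and `<prefix>_idmrs.bed` with called i-DMRs (chrom, start,
#' end, region id, rank score, CpG count, differential fraction). All files
#' carry a single header line starting with `#`.
#'
#' @param solutions List of `region_solution` objects (see [solve_region]).
#' @param out_prefix Output path prefix.
#' @param idmrs Optional precomputed i-DMR data frame (see [rank_idmrs]); if
#'   `NULL`, i-DMRs are called and ranked from `solutions` with defaults.
#' @return Invisibly, the three file paths.
#' @export
write_solution <- function(solutions, out_prefix, idmrs = NULL) {
  prof_path <- paste0(out_prefix, "_profiles.tsv")
  summ_path <- paste0(out_prefix, "_summary.tsv")
  idmr_path <- paste0(out_prefix, "_idmrs.bed")

  prof_rows <- lapply(solutions, function(s) {
    if (is.null(s) || s$d_solved < 1L || s$g == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(s$d_solved), function(k) {
      data.frame(chrom = s$chrom, start = s$start, end = s$end,
                 state = s$profiles[k, ], subpop = k,
                 prevalence = s$prevalence[k], region_id = s$region_id,
                 stringsAsFactors = FALSE)
    }))
  })
  prof <- do.call(rbind, prof_rows)
  con <- file(prof_path, "w")
  writeLines("#chrom\tstart\tend\tstate\tsubpop\tprevalence\tregion_id", con)
  if (!is.null(prof)) {
    utils::write.table(prof, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)

  summ_rows <- lapply(solutions, function(s) {
    if (is.null(s)) return(NULL)
    lp <- paste(sprintf("%d:%.6f", seq_along(s$logprob_by_d), s$logprob_by_d),
                collapse = ",")
    data.frame(region_id = s$region_id, d_solved = s$d_solved,
               logprob_by_d = lp, stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ_rows)
  con <- file(summ_path, "w")
  writeLines("#region_id\td_solved\tlogprob_by_d", con)
  if (!is.null(summ)) {
    utils::write.table(summ, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)

  if (is.null(idmrs)) idmrs <- rank_idmrs(solutions)
  con <- file(idmr_path, "w")
  writeLines("#chrom\tstart\tend\tregion_id\trank_score\tn_cpgs\tfraction_differential",
             con)
  if (!is.null(idmrs) && nrow(idmrs) > 0L) {
    utils::write.table(idmrs[, c("chrom", "start", "end", "region_id",
                                 "rank_score", "n_cpgs",
                                 "fraction_differential")],
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)
  invisible(c(profiles = prof_path, summary = summ_path, idmrs = idmr_path))
}

#' Read a solved-profiles file back
#'
#' Inverse of the profiles file written by [write_solution]; mainly for
#' downstream tooling and round-trip checks.
#'
#' @param path Path to a `*_profiles.tsv` file.
#' @return Data frame with columns chrom, start, end, state, subpop,
#'   prevalence, region_id.
#' @export
read_solution_profiles <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(df) == 0L) return(df)
  names(df) <- c("chrom", "start", "end", "state", "subpop", "prevalence",
                 "region_id")
  df
}
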