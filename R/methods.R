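# S3 methods for the methdecon fit object.

#' @export
print.methdecon <- function(x, ...) {
  cat("Subpopulation methylation deconvolution\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  ds <- vapply(x$solutions, function(s) s$d_solved, integer(1))
  tab <- table(factor(ds, levels = 0:x$d_max))
  cat(length(x$solutions), " region(s) solved; subpopulation counts:\n", sep = "")
  for (d in names(tab)) {
    if (tab[[d]] > 0) cat("  d = ", d, ": ", tab[[d]], " region(s)\n", sep = "")
  }
  cat(nrow(x$idmrs), " i-DMR(s) called\n", sep = "")
  invisible(x)
}

#' @export
summary.methdecon <- function(object, ...) {
  ds <- vapply(object$solutions, function(s) s$d_solved, integer(1))
  gs <- vapply(object$solutions, function(s) s$g, integer(1))
  out <- list(
    n_regions = length(object$solutions),
    d_table = table(factor(ds, levels = 0:object$d_max)),
    n_cpgs = sum(gs),
    prevalence_by_d = object$prevalence_by_d,
    n_idmrs = nrow(object$idmrs),
    top_idmrs = utils::head(object$idmrs, 5)
  )
  class(out) <- "summary.methdecon"
  out
}

#' @export
print.summary.methdecon <- function(x, ...) {
  cat("Regions: ", x$n_regions, " (", x$n_cpgs, " CpGs)\n", sep = "")
  cat("Subpopulation counts:\n")
  print(x$d_table)
  cat("\nEstimated prevalences by candidate d:\n")
  for (d in seq_along(x$prevalence_by_d)) {
    cat("  d = ", d, ": ",
        paste(sprintf("%.2f", x$prevalence_by_d[[d]]), collapse = ", "),
        "\n", sep = "")
  }
  cat("\ni-DMRs called: ", x$n_idmrs, "\n", sep = "")
  if (x$n_idmrs > 0) {
    cat("Top ranked:\n")
    print(x$top_idmrs)
  }
  invisible(x)
}

#' Extract estimated prevalences
#'
#' Returns the estimated prevalence vector for each candidate number of
#' subpopulations.
#'
#' @param object A `methdecon` fit.
#' @param d Candidate number of subpopulations; default: the full list.
#' @param ... Ignored.
#' @return A prevalence vector (if `d` given) or the list of them.
#' @export
coef.methdecon <- function(object, d = NULL, ...) {
  if (is.null(d)) return(object$prevalence_by_d)
  object$prevalence_by_d[[d]]
}

#' Fitted per-CpG methylation levels
#'
#' For each CpG of each region, the fitted level is the prevalence-weighted
#' mean of the solved binary profiles (the expected mixture methylation).
#'
#' @param object A `methdecon` fit.
#' @param ... Ignored.
#' @return Data frame: `region_id`, `chrom`, `start`, `observed`, `fitted`.
#' @export
fitted.methdecon <- function(object, ...) {
  rows <- lapply(object$solutions, function(s) {
    if (s$d_solved < 1L || s$g == 0L) return(NULL)
    fit <- as.numeric(crossprod(s$profiles, s$prevalence))
    data.frame(region_id = s$region_id, chrom = s$chrom, start = s$start,
               observed = s$meth_level, fitted = fit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
residuals.methdecon <- function(object, ...) {
  f <- fitted(object)
  f$observed - f$fitted
}

#' Predict mixture methylation levels from a fit
#'
#' Returns the fitted per-CpG mixture level, optionally under a different
#' prevalence vector than the one estimated (e.g. to ask what the same
#' profiles would look like at another mixing ratio).
#'
#' @param object A `methdecon` fit.
#' @param prevalence Optional replacement prevalence vector; must match
#'   each region's solved number of subpopulations.
#' @param ... Ignored.
#' @return Data frame as in [fitted.methdecon].
#' @export
predict.methdecon <- function(object, prevalence = NULL, ...) {
  if (is.null(prevalence)) return(fitted(object))
  rows <- lapply(object$solutions, function(s) {
    if (s$d_solved < 1L || s$g == 0L) return(NULL)
    if (length(prevalence) != s$d_solved) return(NULL)
    fit <- as.numeric(crossprod(s$profiles, prevalence))
    data.frame(region_id = s$region_id, chrom = s$chrom, start = s$start,
               observed = s$meth_level, fitted = fit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate methylation tables from a fitted deconvolution
#'
#' Parametric simulation: for each region, draws new binomial methylation
#' counts at the observed coverages from the solved profiles and estimated
#' prevalences.
#'
#' @param object A `methdecon` fit.
#' @param nsim Number of simulated tables.
#' @param seed Optional RNG seed.
#' @param ... Ignored.
#' @return List of `nsim` methylation data frames.
#' @export
simulate.methdecon <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      rows <- lapply(object$solutions, function(s) {
        if (s$d_solved < 1L || s$g == 0L) return(NULL)
        simulate_methylation_mixture(s$profiles, s$start, s$prevalence,
                                     s$coverage, chrom = s$chrom,
                                     region_id = s$region_id)
      })
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    })
  })
}

#' Plot a solved region
#'
#' Plots observed fractional methylation against position with the fitted
#' mixture level and one track per solved subpopulation profile.
#'
#' @param x A `methdecon` fit.
#' @param region_id Region to plot (default: the first).
#' @param ... Passed to [graphics::plot].
#' @export
plot.methdecon <- function(x, region_id = NULL, ...) {
  if (is.null(region_id)) region_id <- names(x$solutions)[1]
  s <- x$solutions[[region_id]]
  if (is.null(s)) stop("unknown region id: ", region_id)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(s$start, s$meth_level, ylim = c(-0.1 - 0.15 * s$d_solved, 1),
                 xlab = paste0("position on ", s$chrom),
                 ylab = "methylation (mCG/CG)",
                 main = paste0(region_id, ": ", s$d_solved,
                               " subpopulation(s)"),
                 pch = 16, col = grDevices::grey(0.3), ...)
  fit <- as.numeric(crossprod(s$profiles, s$prevalence))
  graphics::lines(s$start, fit, col = "steelblue", lwd = 2)
  for (k in seq_len(s$d_solved)) {
    y0 <- -0.15 * k
    col <- ifelse(s$profiles[k, ] == 1L, "firebrick", "lightblue")
    graphics::points(s$start, rep(y0, s$g), pch = 15, col = col)
    graphics::text(min(s$start), y0,
                   sprintf("p=%.2f", s$prevalence[k]), pos = 2, xpd = NA,
                   cex = 0.7)
  }
  invisible(x)
}
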