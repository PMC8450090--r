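# Beta-binomial measurement model and HMM emission probabilities.
#
# The emission probability of observing b methylated reads out of n at one
# CpG, given the underlying binary methylation state of each subpopulation,
# combines: which subpopulation each read came from (binomial in the summed
# prevalence p of methylated subpopulations) and measurement error around
# the pure states (two beta-binomial mixtures, m for the methylated and u
# for the unmethylated underlying state). With i reads of methylated origin
# and j of them measured methylated, the total methylated measurement count
# is b = j + (b - j), giving the convolution
#
#   P(b, n) = sum_{i=0}^{n} C(n,i) p^i (1-p)^(n-i)
#             sum_{j} m(i, j) * u(n-i, b-j)
#
# which sums to exactly 1 over b. A variant form inserts the combinatorial
# factor C(i,j) C(n-i,b-j) / C(n,b) into the inner sum (form = "printed");
# since m(i,j) is already the complete probability that j of i
# methylated-origin reads are measured methylated, that factor double-counts
# the read apportionment, the resulting vector no longer sums to 1 over b
# (it is renormalized when the deviation exceeds 1e-6), and at realistic
# coverage the renormalized shape is dominated by the combinatorics rather
# than by p — so the solver uses the convolution form. Both forms agree for
# n = 1. All computation is kept in log space with per-term scaling so no
# probability underflows for n up to 1000.

#' Construct a beta-prior measurement model
#'
#' Holds mixture-of-beta measurement models for the methylated and
#' unmethylated underlying states. Each component is a beta distribution
#' with positive integer shape parameters and a mixture weight; observed
#' methylated read counts under a pure underlying state follow the
#' corresponding mixture of beta-binomials.
#'
#' @param meth_components,unmeth_components Data frames with columns
#'   `alpha`, `beta` (positive integers) and `weight` (weights sum to 1
#'   within each model).
#' @param exact If `TRUE`, the model is an error-free point mass: every read
#'   from a methylated subpopulation is measured methylated and every read
#'   from an unmethylated subpopulation unmethylated. Used for idealized
#'   simulations and oracle checks.
#' @return An object of class `beta_prior`.
#' @export
beta_prior <- function(meth_components = NULL, unmeth_components = NULL,
                       exact = FALSE) {
  if (!exact) {
    check <- function(df, what) {
      stopifnot(is.data.frame(df),
                all(c("alpha", "beta", "weight") %in% names(df)))
      if (any(df$alpha < 1) || any(df$beta < 1) ||
          any(df$alpha != round(df$alpha)) || any(df$beta != round(df$beta))) {
        stop(what, ": alpha/beta must be positive integers")
      }
      if (abs(sum(df$weight) - 1) > 1e-9) {
        stop(what, ": component weights must sum to 1")
      }
      df
    }
    meth_components <- check(meth_components, "meth_components")
    unmeth_components <- check(unmeth_components, "unmeth_components")
  }
  structure(list(meth = meth_components, unmeth = unmeth_components,
                 exact = exact),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  if (x$exact) {
    cat("<beta_prior> exact (error-free measurement)\n")
    return(invisible(x))
  }
  fmt <- function(df) {
    paste(sprintf("Beta(%d,%d) w=%.3g", df$alpha, df$beta, df$weight),
          collapse = " + ")
  }
  cat("<beta_prior>\n  methylated state:   ", fmt(x$meth),
      "\n  unmethylated state: ", fmt(x$unmeth), "\n", sep = "")
  invisible(x)
}

# log pmf of the mixture beta-binomial over k = 0..size for one model side
# ("meth" or "unmeth"). For an exact prior the methylated side is a point
# mass at k = size (all reads measured methylated) and the unmethylated side
# a point mass at k = 0.
mixture_bb_logpmf <- function(size, prior, side = c("meth", "unmeth")) {
  side <- match.arg(side)
  if (prior$exact) {
    lp <- rep(-Inf, size + 1L)
    lp[if (side == "meth") size + 1L else 1L] <- 0
    return(lp)
  }
  comps <- prior[[side]]
  k <- 0:size
  acc <- rep(0, size + 1L)
  for (ci in seq_len(nrow(comps))) {
    a <- comps$alpha[ci]; b <- comps$beta[ci]; w <- comps$weight[ci]
    lp <- lchoose(size, k) + lbeta(k + a, size - k + b) - lbeta(a, b)
    acc <- acc + w * exp(lp)
  }
  log(acc)
}

# Raw (un-normalized) log emission vector over b = 0..n for prevalence-sum p.
emission_table_raw <- function(n, p, prior, form = "convolution") {
  stopifnot(n >= 1)
  b_idx <- 0:n
  ldb <- stats::dbinom(b_idx, n, p, log = TRUE)
  # pure-state shortcut: both forms reduce to a single mixture
  # beta-binomial when p is exactly 0 or 1
  if (p <= 0) return(mixture_bb_logpmf(n, prior, "unmeth"))
  if (p >= 1) return(mixture_bb_logpmf(n, prior, "meth"))

  printed <- identical(form, "printed")
  lch_n <- lchoose(n, b_idx)
  # per-size mixture beta-binomial log pmfs
  lm <- lapply(0:n, function(s) mixture_bb_logpmf(s, prior, "meth"))
  lu <- lapply(0:n, function(s) mixture_bb_logpmf(s, prior, "unmeth"))
  LP <- matrix(-Inf, n + 1L, n + 1L)  # rows i, cols b
  for (i in 0:n) {
    if (!is.finite(ldb[i + 1L])) next
    la <- lm[[i + 1L]]
    lc <- lu[[n - i + 1L]]
    if (printed) {
      la <- la + lchoose(i, 0:i)
      lc <- lc + lchoose(n - i, 0:(n - i))
    }
    ma <- max(la); mc <- max(lc)
    if (!is.finite(ma) || !is.finite(mc)) next
    a <- exp(la - ma)
    cc <- exp(lc - mc)
    # direct convolution: conv[b+1] = sum_j a[j+1] * cc[b-j+1]
    conv <- rep(0, n + 1L)
    for (j in seq_along(a)) {
      span <- j:(j + length(cc) - 1L)
      conv[span] <- conv[span] + a[j] * cc
    }
    pos <- which(conv > 0)
    LP[i + 1L, pos] <- ldb[i + 1L] + ma + mc + log(conv[pos]) -
      if (printed) lch_n[pos] else 0
  }
  apply(LP, 2, logsumexp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Emission probability table for one (coverage, prevalence-sum) pair
#'
#' Computes the log emission probability of every possible methylated read
#' count `b = 0..n` at coverage `n`, given that the subpopulations whose
#' underlying state is methylated have total prevalence `p`.
#'
#' Two algebraic forms are available. `"convolution"` (the default, used by
#' the solver) mixes the binomial read-origin distribution with the
#' convolution of the two beta-binomial measurement models and sums to
#' exactly 1 over `b`. `"printed"` additionally inserts the combinatorial
#' apportionment factor `C(i,j) C(n-i,b-j) / C(n,b)` into the inner sum;
#' that variant loses probability mass over `b` and is renormalized when
#' the deviation exceeds `1e-6` (see the source comments for why it is not
#' used for decoding). The two coincide for `n = 1` and for `p` equal to 0
#' or 1.
#'
#' @param n Coverage (total reads), `n >= 1`.
#' @param p Summed prevalence of methylated subpopulations, in \[0, 1\].
#' @param prior A [beta_prior].
#' @param renormalize Renormalize the emission vector over `b` when its sum
#'   deviates from 1 by more than `1e-6` (default `TRUE`).
#' @param cache Optional environment memoizing tables by `(n, p)`; pass the
#'   same environment across calls with the same prior.
#' @param form `"convolution"` (default) or `"printed"`; see Details.
#' @return Numeric vector of length `n + 1` of log probabilities.
#' @export
emission_table <- function(n, p, prior, renormalize = TRUE, cache = NULL,
                           form = c("convolution", "printed")) {
  form <- match.arg(form)
  key <- NULL
  if (!is.null(cache)) {
    key <- sprintf("%d|%.12g|%d|%s", as.integer(n), p,
                   as.integer(renormalize), form)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  lp <- emission_table_raw(n, p, prior, form = form)
  if (renormalize) {
    s <- logsumexp(lp)
    if (abs(exp(s) - 1) > 1e-6) lp <- lp - s
  }
  if (!is.null(key)) cache[[key]] <- lp
  lp
}

#' Log emission probability of an observed methylated read count
#'
#' Evaluates the emission model for `b` methylated reads out of `n` at one
#' CpG given a joint underlying state (one binary value per subpopulation)
#' and the subpopulation prevalences. The prevalence of the methylated
#' underlying state is `p = sum(prevalence[state == 1])`.
#'
#' @param b Number of methylated reads, `0 <= b <= n`.
#' @param n Coverage, `n >= 1`.
#' @param state Binary vector, one entry per subpopulation.
#' @param prevalence Prevalence vector matching `state` (sums to 1).
#' @param prior A [beta_prior].
#' @inheritParams emission_table
#' @return Log probability (natural log).
#' @export
emission_logprob <- function(b, n, state, prevalence, prior,
                             renormalize = TRUE, cache = NULL,
                             form = c("convolution", "printed")) {
  if (length(n) != 1L || n < 1) stop("n must be a single value >= 1")
  if (length(b) != 1L || b < 0 || b > n) stop("b must satisfy 0 <= b <= n")
  if (length(state) != length(prevalence)) {
    stop("state and prevalence must have the same length")
  }
  p <- sum(prevalence[state == 1])
  emission_table(n, p, prior, renormalize = renormalize, cache = cache,
                 form = form)[b + 1L]
}

# Observed methylated read count from a fractional methylation level;
# deterministic half-up rounding (round() rounds half to even).
meth_count <- function(meth_level, coverage) {
  as.integer(floor(meth_level * coverage + 0.5))
}

#' Fit the beta-prior measurement model to training methylation levels
#'
#' Builds two empirical distributions of fractional methylation on a 0.5%
#' grid — CpGs at 0–40% methylation for the unmethylated-state model and
#' 60–100% for the methylated-state model — and fits each with a mixture of
#' beta densities with positive integer shape parameters, evaluated on the
#' same grid and renormalized, by minimizing the L1 distance to the
#' empirical distribution. The first component is found by exhaustive search
#' over all integer `(alpha, beta)` pairs; further components are added by
#' greedy forward selection over the same candidates and a grid of mixing
#' weights, and kept only if they improve the L1 fit by more than
#' `improve_tol` (relative).
#'
#' @param meth_levels Numeric vector of fractional methylation values in
#'   \[0, 1\] (training CpGs, coverage-filtered), or a data frame with a
#'   `meth_level` column.
#' @param min_cpgs Minimum number of training CpGs (default 10000); with
#'   fewer, fitting errors out and advises using the shipped default prior.
#' @param max_components Maximum mixture components per model (default 3).
#' @param max_shape Upper bound for integer alpha/beta (default 100).
#' @param weight_step Grid step for mixing weights (default 0.05).
#' @param improve_tol Minimum relative L1 improvement required to accept an
#'   additional component (default 0.01).
#' @return A [beta_prior] with an `l1` attribute giving the achieved L1
#'   distances.
#' @export
fit_beta_prior <- function(meth_levels, min_cpgs = 10000, max_components = 3,
                           max_shape = 100, weight_step = 0.05,
                           improve_tol = 0.01) {
  if (is.data.frame(meth_levels)) meth_levels <- meth_levels$meth_level
  meth_levels <- meth_levels[is.finite(meth_levels)]
  if (length(meth_levels) < min_cpgs) {
    stop("only ", length(meth_levels), " training CpGs (< ", min_cpgs,
         "); use default_beta_prior() or supply more data")
  }
  if (any(meth_levels < 0 | meth_levels > 1)) {
    stop("methylation levels must lie in [0, 1]")
  }
  # round to the nearest 0.5% and split into the two state windows
  g <- round(meth_levels * 200)  # grid index 0..200
  emp_dist <- function(idx_range) {
    tab <- tabulate(g[g >= idx_range[1] & g <= idx_range[2]] - idx_range[1] + 1L,
                    nbins = idx_range[2] - idx_range[1] + 1L)
    if (sum(tab) == 0) stop("no training CpGs in the required methylation window")
    tab / sum(tab)
  }
  emp_u <- emp_dist(c(0L, 80L))     # 0%..40%
  emp_m <- emp_dist(c(120L, 200L))  # 60%..100%
  grid_u <- (0:80) / 200
  grid_m <- (120:200) / 200
  fit_u <- fit_beta_mixture(emp_u, grid_u, max_shape, max_components,
                            weight_step, improve_tol)
  fit_m <- fit_beta_mixture(emp_m, grid_m, max_shape, max_components,
                            weight_step, improve_tol)
  out <- beta_prior(meth_components = fit_m$components,
                    unmeth_components = fit_u$components)
  attr(out, "l1") <- c(meth = fit_m$l1, unmeth = fit_u$l1)
  out
}

# Candidate beta densities evaluated on a grid and renormalized; rows are
# (alpha, beta) pairs in column-major order over 1..max_shape.
beta_density_grid <- function(grid, max_shape) {
  ab <- expand.grid(alpha = seq_len(max_shape), beta = seq_len(max_shape))
  D <- matrix(0, nrow(ab), length(grid))
  for (r in seq_len(nrow(ab))) {
    d <- stats::dbeta(grid, ab$alpha[r], ab$beta[r])
    s <- sum(d)
    D[r, ] <- if (s > 0) d / s else 0
  }
  list(ab = ab, D = D)
}

fit_beta_mixture <- function(emp, grid, max_shape, max_components,
                             weight_step, improve_tol) {
  cand <- beta_density_grid(grid, max_shape)
  l1 <- rowSums(abs(sweep(cand$D, 2, emp)))
  best <- which.min(l1)
  comps <- data.frame(alpha = cand$ab$alpha[best], beta = cand$ab$beta[best],
                      weight = 1)
  cur <- cand$D[best, ]
  cur_l1 <- l1[best]
  weights <- seq(weight_step, 1 - weight_step, by = weight_step)
  while (nrow(comps) < max_components) {
    best_new <- NULL
    for (w in weights) {
      mixed <- (1 - w) * matrix(cur, nrow(cand$D), length(grid), byrow = TRUE) +
        w * cand$D
      l1w <- rowSums(abs(sweep(mixed, 2, emp)))
      idx <- which.min(l1w)
      if (is.null(best_new) || l1w[idx] < best_new$l1) {
        best_new <- list(l1 = l1w[idx], idx = idx, w = w)
      }
    }
    if (best_new$l1 >= cur_l1 * (1 - improve_tol)) break
    comps$weight <- comps$weight * (1 - best_new$w)
    comps <- rbind(comps,
                   data.frame(alpha = cand$ab$alpha[best_new$idx],
                              beta = cand$ab$beta[best_new$idx],
                              weight = best_new$w))
    cur <- (1 - best_new$w) * cur + best_new$w * cand$D[best_new$idx, ]
    cur_l1 <- best_new$l1
  }
  comps$weight <- comps$weight / sum(comps$weight)
  list(components = comps, l1 = cur_l1)
}

#' Serialize / read a beta prior
#'
#' @param prior A [beta_prior].
#' @param path File path (JSON).
#' @export
write_beta_prior <- function(prior, path) {
  stopifnot(inherits(prior, "beta_prior"))
  jsonlite::write_json(list(meth = prior$meth, unmeth = prior$unmeth,
                            exact = prior$exact),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_beta_prior
#' @export
read_beta_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (isTRUE(as.logical(obj$exact[1]))) return(beta_prior(exact = TRUE))
  beta_prior(meth_components = as.data.frame(obj$meth),
             unmeth_components = as.data.frame(obj$unmeth))
}

#' Default beta prior
#'
#' The measurement model shipped with the package, fitted with
#' [fit_beta_prior] to the synthetic training corpus produced by
#' [simulate_training_corpus]. It carries a sharp component at each edge of
#' the methylation distribution plus a broader shoulder component,
#' reflecting the spiking-at-the-edges shape of real per-CpG methylation
#' distributions. Refit on your own data when a large training set is
#' available.
#'
#' @return A [beta_prior].
#' @export
default_beta_prior <- function() {
  if (is.null(.methdecon_cache$prior)) {
    path <- system.file("extdata", "default_prior.json",
                        package = "methdecon", mustWork = TRUE)
    .methdecon_cache$prior <- read_beta_prior(path)
  }
  .methdecon_cache$prior
}
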