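# shared builders for small in-code fixtures

make_region <- function(meth, cov, pos = NULL, id = "r1", chrom = "chr1") {
  g <- length(meth)
  if (is.null(pos)) pos <- seq(0, by = 50, length.out = g)
  cov <- rep_len(cov, g)
  meth_region(region_id = id, chrom = chrom, start = pos, end = pos + 1L,
              meth_level = meth, coverage = cov)
}

# hand-built region_solution, for i-DMR and output tests
make_solution <- function(profiles, pos = NULL, prevalence = NULL,
                          logprob_by_d = c(-100, -90), id = "r1",
                          chrom = "chr1", end = NULL) {
  profiles <- as.matrix(profiles)
  d <- nrow(profiles); g <- ncol(profiles)
  if (is.null(pos)) pos <- seq(0, by = 50, length.out = g)
  if (is.null(end)) end <- pos + 1L
  if (is.null(prevalence)) prevalence <- rev(seq_len(d)) / sum(seq_len(d))
  structure(list(region_id = id, chrom = chrom, start = as.integer(pos),
                 end = as.integer(end), g = g, d_solved = d,
                 profiles = profiles, prevalence = prevalence,
                 logprob_by_d = logprob_by_d,
                 meth_level = colMeans(profiles), coverage = rep(60, g)),
            class = "region_solution")
}

# one batch of read-level two-population mixtures at a fixed minor
# prevalence, deconvolved as a single sample (prevalence estimated from the
# pooled CpG levels); returns per-region accuracies and the d = 2
# prevalence estimate
recovery_batch <- function(minor, n_regions, seed0, g = 20, coverage = 55,
                           meas_error = 0.01) {
  prev_true <- c(1 - minor, minor)
  tabs <- vector("list", n_regions)
  refs <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    pos <- synthetic_cpg_positions(g, seed = seed0 + i)
    states <- simulate_reference_profiles(pos, 2, seed = seed0 + 1000 + i)
    sim <- simulate_read_mixture(states, pos, prev_true, coverage,
                                 region = c(min(pos) - 100, max(pos) + 100),
                                 meas_error = meas_error,
                                 seed = seed0 + 2000 + i)
    sim$table$region_id <- paste0("r", i)
    tabs[[i]] <- sim$table
    refs[[i]] <- list(states = states, pos = pos)
  }
  fit <- methdecon(do.call(rbind, tabs), d_max = 3, quiet = TRUE)
  acc_major <- rep(NA_real_, n_regions)
  acc_minor <- rep(NA_real_, n_regions)
  for (i in seq_len(n_regions)) {
    s <- fit$solutions[[paste0("r", i)]]
    if (is.null(s) || s$d_solved < 2) next
    idx <- match(s$start, refs[[i]]$pos)
    refmat <- refs[[i]]$states[, idx, drop = FALSE]
    res <- assign_profiles(s$profiles[1:2, , drop = FALSE], refmat,
                           ref_names = c("major", "minor"))
    acc_major[i] <- res$accuracy[1]
    acc_minor[i] <- res$accuracy[2]
  }
  list(acc_major = acc_major, acc_minor = acc_minor,
       prev_est = as.numeric(coef(fit, 2)),
       frac_multi = mean(vapply(fit$solutions,
                                function(s) s$d_solved >= 2, logical(1))))
}

# small single-component priors used across tests
prior_A <- function() beta_prior(
  meth_components = data.frame(alpha = 5, beta = 1, weight = 1),
  unmeth_components = data.frame(alpha = 1, beta = 5, weight = 1))

prior_B <- function() beta_prior(
  meth_components = data.frame(alpha = 3, beta = 2, weight = 1),
  unmeth_components = data.frame(alpha = 2, beta = 4, weight = 1))

# mirror of prior_B: meth/unmeth swapped with reflected shapes
prior_B_mirror <- function() beta_prior(
  meth_components = data.frame(alpha = 4, beta = 2, weight = 1),
  unmeth_components = data.frame(alpha = 2, beta = 3, weight = 1))
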