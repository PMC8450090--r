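# Independent oracles: exhaustive state-sequence enumeration for the HMM
# decoder, and a direct L1 grid search for the beta fit. Emission oracle
# values (exact-rational direct summation of the double sum, computed with
# arbitrary-precision rational arithmetic) are frozen in
# emission_oracle.csv.

# Brute-force decoder: scores every one of (2^d)^g state sequences and
# returns the best. Shares only the emission/transition primitives with the
# implementation; the path search itself is independent of the Viterbi DP.
enumerate_viterbi <- function(region, d, prevalence, transitions, prior,
                              cache = NULL) {
  g <- region$g
  S <- 2L^d
  bits <- matrix(vapply(0:(S - 1L), function(s) {
    as.integer(bitwAnd(bitwShiftR(s, (d - 1L):0L), 1L))
  }, integer(d)), nrow = d)
  b <- floor(region$meth_level * region$coverage + 0.5)
  emis <- matrix(0, g, S)
  for (k in seq_len(g)) {
    for (s in seq_len(S)) {
      emis[k, s] <- emission_logprob(b[k], region$coverage[k], bits[, s],
                                     prevalence, prior, cache = cache)
    }
  }
  statio <- stationary_distribution(transitions)
  linit <- vapply(seq_len(S), function(s) {
    sum(log(ifelse(bits[, s] == 1L, statio["M"], statio["U"])))
  }, numeric(1))
  ltr <- list()
  if (g > 1) {
    gaps <- diff(region$start)
    for (k in seq_len(g - 1L)) {
      Tm <- log(transition_lookup(transitions, gaps[k]))
      jt <- matrix(0, S, S)
      for (a in seq_len(S)) for (bb in seq_len(S)) {
        jt[a, bb] <- sum(Tm[cbind(bits[, a] + 1L, bits[, bb] + 1L)])
      }
      ltr[[k]] <- jt
    }
  }
  seqs <- as.matrix(rev(expand.grid(rep(list(seq_len(S)), g)))[, g:1, drop = FALSE])
  # rows enumerate sequences; score each
  score <- linit[seqs[, 1]] + emis[cbind(1L, seqs[, 1])]
  if (g > 1) {
    for (k in 2:g) {
      score <- score + ltr[[k - 1L]][cbind(seqs[, k - 1L], seqs[, k])] +
        emis[cbind(k, seqs[, k])]
    }
  }
  best <- which.max(score)
  list(logprob = score[best], states = seqs[best, ] - 1L, scores = score)
}

# independent single-component L1 minimizer over a bounded integer shape
# grid, used to confirm the beta-prior fit
l1_beta_oracle <- function(emp, grid, max_shape = 20) {
  ab <- expand.grid(alpha = seq_len(max_shape), beta = seq_len(max_shape))
  l1 <- numeric(nrow(ab))
  for (r in seq_len(nrow(ab))) {
    d <- stats::dbeta(grid, ab$alpha[r], ab$beta[r])
    d <- d / sum(d)
    l1[r] <- sum(abs(d - emp))
  }
  ord <- order(l1)
  list(alpha = ab$alpha[ord[1]], beta = ab$beta[ord[1]], l1 = l1[ord[1]],
       second_l1 = l1[ord[2]])
}

# empirical distribution of levels on the 0.5% grid restricted to a window,
# mirroring the documented fitting procedure (recomputed independently here)
emp_on_grid <- function(levels, lo_idx, hi_idx) {
  gidx <- round(levels * 200)
  tab <- tabulate(gidx[gidx >= lo_idx & gidx <= hi_idx] - lo_idx + 1L,
                  nbins = hi_idx - lo_idx + 1L)
  tab / sum(tab)
}
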