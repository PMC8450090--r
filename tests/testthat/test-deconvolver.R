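test_that("Viterbi decoding matches exhaustive enumeration on random instances", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  set.seed(202)
  for (i in 1:40) {
    d <- sample(1:2, 1)
    g <- sample(1:5, 1)
    pos <- cumsum(sample(c(5:500, 1500), g, TRUE))
    cov <- sample(4:12, g, TRUE)
    meth <- round(runif(g), 2)
    region <- make_region(meth, cov, pos)
    prev <- if (d == 1) 1 else {
      a <- sample(50:99, 1) / 100
      c(a, 1 - a)
    }
    cache <- new.env(parent = emptyenv())
    vit <- viterbi_region(region, d, prev, trans, prior, cache = cache)
    oracle <- enumerate_viterbi(region, d, prev, trans, prior, cache = cache)
    expect_equal(vit$logprob, oracle$logprob, tolerance = 1e-9)
    gap <- sort(oracle$scores, decreasing = TRUE)
    if (length(gap) > 1 && gap[1] - gap[2] > 1e-9) {
      expect_equal(vit$states, unname(oracle$states))
    }
  }
})

test_that("single-CpG regions reduce to an argmax over initial x emission", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  region <- make_region(0.95, 40, pos = 100)
  vit <- viterbi_region(region, 2, c(0.6, 0.4), trans, prior)
  statio <- stationary_distribution(trans)
  scores <- vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(st) {
    sum(log(ifelse(st == 1, statio["M"], statio["U"]))) +
      emission_logprob(meth_count(0.95, 40), 40, st, c(0.6, 0.4), prior)
  }, numeric(1))
  expect_equal(vit$logprob, max(scores))
  expect_equal(as.numeric(vit$profiles), c(1, 1))
})

test_that("noise-free pure regions decode to their pure profile", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  region <- make_region(rep(1, 8), 60)
  vit <- viterbi_region(region, 1, 1, trans, prior)
  expect_equal(as.numeric(vit$profiles), rep(1, 8))
  region0 <- make_region(rep(0, 8), 60)
  vit0 <- viterbi_region(region0, 1, 1, trans, prior)
  expect_equal(as.numeric(vit0$profiles), rep(0, 8))
})

test_that("termination keeps homogeneous regions at one subpopulation", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  region <- make_region(rep(0, 10), 60)
  sol <- solve_region(region, list(1, c(0.6, 0.4), c(0.5, 0.3, 0.2)),
                      trans, prior)
  expect_equal(sol$d_solved, 1L)
  expect_equal(as.numeric(sol$profiles), rep(0, 10))
  # the rejected candidate's log probability was recorded and is not better
  expect_length(sol$logprob_by_d, 2)
  expect_lte(sol$logprob_by_d[2], sol$logprob_by_d[1])
})

test_that("a 50:50 mixture of constant complementary profiles solves with d = 2 exactly", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  pos <- synthetic_cpg_positions(10, seed = 31)
  states <- rbind(rep(1L, 10), rep(0L, 10))
  tab <- simulate_methylation_mixture(states, pos, c(0.5, 0.5), 60, seed = 32)
  region <- as_meth_regions(tab)[[1]]
  sol <- solve_region(region, list(1, c(0.5, 0.5), c(0.4, 0.3, 0.3)),
                      trans, prior)
  expect_equal(sol$d_solved, 2L)
  expect_setequal(apply(sol$profiles, 1, paste, collapse = ""),
                  c(paste(rep(1, 10), collapse = ""),
                    paste(rep(0, 10), collapse = "")))
  expect_gt(sol$logprob_by_d[2], sol$logprob_by_d[1])
})

test_that("d_max caps the search even when improvements continue", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  pos <- synthetic_cpg_positions(10, seed = 41)
  states <- rbind(rep(1L, 10), rep(0L, 10))
  tab <- simulate_methylation_mixture(states, pos, c(0.5, 0.5), 60, seed = 42)
  region <- as_meth_regions(tab)[[1]]
  sol <- solve_region(region, list(1, c(0.5, 0.5)), trans, prior, d_max = 1)
  expect_equal(sol$d_solved, 1L)
  expect_length(sol$logprob_by_d, 1)
})

test_that("the solver halts on arbitrary random regions", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  set.seed(77)
  cache <- new.env(parent = emptyenv())
  for (i in 1:60) {
    g <- sample(2:8, 1)
    region <- make_region(round(runif(g), 2), sample(4:30, 1),
                          pos = cumsum(sample(10:2000, g, TRUE)))
    sol <- solve_region(region, list(1, c(0.7, 0.3), c(0.5, 0.3, 0.2)),
                        trans, prior, cache = cache)
    expect_true(sol$d_solved %in% 1:3)
    expect_length(sol$logprob_by_d, min(sol$d_solved + 1, 3))
  }
})

test_that("complementing the data with mirrored priors complements the profiles", {
  # a U/M-symmetric transition model, so the symmetry is exact
  uniform2 <- function(stay) {
    matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2, byrow = TRUE,
           dimnames = list(c("U", "M"), c("U", "M")))
  }
  trans <- structure(list(bin_edges = c(50, 100, 200, 500, 1000),
                          matrices = lapply(c(0.95, 0.9, 0.85, 0.75, 0.65,
                                              0.55), uniform2),
                          counts = rep(list(matrix(0, 2, 2)), 6)),
                     class = "transition_model")
  set.seed(55)
  g <- 12
  pos <- cumsum(sample(20:300, g, TRUE))
  # integer methylated counts on both strands of the complement, so that
  # b -> n - b holds exactly after rounding
  cov <- rep(40, g)
  meth <- sample(0:20, g, TRUE) / 20
  region <- make_region(meth, cov, pos)
  # complement observations exactly: b -> n - b
  region_c <- make_region(1 - meth, cov, pos)
  prev <- c(0.65, 0.35)
  vit <- viterbi_region(region, 2, prev, trans, prior_B())
  vit_c <- viterbi_region(region_c, 2, prev, trans, prior_B_mirror())
  expect_equal(vit_c$profiles, 1L - vit$profiles)
  expect_equal(vit_c$logprob, vit$logprob, tolerance = 1e-9)
})

test_that("empty regions yield warnings and null solutions without aborting", {
  trans <- default_transition_model()
  prior <- default_beta_prior()
  empty <- meth_region("none", "chr1", integer(0), integer(0), numeric(0),
                       numeric(0))
  expect_warning(sol <- solve_region(empty, list(1), trans, prior),
                 "no CpGs")
  expect_equal(sol$d_solved, 0L)
  expect_equal(sol$g, 0L)
})

test_that("the full fit estimates prevalence, solves regions and orders profiles", {
  pos <- synthetic_cpg_positions(20, seed = 61)
  states <- rbind(c(rep(1L, 10), rep(0L, 10)), rep(0L, 20))
  tab <- simulate_methylation_mixture(states, pos, c(0.7, 0.3), 80, seed = 62)
  fit <- methdecon(tab, d_max = 2, quiet = TRUE)
  expect_s3_class(fit, "methdecon")
  s <- fit$solutions[[1]]
  expect_equal(s$d_solved, 2L)
  expect_true(all(diff(s$prevalence) <= 0))
  # profile of the major (0.7) subpopulation is the block profile
  expect_equal(as.numeric(s$profiles[1, ]), as.numeric(states[1, ]))
  expect_equal(as.numeric(s$profiles[2, ]), as.numeric(states[2, ]))
  expect_equal(as.numeric(coef(fit, 2)), c(0.7, 0.3), tolerance = 0.06)
})

test_that("transition mass penalizes duplicated profiles (termination argument)", {
  # duplicating the profile leaves emissions unchanged but multiplies in
  # extra transition probability, so the joint log probability drops
  trans <- default_transition_model()
  prior <- default_beta_prior()
  region <- make_region(rep(1, 6), 50)
  v1 <- viterbi_region(region, 1, 1, trans, prior)
  v2 <- viterbi_region(region, 2, c(0.5, 0.5), trans, prior)
  expect_lt(v2$logprob, v1$logprob)
})
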