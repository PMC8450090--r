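test_that("methylation-level mixtures follow the prevalence dot product", {
  pos <- c(0, 50, 100)
  states <- rbind(c(1L, 0L, 1L), c(0L, 0L, 1L))
  tab <- simulate_methylation_mixture(states, pos, c(0.3, 0.7), 1000,
                                      seed = 1)
  # expected levels 0.3, 0, 1; at coverage 1000 the draws are close
  expect_equal(tab$meth_level, c(0.3, 0, 1), tolerance = 0.08)
  expect_equal(tab$coverage, rep(1000, 3))
  expect_equal(tab$start, pos)

  # determinism and seed sensitivity
  t1 <- simulate_methylation_mixture(states, pos, c(0.3, 0.7), 20, seed = 5)
  t2 <- simulate_methylation_mixture(states, pos, c(0.3, 0.7), 20, seed = 5)
  t3 <- simulate_methylation_mixture(states, pos, c(0.3, 0.7), 20, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))

  # mismatched profile positions error
  profs <- list(list(positions = c(0, 50), states = c(1, 0)),
                list(positions = c(0, 60), states = c(1, 0)))
  expect_error(simulate_methylation_mixture(profs, prevalence = c(0.5, 0.5),
                                            coverage = 10),
               "same CpG positions")
})

test_that("binomial sampling concentrates at the expected level", {
  g <- 10000
  pos <- seq_len(g) * 10
  states <- rbind(rep(1L, g), rep(0L, g))
  cov <- 40
  p <- 0.35
  tab <- simulate_methylation_mixture(states, pos, c(p, 1 - p), cov,
                                      seed = 99)
  se <- sqrt(p * (1 - p) / (cov * g))
  expect_lt(abs(mean(tab$meth_level) - p), 3 * se)
})

test_that("read-level mixtures use the coverage*size/length read count", {
  pos <- seq(500, 9500, by = 90)
  states <- rbind(rep(1L, length(pos)), rep(0L, length(pos)))
  sim <- simulate_read_mixture(states, pos, c(0.5, 0.5), coverage = 20,
                               read_length = 100, region = c(0, 10000),
                               seed = 3)
  expect_length(sim$reads, 2000)  # 20 * 10000 / 100

  # collapsed coverage equals the number of covering reads per CpG
  cover_count <- vapply(pos, function(P) {
    sum(vapply(sim$reads, function(r) P >= r$start && P < r$end, logical(1)))
  }, numeric(1))
  expect_equal(sim$table$coverage, cover_count[cover_count > 0])
  expect_true(all(sim$table$meth_level >= 0 & sim$table$meth_level <= 1))

  expect_error(simulate_read_mixture(states, pos, c(0.5, 0.5), 20,
                                     read_length = 100, region = c(0, 80)),
               "shorter than read_length")
})

test_that("error-free single-source reads collapse to the binary profile", {
  pos <- seq(100, 1900, by = 60)
  prof <- matrix(rep(c(1L, 0L), length.out = length(pos)), 1)
  sim <- simulate_read_mixture(prof, pos, 1, coverage = 30,
                               read_length = 100, region = c(0, 2000),
                               meas_error = 0, seed = 8)
  idx <- match(sim$table$start, pos)
  expect_equal(sim$table$meth_level, as.numeric(prof[1, idx]))
})

test_that("source sampling is stochastic: realized proportions vary", {
  pos <- seq(100, 4900, by = 50)
  states <- rbind(rep(1L, length(pos)), rep(0L, length(pos)))
  fracs <- vapply(1:8, function(s) {
    sim <- simulate_read_mixture(states, pos, c(0.7, 0.3), 10,
                                 read_length = 100, region = c(0, 5000),
                                 seed = s)
    mean(vapply(sim$reads, function(r) r$source == 1L, logical(1)))
  }, numeric(1))
  expect_gt(stats::var(fracs), 0)
  expect_equal(mean(fracs), 0.7, tolerance = 0.05)
})

test_that("partial-read classification follows the in-region mixed-call rule", {
  mk <- function(start, end, positions, calls) {
    list(start = start, end = end, positions = positions,
         calls = as.integer(calls), source = 1L)
  }
  reads <- list(
    mk(0, 100, c(10, 40, 70), c(1, 1, 1)),    # uniform: non-partial
    mk(0, 100, c(10, 40, 70), c(1, 0, 1)),    # mixed: partial
    mk(0, 100, c(10, 40, 70), c(0, 0, 0)),    # uniform: non-partial
    mk(150, 250, c(160, 200), c(0, 1)),       # outside region entirely
    # straddles the boundary: out-of-region call 0 at 95, in-region 1,1
    mk(95, 195, c(95, 110, 140), c(0, 1, 1)),
    # single in-region CpG: counted non-partial
    mk(90, 190, c(95, 110), c(1, 0))
  )
  res <- classify_partial_reads(reads, region = c(100, 150))
  # overlapping reads: the straddler and the single-CpG read only
  expect_equal(res$n_total, 2)
  expect_equal(res$n_partial, 0)

  res2 <- classify_partial_reads(reads, region = c(0, 100))
  expect_equal(res2$n_total, 5)  # all but the fully-outside read
  expect_equal(res2$n_partial, 1)
})

test_that("distinct-pattern counting groups cell types not separated by DMRs", {
  full <- matrix(TRUE, 3, 3); diag(full) <- FALSE
  expect_equal(count_distinct_patterns(full), 3)
  none <- matrix(FALSE, 3, 3)
  expect_equal(count_distinct_patterns(none), 1)
  # only A-B separated: C indistinguishable from both, all grouped
  ab <- matrix(FALSE, 3, 3); ab[1, 2] <- ab[2, 1] <- TRUE
  expect_equal(count_distinct_patterns(ab), 1)
  # pair format
  pairs <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                      dmr = c(TRUE, TRUE, TRUE))
  expect_equal(count_distinct_patterns(pairs), 3)
  pairs2 <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                       dmr = c(TRUE, TRUE, FALSE))
  expect_equal(count_distinct_patterns(pairs2), 2)
})

test_that("profile and position generators satisfy their invariants", {
  pos <- synthetic_cpg_positions(500, seed = 21)
  expect_length(pos, 500)
  expect_false(is.unsorted(pos, strictly = TRUE))
  profs <- simulate_reference_profiles(pos, 3, seed = 22)
  expect_equal(dim(profs), c(3, 500))
  expect_true(all(profs %in% 0:1))
  # persistence: neighbouring CpGs agree far more often than chance
  agree <- mean(profs[1, -1] == profs[1, -500])
  expect_gt(agree, 0.6)

  corpus <- simulate_training_corpus(n_cpgs = 2000, seed = 23)
  expect_equal(nrow(corpus), 2000)
  expect_true(all(corpus$meth_level >= 0 & corpus$meth_level <= 1))
  expect_true(all(corpus$coverage >= 4))
  expect_identical(corpus, simulate_training_corpus(n_cpgs = 2000, seed = 23))
})
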