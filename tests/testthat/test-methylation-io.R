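test_that("methylation table parsing, filtering and round trips work", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t101\t0.5\t20\tgeneA",
               "chr1\t150\t151\t1\t30\tgeneA",
               "chr1\t50\t51\t0\t3\tgeneA",      # below coverage floor
               "chr2\t10\t11\t0.2\t1200\tgeneB", # above coverage ceiling
               "chr2\t40\t41\t0.8\t4\tgeneB"), tf)
  expect_message(regs <- read_methylation_table(tf), "2 record\\(s\\) dropped")
  expect_length(regs, 2)
  a <- regs[["geneA"]]
  expect_s3_class(a, "meth_region")
  expect_equal(a$g, 2)
  expect_equal(a$start, c(100L, 150L))
  expect_equal(a$meth_level, c(0.5, 1))
  expect_equal(a$coverage, c(20, 30))
  expect_equal(regs[["geneB"]]$coverage, 4)  # bound is inclusive

  # custom bounds keep everything
  all_regs <- read_methylation_table(tf, coverage_min = 0,
                                     coverage_max = Inf, quiet = TRUE)
  expect_equal(sum(vapply(all_regs, function(r) r$g, integer(1))), 5)

  # write -> reread is the identity on the in-filter records
  out <- withr::local_tempfile(fileext = ".tsv")
  write_methylation_table(regs, out)
  again <- read_methylation_table(out, quiet = TRUE)
  expect_equal(regions_to_table(again), regions_to_table(regs))
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1\t2\t0.5\t10\ta", "chr1\t5\t6\t0.5\t10"), tf)
  expect_error(read_methylation_table(tf), "line 2")

  writeLines(c("chr1\t1\t2\tmeth\t10\ta"), tf)
  expect_error(read_methylation_table(tf), "non-numeric")

  writeLines(c("chr1\t1\t2\t1.5\t10\ta"), tf)
  expect_error(read_methylation_table(tf), "outside \\[0, 1\\]")

  writeLines(c("chr1\t5\t5\t0.5\t10\ta"), tf)
  expect_error(read_methylation_table(tf), "end must exceed")

  # duplicate start positions surface the strand-collapsing ambiguity
  df <- data.frame(chrom = "chr1", start = c(5, 5), end = c(6, 6),
                   meth_level = c(0, 1), coverage = c(10, 10),
                   region_id = "a")
  expect_error(as_meth_regions(df), "duplicate")

  df$start <- c(5, 6); df$end <- c(6, 7); df$chrom <- c("chr1", "chr2")
  expect_error(as_meth_regions(df), "multiple chromosomes")
})

test_that("region grouping sorts by position and keeps records exactly once", {
  set.seed(42)
  pos <- sample.int(10000, 40)
  df <- data.frame(chrom = "chr3", start = pos, end = pos + 1,
                   meth_level = runif(40), coverage = 10,
                   region_id = rep(c("x", "y"), 20))
  regs <- as_meth_regions(df)
  expect_length(regs, 2)
  for (r in regs) expect_false(is.unsorted(r$start, strictly = TRUE))
  back <- regions_to_table(regs)
  expect_equal(nrow(back), 40)
  expect_setequal(back$start, pos)
})

test_that("promoter windows follow TSS, strand, autosome and cmpl rules", {
  ann <- data.frame(
    name2 = c("g1", "g1", "g2", "g3", "g4", "g5"),
    chrom = c("chr1", "chr1", "chr2", "chrX", "chr2", "chr2"),
    strand = c("+", "+", "-", "+", "+", "+"),
    txStart = c(100000, 200000, 50000, 1000, 7000, 30000),
    txEnd = c(110000, 210000, 60000, 2000, 8000, 31000),
    cdsStartStat = c("cmpl", "cmpl", "cmpl", "cmpl", "incmpl", "cmpl"),
    cdsEndStat = c("cmpl", "cmpl", "cmpl", "cmpl", "cmpl", "cmpl"),
    stringsAsFactors = FALSE)
  win <- make_promoter_windows(ann, flank = 5000)
  # g1 first transcript only, g3 on chrX excluded, g4 incomplete excluded
  expect_setequal(win$region_id, c("g1", "g2", "g5"))
  g1 <- win[win$region_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(95000, 105000))
  # minus strand: TSS is txEnd
  g2 <- win[win$region_id == "g2", ]
  expect_equal(c(g2$start, g2$end), c(55000, 65000))
  # all windows have width exactly 2 * flank
  expect_equal(win$end - win$start, rep(10000, 3))
  # negative start clipped at 0 with a warning
  ann_small <- ann[6, ]; ann_small$txStart <- 2000
  expect_warning(w2 <- make_promoter_windows(ann_small, flank = 5000),
                 "clipped")
  expect_equal(w2$start, 0)
  expect_lt(w2$end - w2$start, 10000)
})

test_that("solution writer emits profile rows, summaries and round-trips", {
  sol <- make_solution(matrix(c(1L, 0L, 1L), 1), pos = c(0, 30, 60),
                       prevalence = 1, logprob_by_d = -12.5)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_solution(list(sol), prefix)
  prof <- read_solution_profiles(paths[["profiles"]])
  expect_equal(nrow(prof), 3)  # one region, d = 1, 3 CpGs
  expect_equal(prof$state, c(1, 0, 1))
  expect_equal(prof$subpop, rep(1, 3))

  # d = 2 round trip reproduces the states per subpopulation
  sol2 <- make_solution(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
                        prevalence = c(0.7, 0.3), id = "r2")
  paths2 <- write_solution(list(sol2), file.path(withr::local_tempdir(), "p"))
  prof2 <- read_solution_profiles(paths2[["profiles"]])
  for (k in 1:2) {
    got <- prof2$state[prof2$subpop == k][order(prof2$start[prof2$subpop == k])]
    expect_equal(got, unname(sol2$profiles[k, ]))
  }

  # empty solution list: header-only files
  paths3 <- write_solution(list(), file.path(withr::local_tempdir(), "e"))
  for (p in paths3) {
    lines <- readLines(p)
    expect_length(lines, 1)
    expect_match(lines, "^#")
  }
  expect_equal(nrow(read_solution_profiles(paths3[["profiles"]])), 0)
})

test_that("region BED reader and region assignment agree", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\twinA", "chr1\t50\t150\twinB"), bed)
  regions <- read_region_bed(bed)
  expect_equal(regions$region_id, c("winA", "winB"))
  tab <- data.frame(chrom = "chr1", start = c(10, 75, 140), end = c(11, 76, 141),
                    meth_level = c(0, 1, 0.5), coverage = 10,
                    region_id = "orig")
  out <- assign_regions(tab, regions)
  # CpG at 75 falls in both windows and appears once per window
  expect_equal(sum(out$start == 75), 2)
  expect_setequal(unique(out$region_id), c("winA", "winB"))
  expect_equal(sum(out$region_id == "winA"), 2)
  expect_error(assign_regions(tab[3, ], regions[1, , drop = FALSE]),
               "no CpGs")
})
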