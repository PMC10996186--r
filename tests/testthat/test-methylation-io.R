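test_that("coverage files round-trip with recomputed levels and sorted positions", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t3001\t3001\t100.0\t5\t0",
               "chr1\t2001\t2001\t0.0\t0\t4",
               "chr2\t10\t10\t50.0\t2\t2"), f)
  calls <- read_coverage_file(f)
  expect_equal(calls$pos, c(2001L, 3001L, 10L))   # sorted within chrom
  expect_equal(calls$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(calls[pos == 3001, n_meth], 5L)
  expect_equal(calls[pos == 3001, n_unmeth], 0L)

  # out-of-order input matches an independently re-sorted oracle
  shuf <- calls[sample(.N)]
  f2 <- withr::local_tempfile(fileext = ".cov")
  write_coverage_file(shuf, f2)
  oracle <- shuf[order(chrom, pos)]
  expect_equal(read_coverage_file(f2), oracle, ignore_attr = TRUE)

  # gzip transparently supported
  f3 <- withr::local_tempfile(fileext = ".cov.gz")
  write_coverage_file(calls, f3)
  expect_equal(read_coverage_file(f3), calls, ignore_attr = TRUE)
})

test_that("coverage parsing rejects malformed input with a line number", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(character(), f)
  expect_equal(nrow(read_coverage_file(f)), 0L)

  writeLines(c("chr1\t100\t100\t50\t1\t1", "chr1\t200\t200\t50\tx\t1"), f)
  expect_error(read_coverage_file(f), "line 2")

  writeLines(c("chr1\t100\t100\t50\t-1\t1"), f)
  expect_error(read_coverage_file(f), "negative")
})

test_that("strand merging sums dyad counts and passes unknown sites through", {
  dyads <- data.table(chrom = "chr1", pos = c(100L, 500L))
  calls <- make_calls("chr1", c(100, 101, 500, 777), c(3, 2, 1, 4), c(1, 2, 0, 4))
  m <- merge_strands(calls, dyads)
  expect_equal(m[pos == 100, .(n_meth, n_unmeth)], data.table(n_meth = 5L, n_unmeth = 3L))
  expect_equal(m[pos == 500, n_meth], 1L)       # lone plus-strand record unchanged
  expect_equal(m[pos == 777, n_unmeth], 4L)     # not a known dyad: untouched
  expect_false(any(duplicated(m[, .(chrom, pos)])))
})

test_that("random dyad splits merge back to the pre-split totals", {
  set.seed(42)
  for (rep in 1:5) {
    truth <- random_calls(200)
    dyads <- truth[, .(chrom, pos)]
    mp <- rbinom(nrow(truth), truth$n_meth, 0.5)
    up <- rbinom(nrow(truth), truth$n_unmeth, 0.5)
    split <- rbind(
      make_calls(truth$chrom, truth$pos, mp, up),
      make_calls(truth$chrom, truth$pos + 1L, truth$n_meth - mp, truth$n_unmeth - up)
    )[n_meth + n_unmeth > 0]
    merged <- merge_strands(split, dyads)
    expect_equal(merged, truth[order(chrom, pos)], ignore_attr = TRUE)
  }
})

test_that("coverage filter keeps the closed depth interval and is idempotent", {
  calls <- make_calls("chr1", 1:5 * 100, c(1, 2, 50, 60, 80), c(1, 1, 50, 41, 21))
  # depths: 2, 3, 100, 101, 101
  f <- filter_coverage(calls)
  expect_equal(f$pos, c(200L, 300L))
  expect_equal(filter_coverage(f), f)
  set.seed(1)
  rc <- filter_coverage(random_calls(500, max_depth = 150), 3, 100)
  expect_true(all(rc$n_meth + rc$n_unmeth >= 3 & rc$n_meth + rc$n_unmeth <= 100))
  expect_error(filter_coverage(calls, min_reads = 0), "min_reads")
  expect_equal(nrow(filter_coverage(make_calls("chr1", 100, 0, 0))), 0L)
})

test_that("replicate pooling sums counts and matches a depth-weighted oracle", {
  a <- make_calls("chr1", 100, 5, 0)
  b <- make_calls("chr1", 100, 0, 5)
  p <- pool_replicates(list(a, b))
  expect_equal(p$n_meth, 5L); expect_equal(p$n_unmeth, 5L)
  expect_equal(pool_replicates(list(a), refilter = FALSE), a, ignore_attr = TRUE)
  expect_error(pool_replicates(list()), "at least one")

  # pooled global level equals the depth-weighted mean of inputs (100 sites)
  set.seed(7)
  pos <- sort(sample.int(1e6, 100))
  s1 <- make_calls("chr1", pos, rbinom(100, 20, 0.3), 20 - rbinom(100, 20, 0.3))
  s2 <- make_calls("chr1", pos, rbinom(100, 10, 0.6), 10 - rbinom(100, 10, 0.6))
  pooled <- pool_replicates(list(s1, s2), refilter = FALSE)
  oracle <- sum(s1$n_meth + s2$n_meth) /
    sum(s1$n_meth + s1$n_unmeth + s2$n_meth + s2$n_unmeth)
  expect_equal(global_level(pooled), oracle)
})

test_that("strand merging and pooling commute", {
  set.seed(11)
  dyads <- data.table(chrom = "chr1", pos = sort(sample(seq(10, 1e5, by = 10), 300)))
  mk <- function() {
    d <- sample(0:20, nrow(dyads), replace = TRUE)
    m <- rbinom(nrow(dyads), d, 0.4)
    plus <- make_calls("chr1", dyads$pos, rbinom(nrow(dyads), m, 0.5), rbinom(nrow(dyads), d - m, 0.5))
    minus <- make_calls("chr1", dyads$pos + 1L, m - plus$n_meth, d - m - plus$n_unmeth)
    rbind(plus, minus)[n_meth + n_unmeth > 0]
  }
  s1 <- mk(); s2 <- mk()
  route1 <- pool_replicates(list(merge_strands(s1, dyads), merge_strands(s2, dyads)),
                            refilter = FALSE)
  route2 <- merge_strands(pool_replicates(list(s1, s2), refilter = FALSE), dyads)
  expect_equal(route1, route2, ignore_attr = TRUE)
})

test_that("conversion rate is read from the spike-in contig", {
  spike <- make_calls("lambda_spike", 1:10 * 50, 0, 10)
  expect_equal(conversion_rate(spike), 1.0)
  spike2 <- make_calls("lambda_spike", 1:10 * 50, c(2, rep(0, 9)), c(18, rep(20, 9)))
  expect_equal(conversion_rate(spike2), 0.99)
  expect_warning(r <- conversion_rate(make_calls("chr1", 100, 1, 1)), "spike-in")
  expect_true(is.na(r))

  # binomial simulation: conversion error 0.005 at total depth 2000
  set.seed(5)
  m <- rbinom(100, 20, 0.005)
  sim <- make_calls("lambda_spike", 1:100 * 50, m, 20 - m)
  expect_lt(abs(conversion_rate(sim) - 0.995), 0.005)
})

test_that("replicate correlation is symmetric with unit self-correlation", {
  set.seed(9)
  s <- random_calls(5000, max_pos = 5e6, max_depth = 20)
  s <- filter_coverage(s)
  expect_equal(replicate_correlation(s, s), 1.0)
  inv <- copy(s)[, c("n_meth", "n_unmeth") := .(n_unmeth, n_meth)]
  expect_equal(replicate_correlation(s, inv), -1.0)
  other <- filter_coverage(random_calls(5000, max_pos = 5e6, max_depth = 20))
  expect_lt(abs(replicate_correlation(s, other) - replicate_correlation(other, s)), 1e-12)
  expect_error(replicate_correlation(s[1:3], s[1:3]), "fewer than 2")
})

test_that("two replicates simulated from one truth correlate above 0.9", {
  g <- build_genome(tiny_spec(), seed = 21)
  r1 <- filter_coverage(simulate_sample(g, "FGO", "control", replicate = 1, seed = 21))
  r2 <- filter_coverage(simulate_sample(g, "FGO", "control", replicate = 2, seed = 21))
  expect_gte(replicate_correlation(r1, r2), 0.9)
})

test_that("sample metadata enforces its enumerations", {
  m <- sample_meta("E13.5", "KO", "female", "r2")
  expect_s3_class(m, "sample_meta")
  expect_error(sample_meta("E14.5", "KO"), "arg")
  expect_error(sample_meta("E13.5", "het"), "arg")
})
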