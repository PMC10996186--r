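# two deterministic samples over one window with prescribed per-site counts
two_sample_window <- function(f_ctl, f_ko, depth = 20, chrom = "chr1") {
  n <- length(f_ctl)
  pos <- seq(100, by = 100, length.out = n)
  list(control = make_calls(chrom, pos, round(f_ctl * depth), depth - round(f_ctl * depth)),
       ko = make_calls(chrom, pos, round(f_ko * depth), depth - round(f_ko * depth)))
}

test_that("cleanly separated windows are called hyper, identical ones are not", {
  s <- two_sample_window(rep(0.05, 20), rep(0.25, 20))
  d <- call_dmrs(s$control, s$ko)
  expect_equal(nrow(d$hyper), 1L)
  expect_equal(d$hyper$direction, "hyper")
  expect_equal(d$hyper$delta, 20)
  expect_equal(d$universe_size, 1L)

  same <- call_dmrs(s$control, s$control)
  expect_equal(same$windows$delta, 0)
  expect_equal(nrow(same$hyper) + nrow(same$hypo), 0L)
})

test_that("the 10-point threshold is strict", {
  # constant fractions 0.10 vs 0.20: delta exactly 10.0, zero variance
  s <- two_sample_window(rep(0.10, 10), rep(0.20, 10), depth = 10)
  d <- call_dmrs(s$control, s$ko)
  expect_equal(d$windows$delta, 10)
  expect_equal(d$windows$p_value, 0)     # unequal means, both variances zero
  expect_equal(nrow(d$hyper), 0L)        # not > 10
  d2 <- call_dmrs(s$control, s$ko, delta_threshold = 9.999)
  expect_equal(nrow(d2$hyper), 1L)
})

test_that("zero-variance windows with equal means get p = 1", {
  s <- two_sample_window(rep(0.5, 10), rep(0.5, 10), depth = 10)
  d <- call_dmrs(s$control, s$ko)
  expect_equal(d$windows$p_value, 1)
})

test_that("swapping control and KO maps hyper to hypo exactly", {
  g <- build_genome(tiny_spec(), seed = 31)
  ctl <- filter_coverage(simulate_sample(g, "E11.5", "control", seed = 31))
  ko <- filter_coverage(simulate_sample(g, "E11.5", "KO", seed = 31))
  fwd <- call_dmrs(ctl, ko)
  rev <- call_dmrs(ko, ctl)
  expect_equal(fwd$hyper[, .(chrom, start)], rev$hypo[, .(chrom, start)])
  expect_equal(fwd$hypo[, .(chrom, start)], rev$hyper[, .(chrom, start)])
  expect_equal(fwd$windows$delta, -rev$windows$delta)

  # monotonicity: a stricter delta threshold never yields more DMRs
  for (thr in c(5, 10, 20, 30)) {
    d_lo <- call_dmrs(ctl, ko, delta_threshold = thr)
    d_hi <- call_dmrs(ctl, ko, delta_threshold = thr + 5)
    expect_lte(nrow(d_hi$hyper) + nrow(d_hi$hypo),
               nrow(d_lo$hyper) + nrow(d_lo$hypo))
  }
})

test_that("vectorized Welch test matches stats::t.test window by window", {
  set.seed(13)
  ctl_list <- list(); ko_list <- list()
  for (i in 1:8) {
    n <- sample(5:30, 1)
    pos <- (i - 1) * 10000 + seq(100, by = 150, length.out = n)
    d1 <- sample(5:40, n, replace = TRUE); d2 <- sample(5:40, n, replace = TRUE)
    m1 <- rbinom(n, d1, 0.3); m2 <- rbinom(n, d2, runif(1, 0.2, 0.6))
    ctl_list[[i]] <- make_calls("chr1", pos, m1, d1 - m1)
    ko_list[[i]] <- make_calls("chr1", pos, m2, d2 - m2)
  }
  ctl <- rbindlist(ctl_list); ko <- rbindlist(ko_list)
  d <- call_dmrs(ctl, ko)
  expect_equal(d$universe_size, 8L)
  for (i in seq_len(nrow(d$windows))) {
    w <- d$windows[i]
    fc <- ctl[(pos - 1) %/% 10000 * 10000 == w$start, n_meth / (n_meth + n_unmeth)]
    fk <- ko[(pos - 1) %/% 10000 * 10000 == w$start, n_meth / (n_meth + n_unmeth)]
    ref <- stats::t.test(fk, fc)      # Welch by default, two-sided
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("windows must be informative in both samples and share >= 2 sites", {
  ctl <- make_calls("chr1", seq(100, 900, by = 100), 5, 5)      # 9 CpGs
  ko <- make_calls("chr1", seq(100, 400, by = 100), 5, 5)       # only 4 CpGs
  d <- call_dmrs(ctl, ko)
  expect_equal(d$universe_size, 0L)                             # KO side below min_cpg
  ko2 <- make_calls("chr1", c(seq(100, 500, by = 100), 5000), 8, 2)
  d2 <- call_dmrs(ctl, ko2, min_cpg = 5)
  expect_equal(d2$universe_size, 1L)
  expect_equal(d2$windows$n_shared, 5L)
})

test_that("DMR summaries reproduce the count system and BED output", {
  s <- dmr_summary(14395, 223)
  expect_equal(s$n_total, 14618)
  expect_equal(s$hyper_size_mb, 143.95)
  expect_equal(dmr_summary(0, 0)$n_total, 0)

  sw <- two_sample_window(rep(0.05, 20), rep(0.45, 20))
  d <- call_dmrs(sw$control, sw$ko)
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(d, f)
  bed <- fread(f, header = FALSE)
  expect_equal(nrow(bed), 1L)
  expect_equal(bed$V4, "hyper")
  sm <- summarize_dmrs(d)
  expect_equal(sm$n_hyper, 1L)
  expect_equal(sm$universe_size, 1L)
})
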