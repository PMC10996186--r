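# DMR calling on the fixed 10-kb grid.
#
# A window is a DMR when the KO-minus-control difference in weighted
# methylation exceeds 10 percentage points in magnitude (strict inequality)
# and a two-sided Welch t-test across the per-CpG methylation fractions of the
# sites shared by both (pooled) samples gives p < 0.05. Replicates are pooled
# before windowing, so the CpG sites within a window are the replication unit
# of the test.

#' Call differentially methylated 10-kb windows between control and KO
#'
#' Both samples must be pooled, coverage-filtered and on the same genome. A
#' window enters the tested universe when it holds at least `min_cpg`
#' informative CpGs in *both* samples and at least 2 shared sites (needed for
#' the t-test). `delta` is the difference of the window's weighted levels
#' (KO minus control) in percentage points; `p_value` is a two-sided Welch
#' t-test across the per-CpG site fractions of shared sites. Degenerate
#' zero-variance windows get p = 1 when the group means agree and p = 0 when
#' they differ.
#'
#' @param control_calls,ko_calls Pooled, coverage-filtered CpG call tables.
#' @param window_size Grid window size in bp (default 10 kb).
#' @param min_cpg Minimum informative CpGs per window per sample (default 5).
#' @param delta_threshold DMR threshold on `|delta|` in percentage points,
#'   strict (default 10).
#' @param alpha Significance threshold on the raw p-value, strict
#'   (default 0.05). No multiple-testing correction is applied: the definition
#'   is a joint effect-size + raw-p filter.
#' @param exclude_contigs Contigs excluded from the grid.
#' @return An object of class `"dmr_set"`: a list with `windows` (all tested
#'   windows with levels, `delta`, `p_value`, `direction`), `hyper`, `hypo`
#'   (subsets), `universe_size`, and the calling parameters.
#' @export
call_dmrs <- function(control_calls, ko_calls, window_size = 10000L, min_cpg = 5L,
                      delta_threshold = 10, alpha = 0.05,
                      exclude_contigs = "lambda_spike") {
  assert_calls(control_calls); assert_calls(ko_calls)
  w_ctl <- window_levels(control_calls, window_size, min_cpg, exclude_contigs)
  w_ko <- window_levels(ko_calls, window_size, min_cpg, exclude_contigs)
  win <- merge(w_ctl[, .(chrom, start, end, n_cpg_control = n_cpg, level_control = level)],
               w_ko[, .(chrom, start, n_cpg_ko = n_cpg, level_ko = level)],
               by = c("chrom", "start"))

  ctl <- as_calls_dt(control_calls); ko <- as_calls_dt(ko_calls)
  if (length(exclude_contigs)) {
    ctl <- ctl[!chrom %in% exclude_contigs]
    ko <- ko[!chrom %in% exclude_contigs]
  }
  shared <- merge(ctl[, .(chrom, pos, f_ctl = n_meth / (n_meth + n_unmeth))],
                  ko[, .(chrom, pos, f_ko = n_meth / (n_meth + n_unmeth))],
                  by = c("chrom", "pos"))
  shared[, wstart := window_start(pos, window_size)]
  st <- shared[, .(n_shared = .N,
                   m_ctl = mean(f_ctl), m_ko = mean(f_ko),
                   v_ctl = var(f_ctl), v_ko = var(f_ko)),
               by = .(chrom, start = wstart)]
  st <- st[n_shared >= 2L]

  win <- merge(win, st, by = c("chrom", "start"))
  if (nrow(win) == 0) {
    wt <- welch_p(numeric(0), numeric(0), numeric(0), numeric(0), integer(0), integer(0))
  } else {
    wt <- welch_p(win$m_ctl, win$m_ko, win$v_ctl, win$v_ko, win$n_shared, win$n_shared)
  }
  win[, `:=`(t_stat = wt$t, p_value = wt$p)]
  win[, delta := 100 * (level_ko - level_control)]
  win[, direction := fifelse(delta > delta_threshold & p_value < alpha, "hyper",
                      fifelse(delta < -delta_threshold & p_value < alpha, "hypo", "none"))]
  setorder(win, chrom, start)
  structure(list(
    windows = win[],
    hyper = win[direction == "hyper"],
    hypo = win[direction == "hypo"],
    universe_size = nrow(win),
    params = list(window_size = as.integer(window_size), min_cpg = as.integer(min_cpg),
                  delta_threshold = delta_threshold, alpha = alpha)
  ), class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("DMR set: ", nrow(x$hyper), " hyper / ", nrow(x$hypo), " hypo of ",
      x$universe_size, " tested ", x$params$window_size / 1000, "-kb windows",
      " (|delta| > ", x$params$delta_threshold, " pp, p < ", x$params$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Summary record for hyper-/hypomethylated window counts
#'
#' Computes the count system associated with a DMR set: total regions, the
#' hyper/hypo split, and the genomic footprint of each class
#' (`count * window_size`). Usable directly on counts so that printed count
#' tables can be fed through the same code path as pipeline output.
#'
#' @param n_hyper,n_hypo Window counts.
#' @param window_size Window size in bp (default 10 kb).
#' @return One-row `data.table` with `n_total`, `n_hyper`, `n_hypo`,
#'   `hyper_size_bp`, `hypo_size_bp`, `hyper_size_mb`, `hypo_size_mb`,
#'   `total_size_mb`.
#' @export
dmr_summary <- function(n_hyper, n_hypo, window_size = 10000L) {
  stopifnot(n_hyper >= 0, n_hypo >= 0, window_size > 0)
  data.table(
    n_total = n_hyper + n_hypo, n_hyper = n_hyper, n_hypo = n_hypo,
    hyper_size_bp = n_hyper * window_size, hypo_size_bp = n_hypo * window_size,
    hyper_size_mb = n_hyper * window_size / 1e6,
    hypo_size_mb = n_hypo * window_size / 1e6,
    total_size_mb = (n_hyper + n_hypo) * window_size / 1e6
  )
}

#' Summarize a DMR set
#'
#' @param dmrset A `"dmr_set"` from [call_dmrs()].
#' @return One-row `data.table`; see [dmr_summary()].
#' @export
summarize_dmrs <- function(dmrset) {
  stopifnot(inherits(dmrset, "dmr_set"))
  s <- dmr_summary(nrow(dmrset$hyper), nrow(dmrset$hypo), dmrset$params$window_size)
  s[, universe_size := dmrset$universe_size]
  s[]
}

#' Write DMRs as a BED6+ table
#'
#' Columns: chrom, start, end, name (direction), score (delta), strand (`.`),
#' p_value.
#'
#' @param dmrset A `"dmr_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrset, path) {
  stopifnot(inherits(dmrset, "dmr_set"))
  dmr <- rbind(dmrset$hyper, dmrset$hypo)
  setorder(dmr, chrom, start)
  out <- dmr[, .(chrom, start, end, name = direction,
                 score = round(delta, 4), strand = ".", p_value = signif(p_value, 6))]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

utils::globalVariables(c("n_cpg_control", "n_cpg_ko", "t_stat", "universe_size", "strand"))
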