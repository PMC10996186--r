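# Regional methylation: global, fixed-grid windowed, and arbitrary-interval
# read-weighted CG methylation levels.
#
# All levels are *weighted*: summed methylated read counts divided by summed
# total reads over the region. This is depth-robust and the field's standard
# summary; a mean of per-site fractions would let shallow sites dominate.

#' Global CG methylation level
#'
#' Weighted methylation level over all retained sites, excluding any spike-in
#' contig.
#'
#' @param calls Coverage-filtered CpG call table.
#' @param exclude_contigs Contigs (e.g. the unmethylated spike-in) to exclude.
#' @return Fraction in `[0, 1]`.
#' @export
global_level <- function(calls, exclude_contigs = "lambda_spike") {
  assert_calls(calls)
  dt <- as_calls_dt(calls)
  if (length(exclude_contigs)) dt <- dt[!chrom %in% exclude_contigs]
  tot <- sum(dt$n_meth + dt$n_unmeth)
  if (nrow(dt) == 0 || tot == 0) stop("global_level() undefined: no retained sites")
  sum(dt$n_meth) / tot
}

#' Windowed CG methylation on a fixed genomic grid
#'
#' Tiles each chromosome with non-overlapping windows anchored at coordinate 0
#' and reports the weighted methylation level of every window containing at
#' least `min_cpg` informative CpG sites. Window identity is
#' (`chrom`, `start`), so windows are directly comparable across samples and
#' stages.
#'
#' @param calls Coverage-filtered CpG call table.
#' @param window_size Window size in bp (default 10 kb).
#' @param min_cpg Minimum informative CpG sites for a window to be reported
#'   (default 5).
#' @param exclude_contigs Contigs excluded from the grid (default: the
#'   spike-in).
#' @return A `data.table` with `chrom`, `start` (0-based), `end` (exclusive),
#'   `n_cpg`, `meth_reads`, `total_reads`, `level`, ordered genomically.
#' @export
window_levels <- function(calls, window_size = 10000L, min_cpg = 5L,
                          exclude_contigs = "lambda_spike") {
  assert_calls(calls)
  if (window_size <= 0) stop("window_size must be positive")
  dt <- as_calls_dt(calls)
  if (length(exclude_contigs)) dt <- dt[!chrom %in% exclude_contigs]
  ws <- as.integer(window_size)
  dt[, wstart := window_start(pos, ws)]
  out <- dt[, .(n_cpg = .N, meth_reads = sum(n_meth),
                total_reads = sum(n_meth + n_unmeth)),
            by = .(chrom, start = wstart)]
  out <- out[n_cpg >= min_cpg]
  out[, end := start + ws]
  out[, level := meth_reads / total_reads]
  setorder(out, chrom, start)
  setcolorder(out, c("chrom", "start", "end", "n_cpg", "meth_reads", "total_reads", "level"))
  out[]
}

#' Weighted methylation level of one genomic interval
#'
#' Computes the read-weighted level over CpG sites whose 0-based position lies
#' in `[start, end)`. Returns `NA` when fewer than `min_cpg` informative sites
#' fall in the interval.
#'
#' @param calls Coverage-filtered CpG call table.
#' @param chrom Chromosome name.
#' @param start 0-based interval start.
#' @param end Exclusive interval end.
#' @param min_cpg Minimum informative sites (default 1).
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
interval_level <- function(calls, chrom, start, end, min_cpg = 1L) {
  lv <- interval_levels(calls,
                        data.table(chrom = chrom, start = start, end = end),
                        min_cpg = min_cpg)
  lv$level[1]
}

#' Weighted methylation levels of a set of intervals
#'
#' Vectorized form of [interval_level()]: one weighted level per input
#' interval (0-based half-open coordinates). A CpG at 1-based position `p`
#' belongs to an interval iff `p - 1` lies in `[start, end)`.
#'
#' @param calls Coverage-filtered CpG call table.
#' @param intervals Table with `chrom`, `start`, `end` (0-based half-open);
#'   extra columns are carried through.
#' @param min_cpg Minimum informative sites per interval.
#' @return `intervals` with added `n_cpg`, `meth_reads`, `total_reads`,
#'   `level` (`NA` below `min_cpg`).
#' @export
interval_levels <- function(calls, intervals, min_cpg = 1L) {
  assert_calls(calls)
  iv <- as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) && any(iv$start >= iv$end)) stop("intervals must satisfy start < end")
  dt <- as_calls_dt(calls)
  out <- copy(iv)
  out[, `:=`(n_cpg = 0L, meth_reads = 0L, total_reads = 0L, level = NA_real_)]
  if (nrow(dt) && nrow(iv)) {
    lv <- union(unique(dt$chrom), unique(iv$chrom))
    calls_gr <- GenomicRanges::GRanges(factor(dt$chrom, lv),
                                       IRanges::IRanges(dt$pos, dt$pos))
    iv_gr <- GenomicRanges::GRanges(factor(iv$chrom, lv),
                                    IRanges::IRanges(iv$start + 1L, iv$end))
    hits <- GenomicRanges::findOverlaps(calls_gr, iv_gr)
    if (length(hits)) {
      hdt <- data.table(site = S4Vectors::queryHits(hits), iv = S4Vectors::subjectHits(hits))
      hdt[, `:=`(n_meth = dt$n_meth[site], n_unmeth = dt$n_unmeth[site])]
      agg <- hdt[, .(n_cpg = .N, meth_reads = sum(n_meth),
                     total_reads = sum(n_meth + n_unmeth)), by = iv]
      out[agg$iv, `:=`(n_cpg = agg$n_cpg, meth_reads = agg$meth_reads,
                       total_reads = agg$total_reads)]
    }
  }
  out[n_cpg >= min_cpg & total_reads > 0, level := meth_reads / total_reads]
  out[]
}

utils::globalVariables(c("site", "iv"))
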