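# Histone-mark enrichment over the 10-kb grid and its relation to
# methylation change.

#' Per-window ChIP enrichment score
#'
#' Library-size-normalized log2 IP/input ratio with a pseudocount:
#' `score = log2((ip_w / IP_total + eps) / (input_w / Input_total + eps))`,
#' where `eps = pseudocount / sqrt(IP_total * Input_total)` stabilizes empty
#' windows. IP proportional to input everywhere gives identically zero
#' scores; a window holding twice its expected IP share scores ~1 at large
#' counts.
#'
#' @param counts Per-window count table with `chrom`, `start` (0-based
#'   window starts on the grid), `ip`, `input`; an `end` column is carried
#'   through if present.
#' @param mark Mark name attached to the result (e.g. `"H3K9me3"`).
#' @param pseudocount Pseudocount on the normalized shares (default 1).
#' @return A `data.table` ("mark track") with `chrom`, `start`, `score`,
#'   attribute `mark`.
#' @export
window_enrichment <- function(counts, mark = "mark", pseudocount = 1) {
  dt <- as.data.table(counts)
  stopifnot(all(c("chrom", "start", "ip", "input") %in% names(dt)))
  if (any(dt$ip < 0) || any(dt$input < 0)) stop("negative ChIP counts")
  ip_total <- sum(as.numeric(dt$ip)); input_total <- sum(as.numeric(dt$input))
  if (ip_total <= 0 || input_total <= 0) stop("library sizes must be positive")
  eps <- pseudocount / sqrt(ip_total * input_total)
  out <- dt[, .(chrom, start,
                score = log2((ip / ip_total + eps) / (input / input_total + eps)))]
  if ("end" %in% names(dt)) out[, end := dt$end]
  setorder(out, chrom, start)
  setattr(out, "mark", mark)
  out[]
}

#' Top-quantile windows of a mark track
#'
#' Returns the `ceiling(q * N)` highest-scoring windows. Ties are broken by
#' genomic order (the track's row order), which makes the selection
#' deterministic; nesting holds: the top-q set is contained in every top-q'
#' set with q' >= q.
#'
#' @param track Mark track from [window_enrichment()] (or any table with
#'   `chrom`, `start`, `score`).
#' @param q Quantile in (0, 1); default 0.05 (top 5%).
#' @return Subset of `track` rows in genomic order.
#' @export
top_quantile_windows <- function(track, q = 0.05) {
  dt <- as.data.table(track)
  stopifnot(all(c("chrom", "start", "score") %in% names(dt)))
  if (!(q > 0 && q < 1)) stop("q must lie strictly between 0 and 1")
  k <- ceiling(q * nrow(dt))
  idx <- order(-dt$score)[seq_len(k)] # base order is stable: ties keep genomic order
  out <- dt[sort(idx)]
  out[]
}

set_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    return(list(n = 0L, median = NA_real_, q25 = NA_real_, q75 = NA_real_))
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(values), median = qs[2], q25 = qs[1], q75 = qs[3])
}

#' Compare mark enrichment and methylation between two window sets
#'
#' For each of two window sets on the grid, reports the median and quartiles
#' of the mark score and of the control and KO methylation levels — the
#' numeric backbone of violin-style comparisons of hypermethylated vs other
#' regions.
#'
#' @param track Mark track (`chrom`, `start`, `score`).
#' @param set_a,set_b Window sets (`chrom`, `start`).
#' @param window_levels_control,window_levels_ko Optional [window_levels()]
#'   tables supplying methylation distributions.
#' @param labels Length-2 character labels for the sets.
#' @return `data.table` with one row per set and statistic
#'   (`set`, `statistic`, `n`, `median`, `q25`, `q75`).
#' @export
mark_vs_methylation <- function(track, set_a, set_b,
                                window_levels_control = NULL,
                                window_levels_ko = NULL,
                                labels = c("A", "B")) {
  track <- as.data.table(track)
  sets <- list(as.data.table(set_a), as.data.table(set_b))
  rows <- list()
  for (i in 1:2) {
    s <- sets[[i]][, .(chrom, start)]
    if (nrow(s) == 0) warning("window set '", labels[i], "' is empty")
    sc <- merge(s, track, by = c("chrom", "start"))
    rows[[length(rows) + 1]] <- c(list(set = labels[i], statistic = "mark_score"),
                                  set_summary(sc$score))
    if (!is.null(window_levels_control)) {
      lv <- merge(s, as.data.table(window_levels_control), by = c("chrom", "start"))
      rows[[length(rows) + 1]] <- c(list(set = labels[i], statistic = "level_control"),
                                    set_summary(lv$level))
    }
    if (!is.null(window_levels_ko)) {
      lv <- merge(s, as.data.table(window_levels_ko), by = c("chrom", "start"))
      rows[[length(rows) + 1]] <- c(list(set = labels[i], statistic = "level_ko"),
                                    set_summary(lv$level))
    }
  }
  rbindlist(rows)
}
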