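# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a count relative to an explicit denominator
#'
#' Used throughout the fate/summary stages so that every reported percentage
#' carries its denominator. Raw (unrounded) values are returned; rounding to
#' the nearest integer is a display decision left to callers.
#'
#' @param n Count (numerator).
#' @param d Denominator; must be > 0.
#' @param digits Optional rounding digits; `NULL` (default) leaves the value
#'   unrounded.
#' @return `100 * n / d`, optionally rounded.
#' @examples
#' percent_of(12407, 72907) # ~17
#' @export
percent_of <- function(n, d, digits = NULL) {
  stopifnot(is.numeric(n), is.numeric(d), all(d > 0))
  p <- 100 * n / d
  if (!is.null(digits)) p <- round(p, digits)
  p
}

# 0-based start of the fixed tiling window containing a 1-based position
window_start <- function(pos, window_size) {
  ((as.integer(pos) - 1L) %/% as.integer(window_size)) * as.integer(window_size)
}

# canonical window identifier used for cross-stage comparison
window_id <- function(chrom, start) paste0(chrom, ":", start)

# validate a CpG call table (chrom, pos, n_meth, n_unmeth)
assert_calls <- function(calls, arg = deparse(substitute(calls))) {
  if (!is.data.frame(calls)) stop(arg, " must be a data.frame/data.table of CpG calls")
  need <- c("chrom", "pos", "n_meth", "n_unmeth")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop(arg, " is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(calls) && (any(calls$n_meth < 0) || any(calls$n_unmeth < 0)))
    stop(arg, " contains negative read counts")
  invisible(TRUE)
}

as_calls_dt <- function(calls) {
  dt <- as.data.table(calls)[, .(chrom = as.character(chrom), pos = as.integer(pos),
                                 n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  setorder(dt, chrom, pos)
  dt[]
}

# Deterministic 32-bit sub-seed derived from a master seed and string labels.
# Keeps every derived seed strictly below 2^31.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(labels)) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

# clamp numeric vector into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

# Welch two-sample t-test from summary statistics, vectorized.
# Degenerate rule: pooled standard error 0 -> p = 1 when means agree, 0 when
# they differ (all mass at two distinct points leaves no doubt).
welch_p <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- is.finite(m1) & is.finite(m2) & se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  tstat[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m2[degen] - m1[degen]))
  list(t = tstat, df = df, p = p)
}
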