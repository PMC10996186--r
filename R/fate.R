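# Cross-stage persistence of hypermethylated windows.
#
# Windows are compared across stages by fixed-grid identity (chrom:start), not
# by interval overlap: all stages are windowed on the same 0-anchored 10-kb
# grid, so the same coordinates name the same region everywhere.

fate_stage_order <- c("E11.5", "E13.5", "E16.5", "FGO")

# extract hyper-window ids from a dmr_set, a window table, or an id vector
hyper_ids <- function(x) {
  if (inherits(x, "dmr_set")) return(window_id(x$hyper$chrom, x$hyper$start))
  if (is.data.frame(x)) {
    dt <- as.data.table(x)
    stopifnot(all(c("chrom", "start") %in% names(dt)))
    return(window_id(dt$chrom, dt$start))
  }
  as.character(x)
}

#' Classify the cross-stage fate of hypermethylated windows
#'
#' Takes per-stage hypermethylated window sets (as `"dmr_set"` objects, window
#' tables, or window-id vectors) named by stage (`E11.5`, `E13.5`, `E16.5`,
#' `FGO`; any subset) and partitions the union of flagged windows into
#' persistence categories by set algebra:
#'
#' * `persistent_to_FGO` — hyper at E13.5 or E16.5 *and* in FGOs;
#' * `PGC_only` — hyper at E13.5 or E16.5 but resolved before the FGO stage;
#' * `FGO_only` — hyper only in FGOs;
#' * `E11.5_and_FGO` — hyper at E11.5 and again in FGOs but at neither
#'   intermediate stage;
#' * `lost_after_E11.5` — hyper at E11.5 only.
#'
#' A companion count table reports the derived set sizes (remained at E13.5
#' only / E16.5 only / both / lost; pairwise and triple stage intersections;
#' category sizes) with explicit denominators and raw percentages via
#' [percent_of()].
#'
#' @param dmr_sets Named list of per-stage hyper-window sets. All grids must
#'   match (checked when `"dmr_set"` objects carry their window size).
#' @return An object of class `"fate_table"`: list with `windows`
#'   (`window`, one logical flag per stage, `category`), `counts`
#'   (`name`, `count`, `denominator`, `percent`), and `stages`.
#' @export
classify_fates <- function(dmr_sets) {
  stopifnot(is.list(dmr_sets), length(dmr_sets) >= 2, !is.null(names(dmr_sets)))
  stages <- names(dmr_sets)
  unknown <- setdiff(stages, fate_stage_order)
  if (length(unknown)) stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  ws <- unique(unlist(lapply(dmr_sets, function(x)
    if (inherits(x, "dmr_set")) x$params$window_size else NULL)))
  if (length(ws) > 1) stop("stage DMR sets are on different window grids: ",
                           paste(ws, collapse = " vs "))
  sets <- lapply(dmr_sets, hyper_ids)
  universe <- sort(unique(unlist(sets)))
  flags <- data.table(window = universe)
  for (st in fate_stage_order)
    flags[, (paste0("hyper_", st)) := universe %in% (sets[[st]] %||% character())]

  e11 <- flags$hyper_E11.5; e13 <- flags$hyper_E13.5
  e16 <- flags$hyper_E16.5; fgo <- flags$hyper_FGO
  pgc_late <- e13 | e16
  flags[, category := fifelse(pgc_late & fgo, "persistent_to_FGO",
                       fifelse(pgc_late, "PGC_only",
                        fifelse(fgo & e11, "E11.5_and_FGO",
                         fifelse(fgo, "FGO_only", "lost_after_E11.5"))))]

  n <- function(x) sum(x)
  counts <- list()
  add <- function(name, count, denom) {
    counts[[length(counts) + 1]] <<- data.table(
      name = name, count = count, denominator = denom,
      percent = if (denom > 0) percent_of(count, denom) else NA_real_)
  }
  add(paste0("hyper_E11.5"), n(e11), length(universe))
  add(paste0("hyper_E13.5"), n(e13), length(universe))
  add(paste0("hyper_E16.5"), n(e16), length(universe))
  add(paste0("hyper_FGO"), n(fgo), length(universe))
  if (n(e11) > 0) {
    add("remained_E13.5_only", n(e11 & e13 & !e16), n(e11))
    add("remained_E16.5_only", n(e11 & !e13 & e16), n(e11))
    add("remained_both", n(e11 & e13 & e16), n(e11))
    add("remained_any", n(e11 & (e13 | e16)), n(e11))
    add("lost_after_E11.5", n(e11 & !e13 & !e16 & !fgo), n(e11))
    add("E11.5_in_FGO", n(e11 & fgo), n(e11))
  }
  if (n(e13) > 0) {
    add("E13.5_in_E16.5", n(e13 & e16), n(e13))
    add("E13.5_in_FGO", n(e13 & fgo), n(e13))
    add("persistent_of_E13.5", n(e13 & e16 & fgo), n(e13))
  }
  if (n(e16) > 0) {
    add("E16.5_in_FGO", n(e16 & fgo), n(e16))
    add("persistent_of_E16.5", n(e13 & e16 & fgo), n(e16))
  }
  cat_counts <- flags[, .N, by = category]
  for (i in seq_len(nrow(cat_counts)))
    add(paste0("category_", cat_counts$category[i]), cat_counts$N[i], length(universe))

  structure(list(windows = flags[], counts = rbindlist(counts), stages = stages),
            class = "fate_table")
}

#' @export
print.fate_table <- function(x, ...) {
  cat("Fate table over", nrow(x$windows), "windows flagged in >=1 stage (",
      paste(x$stages, collapse = ", "), ")\n")
  print(x$windows[, .N, by = category])
  invisible(x)
}

#' Per-window methylation-difference matrix across stages
#'
#' Builds the (windows x stages) matrix of KO-minus-control differences in
#' percentage points, row-ordered by a mark track's score (descending) — the
#' numeric content of a persistence heatmap.
#'
#' @param stage_levels Named list: per stage, a list with elements `control`
#'   and `ko`, each a [window_levels()] table on the shared grid.
#' @param order_by Optional mark track (`chrom`, `start`, `score`) used to
#'   sort rows by descending score; unscored windows sort last.
#' @return `data.table` with `window`, `chrom`, `start`, one
#'   `delta_<stage>` column per stage, and `order_score`.
#' @export
delta_matrix <- function(stage_levels, order_by = NULL) {
  stopifnot(is.list(stage_levels), length(stage_levels) >= 1, !is.null(names(stage_levels)))
  deltas <- lapply(names(stage_levels), function(st) {
    pair <- stage_levels[[st]]
    m <- merge(as.data.table(pair$control)[, .(chrom, start, level_control = level)],
               as.data.table(pair$ko)[, .(chrom, start, level_ko = level)],
               by = c("chrom", "start"))
    m[, .(chrom, start, delta = 100 * (level_ko - level_control))]
  })
  names(deltas) <- names(stage_levels)
  out <- NULL
  for (st in names(deltas)) {
    d <- deltas[[st]]
    setnames(d, "delta", paste0("delta_", st))
    out <- if (is.null(out)) d else merge(out, d, by = c("chrom", "start"), all = TRUE)
  }
  out[, window := window_id(chrom, start)]
  if (!is.null(order_by)) {
    tr <- as.data.table(order_by)[, .(chrom, start, order_score = score)]
    out <- merge(out, tr, by = c("chrom", "start"), all.x = TRUE)
    setorder(out, -order_score, chrom, start, na.last = TRUE)
  } else {
    out[, order_score := NA_real_]
    setorder(out, chrom, start)
  }
  setcolorder(out, c("window", "chrom", "start"))
  out[]
}

#' Per-category mark and FGO-methylation profiles
#'
#' For each fate category, the median and quartiles of a mark score and of
#' control/KO FGO methylation levels.
#'
#' @param fate A `"fate_table"` from [classify_fates()].
#' @param track Optional mark track (`chrom`, `start`, `score`).
#' @param fgo_levels_control,fgo_levels_ko Optional [window_levels()] tables
#'   for FGO samples.
#' @return `data.table` with `category`, `statistic`, `n`, `median`, `q25`,
#'   `q75`.
#' @export
category_profiles <- function(fate, track = NULL, fgo_levels_control = NULL,
                              fgo_levels_ko = NULL) {
  stopifnot(inherits(fate, "fate_table"))
  win <- copy(fate$windows)
  parts <- tstrsplit(win$window, ":", fixed = TRUE)
  win[, `:=`(chrom = parts[[1]], start = as.integer(parts[[2]]))]
  rows <- list()
  for (cat_nm in sort(unique(win$category))) {
    s <- win[category == cat_nm, .(chrom, start)]
    if (nrow(s) == 0) { warning("empty fate category: ", cat_nm); next }
    if (!is.null(track)) {
      sc <- merge(s, as.data.table(track), by = c("chrom", "start"))
      rows[[length(rows) + 1]] <- c(list(category = cat_nm, statistic = "mark_score"),
                                    set_summary(sc$score))
    }
    if (!is.null(fgo_levels_control)) {
      lv <- merge(s, as.data.table(fgo_levels_control), by = c("chrom", "start"))
      rows[[length(rows) + 1]] <- c(list(category = cat_nm, statistic = "fgo_level_control"),
                                    set_summary(lv$level))
    }
    if (!is.null(fgo_levels_ko)) {
      lv <- merge(s, as.data.table(fgo_levels_ko), by = c("chrom", "start"))
      rows[[length(rows) + 1]] <- c(list(category = cat_nm, statistic = "fgo_level_ko"),
                                    set_summary(lv$level))
    }
  }
  rbindlist(rows)
}

utils::globalVariables(c("hyper_E11.5", "hyper_E13.5", "hyper_E16.5", "hyper_FGO",
                         "order_score", "N"))
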