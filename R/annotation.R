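# Genomic-context annotation of DMRs, repeat-family methylation aggregation,
# and ICR methylation fold-changes.

#' Bundle genome annotations
#'
#' @param repeats Table of repeat copies: `chrom`, `start`, `end` (0-based
#'   half-open), `family`, `class` (e.g. LTR, LINE, SINE, satellite).
#' @param genes Optional gene intervals: `chrom`, `start`, `end`, `name`.
#' @param exons Optional exon intervals: `chrom`, `start`, `end`, `name`
#'   (gene).
#' @param icrs Optional imprinting-control-region intervals: `chrom`, `start`,
#'   `end`, `name` (unique).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(repeats, genes = NULL, exons = NULL, icrs = NULL,
                           chrom_sizes = NULL) {
  repeats <- as.data.table(repeats)
  stopifnot(all(c("chrom", "start", "end", "family", "class") %in% names(repeats)))
  if (!is.null(icrs)) {
    icrs <- as.data.table(icrs)
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(icrs)))
    if (anyDuplicated(icrs$name)) stop("ICR names must be unique")
  }
  if (!is.null(genes)) genes <- as.data.table(genes)
  if (!is.null(exons)) exons <- as.data.table(exons)
  structure(list(repeats = repeats, genes = genes, exons = exons, icrs = icrs,
                 chrom_sizes = chrom_sizes),
            class = "annotation_set")
}

#' Read a repeat BED file (name field `family|class`)
#'
#' @param path BED path (chrom, start, end, name; 0-based half-open).
#' @return `data.table` with `chrom`, `start`, `end`, `family`, `class`.
#' @export
read_repeat_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "name")[1:4], select = 1:4)
  parts <- tstrsplit(dt$name, "|", fixed = TRUE)
  dt[, `:=`(family = parts[[1]],
            class = if (length(parts) > 1) parts[[2]] else "other")]
  dt[, name := NULL]
  dt[]
}

#' Read a named BED file (e.g. ICRs or genes)
#'
#' @param path BED path (chrom, start, end, name).
#' @return `data.table` with `chrom`, `start`, `end`, `name`.
#' @export
read_named_bed <- function(path) {
  fread(path, header = FALSE, sep = "\t", select = 1:4,
        col.names = c("chrom", "start", "end", "name"))
}

as_granges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
}

# put a list of GRanges on a shared seqlevel universe so that set operations
# do not warn about disjoint sequence levels
share_seqlevels <- function(grl) {
  lv <- unique(unlist(lapply(grl, GenomeInfoDb::seqlevels)))
  lapply(grl, function(g) { GenomeInfoDb::seqlevels(g) <- lv; g })
}

# Category GRanges in precedence order: repeat classes, then exon/intron;
# anything uncovered is intergenic.
context_category_ranges <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  rep_classes <- c("LTR", "LINE", "SINE", "satellite")
  cats <- list()
  for (cl in rep_classes) {
    sub <- annotation$repeats[class == cl]
    if (nrow(sub)) cats[[cl]] <- GenomicRanges::reduce(as_granges(sub))
  }
  other <- annotation$repeats[!class %in% rep_classes]
  if (nrow(other)) cats[["other_repeat"]] <- GenomicRanges::reduce(as_granges(other))
  if (!is.null(annotation$exons) && nrow(annotation$exons))
    cats[["exon"]] <- GenomicRanges::reduce(as_granges(annotation$exons))
  if (!is.null(annotation$genes) && nrow(annotation$genes)) {
    genes_gr <- GenomicRanges::reduce(as_granges(annotation$genes))
    introns <- if (!is.null(cats[["exon"]]))
      GenomicRanges::setdiff(genes_gr, cats[["exon"]]) else genes_gr
    cats[["intron"]] <- introns
  }
  cats
}

#' Genomic-context proportions of a region set
#'
#' Assigns every base of the regions to one context category using the
#' precedence repeat class (LTR > LINE > SINE > satellite > other repeat) >
#' exon > intron > intergenic, then reports each category's share of the
#' regions' total span. Shares sum to 1.
#'
#' @param regions Table of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param annotation An [annotation_set()].
#' @return Named numeric vector of base-pair proportions.
#' @export
context_proportions <- function(regions, annotation) {
  regions <- as.data.table(regions)
  if (nrow(regions) == 0) stop("context_proportions() needs a non-empty region set")
  cats <- context_category_ranges(annotation)
  shared <- share_seqlevels(c(list(GenomicRanges::reduce(as_granges(regions))), cats))
  remaining <- shared[[1]]
  cats <- setNames(shared[-1], names(cats))
  total <- sum(GenomicRanges::width(remaining))
  bp <- setNames(numeric(length(cats) + 1), c(names(cats), "intergenic"))
  for (nm in names(cats)) {
    ov <- GenomicRanges::intersect(remaining, cats[[nm]])
    bp[nm] <- sum(GenomicRanges::width(ov))
    remaining <- GenomicRanges::setdiff(remaining, cats[[nm]])
  }
  bp["intergenic"] <- sum(GenomicRanges::width(remaining))
  bp / total
}

#' Context fold-enrichment of a region set over the whole genome
#'
#' Per-category ratio of the category's share of the regions to its share of
#' the whole genome (requires `chrom_sizes` in the annotation). A category
#' absent from the genome gets `NA`.
#'
#' @inheritParams context_proportions
#' @return Named numeric vector of fold-enrichments.
#' @export
context_fold_enrichment <- function(regions, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (is.null(annotation$chrom_sizes))
    stop("context_fold_enrichment() needs chrom_sizes in the annotation")
  genome <- data.table(chrom = names(annotation$chrom_sizes), start = 0L,
                       end = as.integer(annotation$chrom_sizes))
  p_reg <- context_proportions(regions, annotation)
  p_gen <- context_proportions(genome, annotation)
  fold <- p_reg / p_gen
  fold[p_gen == 0] <- NA_real_
  fold
}

#' Weighted methylation per repeat family in control vs KO
#'
#' Aggregates CpG read counts over the union of all genomic copies of each
#' repeat family (a CpG covered by two copies of the same family counts once)
#' and reports control and KO weighted levels plus the difference in
#' percentage points. Only families with at least `min_copies` genomic copies
#' are reported.
#'
#' @param control_calls,ko_calls Pooled, coverage-filtered CpG call tables.
#' @param annotation An [annotation_set()] with repeat copies.
#' @param min_copies Minimum genomic copy number for a family (default 50).
#' @return `data.table` with `family`, `class`, `n_copies`, `n_cpg`,
#'   `level_control`, `level_ko`, `delta_pp`, ordered by `delta_pp`
#'   descending.
#' @export
repeat_family_methylation <- function(control_calls, ko_calls, annotation,
                                      min_copies = 50L) {
  stopifnot(inherits(annotation, "annotation_set"))
  reps <- copy(annotation$repeats)
  counts <- reps[, .(n_copies = .N), by = .(family, class)]
  keep <- counts[n_copies >= min_copies]
  if (nrow(keep) == 0) return(data.table(family = character(), class = character(),
                                         n_copies = integer(), n_cpg = integer(),
                                         level_control = numeric(), level_ko = numeric(),
                                         delta_pp = numeric()))
  reps <- reps[family %in% keep$family]

  family_level <- function(calls) {
    dt <- as_calls_dt(calls)
    calls_gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
    rep_gr <- as_granges(reps)
    hits <- GenomicRanges::findOverlaps(calls_gr, rep_gr)
    hdt <- unique(data.table(site = S4Vectors::queryHits(hits),
                             family = reps$family[S4Vectors::subjectHits(hits)]))
    hdt[, `:=`(n_meth = dt$n_meth[site], n_unmeth = dt$n_unmeth[site])]
    hdt[, .(n_cpg = .N, meth = sum(n_meth), total = sum(n_meth + n_unmeth)),
        by = family]
  }
  lc <- family_level(control_calls)
  lk <- family_level(ko_calls)
  out <- merge(keep,
               merge(lc[, .(family, n_cpg, level_control = meth / total)],
                     lk[, .(family, level_ko = meth / total)],
                     by = "family", all = TRUE),
               by = "family", all.x = TRUE)
  out[, delta_pp := 100 * (level_ko - level_control)]
  setorder(out, -delta_pp, na.last = TRUE)
  setcolorder(out, c("family", "class", "n_copies", "n_cpg",
                     "level_control", "level_ko", "delta_pp"))
  out[]
}

#' Rank hypermethylated repeat families
#'
#' Families whose KO-minus-control difference exceeds `delta_threshold`
#' percentage points (strict), sorted by difference descending with rank
#' `1..k`.
#'
#' @param summaries Output of [repeat_family_methylation()].
#' @param delta_threshold Threshold in percentage points (default 10, strict).
#' @return Subset of `summaries` with a `rank` column.
#' @export
rank_hyper_families <- function(summaries, delta_threshold = 10) {
  dt <- as.data.table(summaries)[!is.na(delta_pp) & delta_pp > delta_threshold]
  setorder(dt, -delta_pp)
  dt[, rank := seq_len(.N)]
  dt[]
}

#' ICR methylation levels and fold-increase in KO
#'
#' Computes the weighted methylation level of each imprinting control region
#' in control and KO, the KO/control fold-increase, and flags ICRs exceeding
#' the fold threshold (strict). A control level of exactly 0 leaves the fold
#' undefined (`fold_defined = FALSE`) rather than infinite.
#'
#' @param control_calls,ko_calls Pooled, coverage-filtered CpG call tables.
#' @param annotation An [annotation_set()] with `icrs`.
#' @param fold_threshold Flagging threshold on the fold-increase (default
#'   1.3, strict).
#' @return `data.table` with `name`, `chrom`, `start`, `end`,
#'   `level_control`, `level_ko`, `fold_increase`, `fold_defined`, `flagged`.
#' @export
icr_methylation <- function(control_calls, ko_calls, annotation, fold_threshold = 1.3) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (is.null(annotation$icrs) || nrow(annotation$icrs) == 0)
    stop("annotation has no ICR intervals")
  icrs <- annotation$icrs
  lc <- interval_levels(control_calls, icrs, min_cpg = 1L)
  lk <- interval_levels(ko_calls, icrs, min_cpg = 1L)
  out <- data.table(name = icrs$name, chrom = icrs$chrom, start = icrs$start,
                    end = icrs$end, level_control = lc$level, level_ko = lk$level)
  out[, fold_defined := !is.na(level_control) & !is.na(level_ko) & level_control > 0]
  out[, fold_increase := fifelse(fold_defined, level_ko / level_control, NA_real_)]
  out[, flagged := fold_defined & fold_increase > fold_threshold]
  out[]
}

utils::globalVariables(c("meth", "total"))
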