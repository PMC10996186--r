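# CpG-level bisulfite call IO, filtering, strand merging, pooling and QC.
#
# The on-disk format is the 6-column tab-delimited "coverage" dialect emitted
# by common bisulfite methylation extractors:
#   chrom  start  end  percent_methylated  count_methylated  count_unmethylated
# with 1-based inclusive coordinates (start == end for a single CpG). The
# percent column is never trusted: it is recomputed from the two counts, which
# makes ingestion robust to the rounding conventions of different extractors.

#' Read a CpG coverage file
#'
#' Parses a tab-delimited 6-column coverage file (chrom, start, end, %meth,
#' methylated count, unmethylated count; 1-based inclusive coordinates) into a
#' table of per-CpG calls. The percent-methylation column is ignored and the
#' level is always recomputed from the counts downstream. Gzip-compressed
#' files are read transparently.
#'
#' @param path Path to the coverage file (optionally `.gz`).
#' @return A `data.table` with columns `chrom`, `pos` (1-based position of the
#'   plus-strand C of the dyad), `n_meth`, `n_unmeth`, sorted by
#'   (`chrom`, `pos`).
#' @export
read_coverage_file <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r"); on.exit(close(con), add = TRUE)
      txt <- readLines(con)
      if (length(txt) == 0) data.table() else
        fread(text = txt, header = FALSE, sep = "\t", colClasses = list(character = 1))
    } else if (file.size(path) == 0) {
      data.table()
    } else {
      fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1))
    }
  }, error = function(e) stop("failed to parse coverage file ", path, ": ",
                              conditionMessage(e)))
  if (nrow(dt) == 0) {
    return(data.table(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer()))
  }
  if (ncol(dt) != 6)
    stop("malformed coverage file ", path, ": expected 6 columns, found ", ncol(dt))
  for (j in c(2L, 5L, 6L)) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed coverage file ", path, ": non-numeric value in column ", j,
           " at line ", bad[1])
    set(dt, j = j, value = v)
  }
  if (any(dt[[5]] < 0) || any(dt[[6]] < 0)) {
    bad <- which(dt[[5]] < 0 | dt[[6]] < 0)[1]
    stop("invalid coverage file ", path, ": negative read count at line ", bad)
  }
  out <- dt[, .(chrom = as.character(.SD[[1]]), pos = as.integer(.SD[[2]]),
                n_meth = as.integer(.SD[[5]]), n_unmeth = as.integer(.SD[[6]]))]
  setorder(out, chrom, pos)
  out[]
}

#' Write CpG calls to a coverage file
#'
#' Emits the standard 6-column coverage dialect; the percent column is
#' recomputed from the counts.
#'
#' @param calls CpG call table (`chrom`, `pos`, `n_meth`, `n_unmeth`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(calls, path) {
  assert_calls(calls)
  dt <- as_calls_dt(calls)
  out <- dt[, .(chrom, start = pos, end = pos,
                pct = round(100 * n_meth / pmax(1L, n_meth + n_unmeth), 6),
                n_meth, n_unmeth)]
  fwrite(out, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Merge plus- and minus-strand calls of each CpG dyad
#'
#' A CpG dyad covers two positions: the C on the plus strand at `p` and the C
#' on the minus strand at `p + 1`. Extractor output may report them as separate
#' records; this merges the two by summing counts into a single record at the
#' plus-strand position. Records whose position matches no known dyad pass
#' through unchanged.
#'
#' @param calls CpG call table.
#' @param cpg_positions Table of plus-strand dyad coordinates with columns
#'   `chrom` and `pos`.
#' @return Merged call table sorted by (`chrom`, `pos`); positions are unique
#'   within each chromosome.
#' @export
merge_strands <- function(calls, cpg_positions) {
  assert_calls(calls)
  stopifnot(all(c("chrom", "pos") %in% names(cpg_positions)))
  dt <- as_calls_dt(calls)
  cpg <- as.data.table(cpg_positions)[, .(chrom = as.character(chrom), pos = as.integer(pos))]
  dt[, newpos := pos]
  # a record on the plus-strand C keeps its position ...
  is_plus <- dt[cpg, on = c("chrom", "pos"), which = TRUE, nomatch = 0L]
  plus <- rep(FALSE, nrow(dt)); plus[is_plus] <- TRUE
  # ... a record on the minus-strand C (dyad position + 1) is shifted back
  minus_key <- cpg[, .(chrom, pos = pos + 1L)]
  is_minus <- dt[minus_key, on = c("chrom", "pos"), which = TRUE, nomatch = 0L]
  minus <- rep(FALSE, nrow(dt)); minus[is_minus] <- TRUE
  dt[minus & !plus, newpos := pos - 1L]
  out <- dt[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
            by = .(chrom, pos = newpos)]
  setorder(out, chrom, pos)
  out[]
}

#' Filter CpG sites by read depth
#'
#' Retains sites whose total depth (methylated + unmethylated reads) lies in
#' the closed interval `[min_reads, max_reads]`. The defaults, 3 and 100 reads
#' inclusive, drop unreliably shallow sites and collapsed/amplified repeats
#' with implausibly deep coverage. The operation is idempotent.
#'
#' @param calls CpG call table.
#' @param min_reads Minimum depth (inclusive), `>= 1`.
#' @param max_reads Maximum depth (inclusive), `>= min_reads`.
#' @return Filtered call table.
#' @export
filter_coverage <- function(calls, min_reads = 3L, max_reads = 100L) {
  assert_calls(calls)
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (max_reads < min_reads) stop("max_reads must be >= min_reads")
  dt <- as_calls_dt(calls)
  dt[n_meth + n_unmeth >= min_reads & n_meth + n_unmeth <= max_reads][]
}

#' Pool biological replicates by summing per-site read counts
#'
#' Counts (not levels) are combined, so deeply covered sites contribute with
#' their full weight; the coverage filter is re-applied to the pooled counts
#' because pooling can push sites above the depth ceiling or lift shallow
#' sites above the floor.
#'
#' @param samples A list of CpG call tables on the same genome.
#' @param min_reads,max_reads Depth filter re-applied after pooling; set
#'   `refilter = FALSE` to skip.
#' @param refilter Re-apply the coverage filter after pooling (default `TRUE`).
#' @return Pooled call table.
#' @export
pool_replicates <- function(samples, min_reads = 3L, max_reads = 100L, refilter = TRUE) {
  if (!is.list(samples) || length(samples) == 0 || is.data.frame(samples))
    samples <- if (is.data.frame(samples)) list(samples) else samples
  if (length(samples) == 0) stop("pool_replicates() needs at least one sample")
  for (s in samples) assert_calls(s, "each element of samples")
  all <- rbindlist(lapply(samples, as_calls_dt))
  pooled <- all[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)), by = .(chrom, pos)]
  setorder(pooled, chrom, pos)
  if (refilter) pooled <- filter_coverage(pooled, min_reads, max_reads)
  pooled[]
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' Libraries are spiked with fully unmethylated exogenous DNA (lambda phage);
#' any methylated call on that contig reflects a conversion failure. The rate
#' returned is `1 - sum(n_meth) / sum(depth)` over spike-in sites.
#'
#' @param calls CpG call table including spike-in records.
#' @param spike_contig Name of the spike-in contig.
#' @return Conversion rate in `[0, 1]`, or `NA` (with a warning) if no
#'   spike-in site is covered.
#' @export
conversion_rate <- function(calls, spike_contig = "lambda_spike") {
  assert_calls(calls)
  dt <- as_calls_dt(calls)[chrom == spike_contig]
  tot <- sum(dt$n_meth + dt$n_unmeth)
  if (nrow(dt) == 0 || tot == 0) {
    warning("no covered spike-in sites on contig '", spike_contig, "'")
    return(NA_real_)
  }
  1 - sum(dt$n_meth) / tot
}

#' Pearson correlation of regional methylation between two replicates
#'
#' Both samples are windowed on a common fixed grid (500-kb by default) and
#' the correlation is computed over windows informative (at least `min_cpg`
#' CpG sites) in both samples. Symmetric in its arguments.
#'
#' @param sample_a,sample_b Coverage-filtered CpG call tables.
#' @param window_size Grid window size in bp (default 500 kb).
#' @param min_cpg Minimum informative CpGs per window in each sample.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(sample_a, sample_b, window_size = 500000L, min_cpg = 5L) {
  wa <- window_levels(sample_a, window_size = window_size, min_cpg = min_cpg)
  wb <- window_levels(sample_b, window_size = window_size, min_cpg = min_cpg)
  m <- merge(wa[, .(chrom, start, level_a = level)],
             wb[, .(chrom, start, level_b = level)], by = c("chrom", "start"))
  if (nrow(m) < 2)
    stop("replicate_correlation() is undefined: fewer than 2 shared informative windows")
  stats::cor(m$level_a, m$level_b)
}

#' Sample metadata record
#'
#' Light validation of the stage/genotype/sex enumerations used across the
#' germ-cell chronology (epiblast through fully grown oocytes).
#'
#' @param stage Developmental stage, one of `"epiblast"`, `"E9.5"`, `"E10.5"`,
#'   `"E11.5"`, `"E12.5"`, `"E13.5"`, `"E16.5"`, `"GO"`, `"FGO"`.
#' @param genotype `"control"`, `"KO"`, or `"WT"`.
#' @param sex `"female"`, `"male"`, or `"mixed"`.
#' @param replicate Replicate label.
#' @return A named list of class `"sample_meta"`.
#' @export
sample_meta <- function(stage, genotype, sex = "mixed", replicate = "r1") {
  stage <- match.arg(stage, c("epiblast", "E9.5", "E10.5", "E11.5", "E12.5",
                              "E13.5", "E16.5", "GO", "FGO"))
  genotype <- match.arg(genotype, c("control", "KO", "WT"))
  sex <- match.arg(sex, c("female", "male", "mixed"))
  structure(list(stage = stage, genotype = genotype, sex = sex,
                 replicate = as.character(replicate)),
            class = "sample_meta")
}
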