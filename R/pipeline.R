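# End-to-end orchestration: simulate -> QC -> windows -> DMR -> annotation ->
# chromatin -> fate -> expression, with a reproducibility manifest.
#
# All stage hand-offs go through plain-text files in the output directory; no
# hidden state is carried between stages, so any stage can be re-run from the
# files of the previous ones.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "pgcmeth_run",
    stages = c("E11.5", "E13.5", "E16.5", "FGO"),
    genotypes = c("control", "KO"),
    window_size = 10000L,
    min_cpg = 5L,
    min_reads = 3L,
    max_reads = 100L,
    delta_threshold = 10,
    alpha = 0.05,
    fold_threshold = 1.3,
    top_quantile = 0.05,
    mark = "H3K9me3",
    genome = list()   # overrides forwarded to synthetic_genome_spec()
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on a freshly simulated genome:
#' genome + annotation build, per-sample simulation and QC (conversion rate,
#' replicate correlation), replicate pooling and windowing, per-stage DMR
#' calling, genomic-context / repeat-family / ICR characterization of the
#' E13.5 hypermethylated windows, ChIP enrichment and its relation to the
#' DMRs, cross-stage fate classification, and the differential-expression
#' filter. Writes tab-delimited outputs plus a JSON manifest of parameters
#' and output checksums; a rerun with the same config produces byte-identical
#' outputs.
#'
#' @param config Named list overriding the defaults (seed, out_dir, stages,
#'   thresholds, `genome` spec overrides), or a path to a YAML file holding
#'   such a list.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  for (f in c("stages", "genotypes")) cfg[[f]] <- unlist(cfg[[f]])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage_log <- function(name) message(sprintf("[pgcmeth] %-12s %.1fs", name,
                                              as.numeric(Sys.time() - t0, units = "secs")))
  outputs <- character()
  keep <- function(path) { outputs[[length(outputs) + 1]] <<- path; path }

  # 1. genome + annotations --------------------------------------------------
  spec <- do.call(synthetic_genome_spec, cfg$genome)
  genome <- build_genome(spec, seed = cfg$seed)
  ann_paths <- write_genome_annotations(genome, file.path(cfg$out_dir, "genome"))
  for (p in ann_paths) keep(p)
  annotation <- annotation_set(genome$repeats, genes = genome$genes,
                               exons = genome$exons, icrs = genome$icrs,
                               chrom_sizes = genome$chrom_sizes[names(spec$chrom_sizes)])
  stage_log("genome")

  # 2. samples + QC ----------------------------------------------------------
  cov_dir <- file.path(cfg$out_dir, "coverage"); dir.create(cov_dir, showWarnings = FALSE)
  samples <- list(); qc <- list()
  for (st in cfg$stages) for (gt in cfg$genotypes) {
    reps <- lapply(seq_len(spec$replicates), function(r)
      simulate_sample(genome, st, gt, replicate = r, seed = cfg$seed))
    for (r in seq_along(reps))
      keep(write_coverage_file(reps[[r]],
             file.path(cov_dir, sprintf("%s_%s_r%d.cov.gz", st, gt, r))))
    filtered <- lapply(reps, filter_coverage, cfg$min_reads, cfg$max_reads)
    rep_cor <- if (length(filtered) >= 2)
      replicate_correlation(filtered[[1]], filtered[[2]]) else NA_real_
    pooled <- pool_replicates(filtered, cfg$min_reads, cfg$max_reads)
    samples[[paste(st, gt, sep = "_")]] <- pooled
    qc[[length(qc) + 1]] <- data.table(
      stage = st, genotype = gt, n_sites = nrow(pooled),
      conversion_rate = conversion_rate(pooled, spec$spike_contig),
      replicate_correlation = rep_cor,
      global_level = global_level(pooled, spec$spike_contig))
  }
  fwrite(rbindlist(qc), keep(file.path(cfg$out_dir, "qc.tsv")), sep = "\t")
  stage_log("samples+qc")

  # 3. windows ---------------------------------------------------------------
  wl <- lapply(samples, window_levels, window_size = cfg$window_size,
               min_cpg = cfg$min_cpg, exclude_contigs = spec$spike_contig)
  for (nm in names(wl))
    fwrite(wl[[nm]], keep(file.path(cfg$out_dir, sprintf("windows_%s.tsv", nm))), sep = "\t")
  stage_log("windows")

  # 4. DMRs per stage --------------------------------------------------------
  dmrs <- list(); summaries <- list()
  for (st in cfg$stages) {
    dmrs[[st]] <- call_dmrs(samples[[paste0(st, "_control")]],
                            samples[[paste0(st, "_KO")]],
                            window_size = cfg$window_size, min_cpg = cfg$min_cpg,
                            delta_threshold = cfg$delta_threshold, alpha = cfg$alpha,
                            exclude_contigs = spec$spike_contig)
    keep(write_dmr_bed(dmrs[[st]], file.path(cfg$out_dir, sprintf("dmr_%s.bed", st))))
    summaries[[st]] <- cbind(stage = st, summarize_dmrs(dmrs[[st]]))
  }
  fwrite(rbindlist(summaries), keep(file.path(cfg$out_dir, "dmr_summary.tsv")), sep = "\t")
  stage_log("dmr")

  # 5. annotation of E13.5 hyper windows -------------------------------------
  anno_stage <- if ("E13.5" %in% cfg$stages) "E13.5" else cfg$stages[1]
  hyper <- dmrs[[anno_stage]]$hyper[, .(chrom, start, end)]
  if (nrow(hyper)) {
    ctx <- context_proportions(hyper, annotation)
    fold <- context_fold_enrichment(hyper, annotation)
    fwrite(data.table(category = names(ctx), proportion = as.numeric(ctx),
                      fold_enrichment = as.numeric(fold[names(ctx)])),
           keep(file.path(cfg$out_dir, "context.tsv")), sep = "\t")
  }
  fam <- repeat_family_methylation(samples[[paste0(anno_stage, "_control")]],
                                   samples[[paste0(anno_stage, "_KO")]], annotation)
  fwrite(fam, keep(file.path(cfg$out_dir, "repeat_families.tsv")), sep = "\t")
  fwrite(rank_hyper_families(fam, cfg$delta_threshold),
         keep(file.path(cfg$out_dir, "repeat_families_hyper.tsv")), sep = "\t")
  icr <- icr_methylation(samples[[paste0(anno_stage, "_control")]],
                         samples[[paste0(anno_stage, "_KO")]], annotation,
                         fold_threshold = cfg$fold_threshold)
  fwrite(icr, keep(file.path(cfg$out_dir, "icr.tsv")), sep = "\t")
  stage_log("annotation")

  # 6. chromatin -------------------------------------------------------------
  chip <- simulate_chip(genome, mark = cfg$mark, seed = cfg$seed)
  track <- window_enrichment(chip, mark = cfg$mark)
  fwrite(track, keep(file.path(cfg$out_dir, "mark_track.tsv")), sep = "\t")
  top <- top_quantile_windows(track, cfg$top_quantile)
  fwrite(top, keep(file.path(cfg$out_dir, "mark_top_windows.tsv")), sep = "\t")
  other <- data.table::fsetdiff(track[, .(chrom, start)], hyper[, .(chrom, start)])
  cmp <- mark_vs_methylation(track, hyper[, .(chrom, start)], other,
                             wl[[paste0(anno_stage, "_control")]],
                             wl[[paste0(anno_stage, "_KO")]],
                             labels = c("hyper", "other"))
  fwrite(cmp, keep(file.path(cfg$out_dir, "mark_vs_methylation.tsv")), sep = "\t")
  stage_log("chromatin")

  # 7. fate ------------------------------------------------------------------
  fate_stages <- intersect(c("E11.5", "E13.5", "E16.5", "FGO"), names(dmrs))
  if (length(fate_stages) >= 2) {
    fate <- classify_fates(dmrs[fate_stages])
    fwrite(fate$windows, keep(file.path(cfg$out_dir, "fate_windows.tsv")), sep = "\t")
    fwrite(fate$counts, keep(file.path(cfg$out_dir, "fate_counts.tsv")), sep = "\t")
    if ("FGO" %in% cfg$stages) {
      prof <- category_profiles(fate, track, wl[["FGO_control"]], wl[["FGO_KO"]])
      fwrite(prof, keep(file.path(cfg$out_dir, "category_profiles.tsv")), sep = "\t")
    }
  }
  dm <- delta_matrix(setNames(lapply(cfg$stages, function(st)
    list(control = wl[[paste0(st, "_control")]], ko = wl[[paste0(st, "_KO")]])),
    cfg$stages), order_by = track)
  fwrite(dm, keep(file.path(cfg$out_dir, "delta_matrix.tsv")), sep = "\t")
  stage_log("fate")

  # 8. expression ------------------------------------------------------------
  fpkm <- simulate_expression(genome, seed = cfg$seed)
  fwrite(fpkm, keep(file.path(cfg$out_dir, "fpkm.tsv")), sep = "\t")
  de <- de_genes(fpkm, grep("^control_", names(fpkm), value = TRUE),
                 grep("^ko_", names(fpkm), value = TRUE))
  fwrite(de, keep(file.path(cfg$out_dir, "de_genes.tsv")), sep = "\t")
  stage_log("expression")

  # manifest -----------------------------------------------------------------
  outputs <- unlist(outputs)
  manifest <- list(
    package = "pgcmeth",
    version = as.character(utils::packageVersion("pgcmeth")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    files = lapply(outputs, function(p) list(
      path = sub(paste0("^", cfg$out_dir, "/?"), "", p),
      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("manifest")
  invisible(manifest)
}
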