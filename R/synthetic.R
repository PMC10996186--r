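# Synthetic toy genome, annotations, chromatin tracks, and bisulfite read
# counts with machine-readable truth tables.
#
# The generator emulates the measured structure of germline methylation
# reprogramming: a stage trajectory of control methylation (high in epiblast,
# eroding through E13.5, regained in fully grown oocytes), knockout
# hypermethylation planted preferentially at H3K9me3-marked IAP-like LTR
# copies and a satellite block, residual imprint retention at 5 of 15 ICRs,
# de-novo-only hypermethylation appearing first in KO FGOs, an unmethylated
# spike-in contig, and replicate structure with beta-binomial read noise.
# Every planted effect is recorded in truth tables so downstream stages can be
# validated exactly.

#' Specification of the synthetic genome and study design
#'
#' All defaults define the simulated study conditions; see the methods
#' vignette for the rationale behind each value. Probabilities are fractions
#' in `[0, 1]`; deltas are on the fraction scale.
#'
#' @param chrom_sizes Named vector of chromosome lengths (default 4 x 5 Mb).
#' @param spike_contig,spike_size Unmethylated spike-in contig name and length.
#' @param cpg_spacing,cpg_jitter Mean CpG spacing in bp and uniform placement
#'   jitter.
#' @param window_size Analysis grid window (default 10 kb).
#' @param stage_levels Control global methylation baseline per stage
#'   (pre-oocyte stages; the FGO landscape is bimodal, see `fgo_*`).
#' @param window_jitter_sd SD of the per-window, per-stage truth jitter
#'   around the stage baseline (shared between genotypes and replicates).
#' @param ko_delta Planted KO increment at hypermethylated windows during the
#'   PGC stages.
#' @param satellite_delta Planted KO increment at satellite-block windows,
#'   slightly below `ko_delta` so the IAP-like family carries the largest
#'   repeat-family effect.
#' @param lost_residual Named residual KO increments at "lost" windows after
#'   E11.5.
#' @param fgo_hi_level,fgo_lo_level,fgo_hi_fraction Bimodal control FGO
#'   landscape: fraction of background windows at the high level.
#' @param fgo_persistent_control Control FGO level at windows whose KO
#'   hypermethylation persists into oocytes.
#' @param fgo_persistent_delta,fgo_only_delta Planted KO FGO increments for
#'   persistent and FGO-only windows.
#' @param n_iap,iap_len IAP-like LTR family: copy number and copy length.
#' @param n_line,line_len,n_sine,sine_len LINE-like and SINE-like families.
#' @param n_rare,rare_len A low-copy LTR family (below the 50-copy reporting
#'   floor).
#' @param n_satellite,satellite_len Tandem satellite block copies.
#' @param n_icrs,icr_len Imprinting control regions: count and length.
#' @param icr_control_levels Control ICR level per stage (erasure dynamics;
#'   a residual is left at E13.5/E16.5 so fold-changes are estimable at
#'   desk-scale depth).
#' @param icr_retained_level KO level at the retained ICRs during PGC stages.
#' @param persistent_fraction Fraction of H3K9me3-marked hyper windows whose
#'   hypermethylation persists into FGOs.
#' @param n_lost,n_fgo_only Counts of unmarked windows hypermethylated only
#'   at E11.5 ("lost") and only in KO FGOs.
#' @param dispersion Beta-binomial overdispersion of per-CpG read draws.
#' @param depth Mean sequencing depth (Poisson, floored at 1 read).
#' @param conversion_error Bisulfite non-conversion rate.
#' @param replicates Biological replicates per (stage, genotype).
#' @param chip_background,chip_fold ChIP simulation: background Poisson mean
#'   per window and IP fold at truth windows.
#' @param n_genes Gene count (includes the knocked-out and the derepressed
#'   gene).
#' @return A named list of class `"synthetic_genome_spec"`.
#' @export
synthetic_genome_spec <- function(
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6, chr4 = 5e6),
    spike_contig = "lambda_spike", spike_size = 48502L,
    cpg_spacing = 100L, cpg_jitter = 40L, window_size = 10000L,
    stage_levels = c(epiblast = 0.70, E9.5 = 0.30, E10.5 = 0.15, E11.5 = 0.091,
                     E12.5 = 0.05, E13.5 = 0.025, E16.5 = 0.022, GO = 0.15),
    window_jitter_sd = 0.02,
    ko_delta = 0.30,
    satellite_delta = 0.26,
    lost_residual = c(E13.5 = 0.015, E16.5 = 0.010),
    fgo_hi_level = 0.85, fgo_lo_level = 0.05, fgo_hi_fraction = 0.47,
    fgo_persistent_control = 0.60, fgo_persistent_delta = 0.30,
    fgo_only_delta = 0.50,
    n_iap = 200L, iap_len = 3000L, n_line = 300L, line_len = 1500L,
    n_sine = 400L, sine_len = 200L, n_rare = 30L, rare_len = 800L,
    n_satellite = 60L, satellite_len = 1000L,
    n_icrs = 15L, icr_len = 8000L,
    icr_control_levels = c(E11.5 = 0.25, E13.5 = 0.12, E16.5 = 0.12,
                           GO = 0.20, FGO = 0.85),
    icr_retained_level = 0.45,
    persistent_fraction = 0.5, n_lost = 300L, n_fgo_only = 200L,
    dispersion = 0.05, depth = 15, conversion_error = 0.005, replicates = 2L,
    chip_background = 50, chip_fold = 8, n_genes = 40L) {
  spec <- as.list(environment())
  # tolerate YAML-style named lists for the vector-valued fields
  for (f in c("chrom_sizes", "stage_levels", "lost_residual", "icr_control_levels"))
    spec[[f]] <- unlist(spec[[f]])
  if (is.null(names(spec$chrom_sizes)) || any(!nzchar(names(spec$chrom_sizes))))
    stop("chrom_sizes must be a named vector (or named map in a config file)")
  stopifnot(all(spec$chrom_sizes > 0), spec$window_size > 0,
            all(spec$stage_levels >= 0 & spec$stage_levels <= 1),
            spec$dispersion >= 0, spec$dispersion < 1,
            spec$conversion_error >= 0, spec$conversion_error < 1,
            spec$depth >= 1, spec$replicates >= 1,
            spec$persistent_fraction >= 0, spec$persistent_fraction <= 1)
  if (spec$n_iap < 50)
    warning("IAP-like family has fewer than 50 copies; it would be excluded ",
            "from repeat-family reporting downstream")
  structure(spec, class = "synthetic_genome_spec")
}

icr_names_default <- c("Impact", "U2af1-rs1", "Kcnq1ot1", "Igf2r", "Zac1",
                       "H19", "Meg3-IG", "Snrpn", "Peg3", "Peg10", "Mest",
                       "Grb10", "Nespas", "Gnas1A", "Rasgrf1")
icr_retained_default <- c("Impact", "U2af1-rs1", "Kcnq1ot1", "Igf2r", "Zac1")

ko_stages <- c("E11.5", "E13.5", "E16.5", "FGO")

#' Build the synthetic genome, annotations and truth tables
#'
#' Deterministic given (`spec`, `seed`): lays down CpG positions, repeat
#' copies (IAP-like LTR, LINE-like, SINE-like, a tandem satellite block, and
#' one low-copy family), genes with exons, 15 named ICRs, assigns H3K9me3 to
#' the IAP/satellite windows, samples the per-window fate categories
#' (persistent, PGC-only, lost, FGO-only), and precomputes the per-window
#' per-stage truth methylation levels for both genotypes.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param seed Master seed (integer).
#' @return An object of class `"synthetic_genome"`: list with `spec`, `seed`,
#'   `chrom_sizes` (incl. spike-in), `cpgs`, `windows`, `window_truth`,
#'   `repeats`, `genes`, `exons`, `icrs`, `marked_windows`, `gene_baseline`,
#'   and `truth` (window categories, H3K9me3 windows, ICR retention, planted
#'   DE genes).
#' @export
build_genome <- function(spec = synthetic_genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(derive_seed(seed, "genome"))
  chroms <- names(spec$chrom_sizes)
  ws <- as.integer(spec$window_size)

  # CpG dyads: ~1 per cpg_spacing bp with uniform jitter, strictly increasing
  place_cpgs <- function(chrom, size) {
    base <- seq(spec$cpg_spacing %/% 2, size - spec$cpg_spacing %/% 2,
                by = spec$cpg_spacing)
    pos <- as.integer(base + sample(seq(-spec$cpg_jitter, spec$cpg_jitter), length(base),
                                    replace = TRUE))
    data.table(chrom = chrom, pos = sort(unique(pos)))
  }
  cpgs <- rbindlist(c(
    lapply(chroms, function(cn) place_cpgs(cn, spec$chrom_sizes[[cn]])),
    list(place_cpgs(spec$spike_contig, spec$spike_size))
  ))
  cpgs[, wstart := window_start(pos, ws)]

  windows <- rbindlist(lapply(chroms, function(cn) {
    starts <- seq(0L, as.integer(spec$chrom_sizes[[cn]]) - 1L, by = ws)
    data.table(chrom = cn, start = starts, end = pmin(starts + ws,
                                                      as.integer(spec$chrom_sizes[[cn]])))
  }))
  windows[, window := window_id(chrom, start)]

  # --- ICRs: evenly spaced windows on the last (or only) chromosome --------
  icr_chrom <- chroms[min(length(chroms), 3L)]
  icr_wins <- windows[chrom == icr_chrom]
  stride <- max(1L, nrow(icr_wins) %/% (spec$n_icrs + 1L))
  icr_win_idx <- stride * seq_len(spec$n_icrs)
  icr_windows <- icr_wins[icr_win_idx]
  nm <- if (spec$n_icrs <= length(icr_names_default)) icr_names_default[seq_len(spec$n_icrs)]
        else c(icr_names_default, paste0("ICR", seq_len(spec$n_icrs - length(icr_names_default))))
  icr_off <- (ws - spec$icr_len) %/% 2L
  icrs <- data.table(chrom = icr_windows$chrom,
                     start = icr_windows$start + icr_off,
                     end = icr_windows$start + icr_off + spec$icr_len,
                     name = nm)
  if (any(icrs$end[-nrow(icrs)] > icrs$start[-1] & icrs$chrom[-nrow(icrs)] == icrs$chrom[-1]))
    stop("synthetic spec invalid: ICR intervals overlap")
  retained <- intersect(icr_retained_default, nm)
  if (length(retained) < min(5L, spec$n_icrs)) retained <- nm[seq_len(min(5L, spec$n_icrs))]

  # --- repeats -------------------------------------------------------------
  rep_chroms <- chroms[seq_len(min(2L, length(chroms)))]
  sat_chrom <- rep_chroms[length(rep_chroms)]
  sat_start <- as.integer(min(1e6, spec$chrom_sizes[[sat_chrom]] %/% 2))
  satellites <- data.table(chrom = sat_chrom,
                           start = sat_start + spec$satellite_len * (seq_len(spec$n_satellite) - 1L),
                           end = sat_start + spec$satellite_len * seq_len(spec$n_satellite),
                           family = "GSAT-like", class = "satellite")
  sat_windows <- unique(window_id(satellites$chrom, window_start(satellites$start + 1L, ws)))

  cand <- windows[chrom %in% rep_chroms & !window %in% sat_windows &
                    !window %in% icr_windows$window]
  iap_wins <- cand[sample(.N, min(spec$n_iap, .N))]
  iap_off <- (ws - spec$iap_len) %/% 2L
  iaps <- data.table(chrom = iap_wins$chrom, start = iap_wins$start + iap_off,
                     end = iap_wins$start + iap_off + spec$iap_len,
                     family = "IAPEz-like", class = "LTR")

  scatter_family <- function(n, len, family, class) {
    cn <- sample(rep_chroms, n, replace = TRUE)
    st <- floor(runif(n, 0, spec$chrom_sizes[cn] - len))
    data.table(chrom = cn, start = as.integer(st), end = as.integer(st + len),
               family = family, class = class)
  }
  repeats <- rbindlist(list(
    iaps, satellites,
    scatter_family(spec$n_line, spec$line_len, "L1Md-like", "LINE"),
    scatter_family(spec$n_sine, spec$sine_len, "B1-like", "SINE"),
    scatter_family(spec$n_rare, spec$rare_len, "RLTR-rare", "LTR")
  ))
  setorder(repeats, chrom, start)

  marked_windows <- sort(unique(c(window_id(iap_wins$chrom, iap_wins$start), sat_windows)))

  # --- genes (incl. the knocked-out and the derepressed gene) --------------
  gene_chroms <- chroms[seq.int(min(3L, length(chroms)), length(chroms))]
  gene_names <- c("Dppa3", "Chkb",
                  sprintf("Gene%02d", seq_len(max(0L, spec$n_genes - 2L))))
  gn <- length(gene_names)
  gcn <- sample(gene_chroms, gn, replace = TRUE)
  gst <- as.integer(floor(runif(gn, 0, spec$chrom_sizes[gcn] - 20000)))
  genes <- data.table(chrom = gcn, start = gst, end = gst + 20000L, name = gene_names)
  exons <- rbindlist(lapply(c(0L, 8000L, 18000L), function(off)
    data.table(chrom = genes$chrom, start = genes$start + off,
               end = genes$start + off + 1000L, name = genes$name)))
  setorder(genes, chrom, start); setorder(exons, chrom, start)
  gene_baseline <- setNames(2^rnorm(gn, mean = 3, sd = 1.5), gene_names)
  gene_baseline["Dppa3"] <- 30; gene_baseline["Chkb"] <- 2

  # --- fate categories -----------------------------------------------------
  n_marked <- length(marked_windows)
  perm <- sample(marked_windows)
  n_persist <- round(spec$persistent_fraction * n_marked)
  persistent <- sort(perm[seq_len(n_persist)])
  pgc_only <- sort(setdiff(marked_windows, persistent))
  background <- setdiff(windows$window, c(marked_windows, icr_windows$window))
  picks <- sample(background, min(spec$n_lost + spec$n_fgo_only, length(background)))
  lost <- sort(picks[seq_len(min(spec$n_lost, length(picks)))])
  fgo_only <- sort(setdiff(picks, lost))
  icr_pgc <- sort(icr_windows$window[nm %in% retained])

  truth_windows <- rbind(
    data.table(window = persistent, category = "persistent_to_FGO"),
    data.table(window = pgc_only, category = "PGC_only"),
    data.table(window = icr_pgc, category = "PGC_only"),
    data.table(window = lost, category = "lost_after_E11.5"),
    data.table(window = fgo_only, category = "FGO_only")
  )

  # --- per-window, per-stage truth levels ----------------------------------
  stages_pgc <- names(spec$stage_levels)
  cat_of <- setNames(rep("none", nrow(windows)), windows$window)
  cat_of[truth_windows$window] <- truth_windows$category
  wt_list <- lapply(stages_pgc, function(st) {
    ctl <- clamp(spec$stage_levels[[st]] +
                   rnorm(nrow(windows), 0, spec$window_jitter_sd), 0.001, 0.97)
    delta <- numeric(nrow(windows))
    if (st %in% ko_stages) {
      cc <- cat_of[windows$window]
      hyper_now <- cc %in% c("persistent_to_FGO", "PGC_only")
      delta[hyper_now] <- spec$ko_delta
      # the satellite block is hypermethylated slightly less than the
      # IAP-like LTR family, which carries the largest planted effect
      delta[hyper_now & windows$window %in% sat_windows] <- spec$satellite_delta
      if (st == "E11.5") delta[cc == "lost_after_E11.5"] <- spec$ko_delta
      if (st %in% names(spec$lost_residual))
        delta[cc == "lost_after_E11.5"] <- spec$lost_residual[[st]]
    }
    data.table(window = windows$window, chrom = windows$chrom, start = windows$start,
               stage = st, level_control = ctl,
               level_ko = clamp(ctl + delta, 0.001, 0.97))
  })
  # FGO: bimodal control landscape; persistent windows sit mid-high and gain
  # further in KO; FGO-only windows start low and gain strongly in KO
  cc <- cat_of[windows$window]
  fgo_ctl <- ifelse(cc == "persistent_to_FGO", spec$fgo_persistent_control,
             ifelse(cc == "FGO_only", spec$fgo_lo_level,
                    ifelse(runif(nrow(windows)) < spec$fgo_hi_fraction,
                           spec$fgo_hi_level, spec$fgo_lo_level)))
  fgo_ctl <- clamp(fgo_ctl + rnorm(nrow(windows), 0, spec$window_jitter_sd), 0.001, 0.97)
  fgo_delta <- ifelse(cc == "persistent_to_FGO", spec$fgo_persistent_delta,
               ifelse(cc == "FGO_only", spec$fgo_only_delta, 0))
  wt_list[[length(wt_list) + 1]] <- data.table(
    window = windows$window, chrom = windows$chrom, start = windows$start,
    stage = "FGO", level_control = fgo_ctl,
    level_ko = clamp(fgo_ctl + fgo_delta, 0.001, 0.97))
  window_truth <- rbindlist(wt_list)

  # per-CpG ICR membership (ICR CpG truth overrides the window truth)
  icr_gr <- GenomicRanges::GRanges(icrs$chrom, IRanges::IRanges(icrs$start + 1L, icrs$end))
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos, cpgs$pos))
  hits <- GenomicRanges::findOverlaps(cpg_gr, icr_gr)
  cpgs[, icr := NA_character_]
  cpgs[S4Vectors::queryHits(hits), icr := icrs$name[S4Vectors::subjectHits(hits)]]

  structure(list(
    spec = spec, seed = seed,
    chrom_sizes = c(spec$chrom_sizes, setNames(spec$spike_size, spec$spike_contig)),
    cpgs = cpgs[], windows = windows[], window_truth = window_truth,
    repeats = repeats[], genes = genes[], exons = exons[], icrs = icrs[],
    marked_windows = marked_windows, gene_baseline = gene_baseline,
    truth = list(
      windows = truth_windows[order(window)],
      h3k9me3_windows = marked_windows,
      icrs = data.table(name = nm, retained = nm %in% retained),
      planted_hyper_E11.5 = sort(c(persistent, pgc_only, lost)),
      de_genes = c("Dppa3", "Chkb")
    )
  ), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$spec$chrom_sizes), "chromosomes +",
      x$spec$spike_contig, "|", nrow(x$cpgs), "CpGs |", nrow(x$windows),
      "grid windows |", nrow(x$repeats), "repeat copies |",
      nrow(x$icrs), "ICRs\n")
  print(x$truth$windows[, .N, by = category])
  invisible(x)
}

# truth methylation level for each CpG of one (stage, genotype)
cpg_truth_levels <- function(genome, stage, genotype) {
  spec <- genome$spec
  cpgs <- genome$cpgs
  wt <- genome$window_truth[stage, on = "stage"]
  lvl_col <- if (genotype == "KO") "level_ko" else "level_control"
  m <- wt[cpgs, on = c(chrom = "chrom", start = "wstart")]
  truth <- m[[lvl_col]]
  truth[cpgs$chrom == spec$spike_contig] <- 0
  # ICR overrides where the stage has explicit ICR erasure/retention dynamics
  if (stage %in% names(spec$icr_control_levels)) {
    in_icr <- !is.na(cpgs$icr)
    truth[in_icr] <- spec$icr_control_levels[[stage]]
    if (genotype == "KO" && stage %in% c("E11.5", "E13.5", "E16.5")) {
      ret <- genome$truth$icrs[retained == TRUE, name]
      truth[in_icr & cpgs$icr %in% ret] <- spec$icr_retained_level
    }
  }
  truth
}

#' Simulate one WGBS sample as CpG calls
#'
#' Draws per-CpG read counts around the genome's planted truth levels:
#' depth ~ Poisson(`depth`) floored at one read, per-site methylation
#' probability beta-distributed around the truth with overdispersion
#' `dispersion`, and counts binomial. Bisulfite conversion failure inflates
#' the observed probability to `t + (1 - t) * conversion_error`; the spike-in
#' contig has truth level 0 everywhere. `noiseless = TRUE` replaces all
#' random draws with fixed depth and rounded expected counts (the
#' infinite-depth limit used for exact truth-recovery checks).
#'
#' @param genome A `"synthetic_genome"` from [build_genome()].
#' @param stage Stage label present in the genome's trajectory.
#' @param genotype `"control"` or `"KO"`.
#' @param replicate Replicate label (seeds differ per replicate).
#' @param seed Seed; defaults to the genome's master seed.
#' @param depth Mean depth override (default: spec).
#' @param noiseless Deterministic expected counts instead of random draws.
#' @param per_strand Emit separate plus/minus-strand records per dyad (counts
#'   split binomially), for exercising [merge_strands()].
#' @return Unfiltered CpG call table (`chrom`, `pos`, `n_meth`, `n_unmeth`).
#' @export
simulate_sample <- function(genome, stage, genotype = c("control", "KO"),
                            replicate = 1L, seed = NULL, depth = NULL,
                            noiseless = FALSE, per_strand = FALSE) {
  stopifnot(inherits(genome, "synthetic_genome"))
  genotype <- match.arg(genotype)
  spec <- genome$spec
  if (!stage %in% unique(genome$window_truth$stage))
    stop("unknown stage: ", stage)
  seed <- seed %||% genome$seed
  set.seed(derive_seed(seed, "sample", stage, genotype, replicate))
  depth <- depth %||% spec$depth

  truth <- cpg_truth_levels(genome, stage, genotype)
  p_obs <- truth + (1 - truth) * spec$conversion_error
  n <- length(p_obs)
  if (noiseless) {
    d <- rep(as.integer(round(depth)), n)
    n_meth <- as.integer(round(p_obs * d))
  } else {
    d <- pmax(1L, rpois(n, depth))
    if (spec$dispersion > 0) {
      rho <- spec$dispersion
      a <- p_obs * (1 - rho) / rho
      b <- (1 - p_obs) * (1 - rho) / rho
      p_i <- ifelse(p_obs <= 0, 0, ifelse(p_obs >= 1, 1, rbeta(n, pmax(a, 1e-8), pmax(b, 1e-8))))
    } else {
      p_i <- p_obs
    }
    n_meth <- rbinom(n, d, p_i)
  }
  calls <- data.table(chrom = genome$cpgs$chrom, pos = genome$cpgs$pos,
                      n_meth = as.integer(n_meth),
                      n_unmeth = as.integer(d - n_meth))
  if (per_strand) {
    mp <- rbinom(n, calls$n_meth, 0.5)
    up <- rbinom(n, calls$n_unmeth, 0.5)
    plus <- calls[, .(chrom, pos, n_meth = as.integer(mp), n_unmeth = as.integer(up))]
    minus <- calls[, .(chrom, pos = pos + 1L,
                       n_meth = as.integer(n_meth - mp),
                       n_unmeth = as.integer(n_unmeth - up))]
    calls <- rbind(plus, minus)[n_meth + n_unmeth > 0]
  }
  setorder(calls, chrom, pos)
  calls[]
}

#' Simulate per-window ChIP IP and input counts for one histone mark
#'
#' Input counts are Poisson around a flat background; IP counts are Poisson
#' around `background * fold` at the mark's truth windows and around the
#' background elsewhere. `H3K9me3` truth windows are the IAP/satellite-marked
#' windows; the other marks (H3K4me3, H3K4me1, H3K27ac, H3K27me3) sit on
#' gene-promoter windows.
#'
#' @param genome A `"synthetic_genome"`.
#' @param mark Mark name.
#' @param seed Seed; defaults to the genome's master seed.
#' @param background,fold Overrides of the spec's Poisson background and
#'   enrichment fold.
#' @return `data.table` with `chrom`, `start`, `end`, `ip`, `input`;
#'   attribute `truth_windows`.
#' @export
simulate_chip <- function(genome, mark = "H3K9me3", seed = NULL,
                          background = NULL, fold = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  seed <- seed %||% genome$seed
  set.seed(derive_seed(seed, "chip", mark))
  bg <- background %||% genome$spec$chip_background
  fd <- fold %||% genome$spec$chip_fold
  win <- genome$windows
  if (mark == "H3K9me3") {
    truth_win <- genome$marked_windows
  } else {
    promoter <- window_id(genome$genes$chrom,
                          window_start(genome$genes$start + 1L, genome$spec$window_size))
    truth_win <- sort(unique(promoter))
  }
  lambda_ip <- ifelse(win$window %in% truth_win, bg * fd, bg)
  out <- data.table(chrom = win$chrom, start = win$start, end = win$end,
                    ip = rpois(nrow(win), lambda_ip),
                    input = rpois(nrow(win), bg))
  setattr(out, "truth_windows", truth_win)
  out[]
}

#' Simulate a gene-level FPKM matrix
#'
#' Log-normal FPKM per gene per replicate around the genome's per-gene
#' baseline. The knocked-out gene (`Dppa3`) collapses to ~0 FPKM in KO
#' samples; the derepressed gene (`Chkb`) is elevated 10-fold; every other
#' gene shares its baseline between genotypes.
#'
#' @param genome A `"synthetic_genome"`.
#' @param seed Seed; defaults to the genome's master seed.
#' @param n_replicates Replicates per genotype (default: spec).
#' @param sd_log2 Replicate noise SD on the log2 scale.
#' @return `data.table` with a `gene` column and one column per sample
#'   (`control_1`, ..., `ko_1`, ...); attribute `truth_de`.
#' @export
simulate_expression <- function(genome, seed = NULL, n_replicates = NULL,
                                sd_log2 = 0.2) {
  stopifnot(inherits(genome, "synthetic_genome"))
  seed <- seed %||% genome$seed
  set.seed(derive_seed(seed, "expression"))
  reps <- n_replicates %||% genome$spec$replicates
  base <- genome$gene_baseline
  ko_mean <- base
  ko_mean["Dppa3"] <- 0.01
  ko_mean["Chkb"] <- base["Chkb"] * 10
  draw <- function(mu) 2^(log2(mu) + rnorm(length(mu), 0, sd_log2))
  out <- data.table(gene = names(base))
  for (r in seq_len(reps)) out[[paste0("control_", r)]] <- draw(base)
  for (r in seq_len(reps)) out[[paste0("ko_", r)]] <- draw(ko_mean)
  setattr(out, "truth_de", genome$truth$de_genes)
  out[]
}

#' Write the synthetic genome's annotations and truth tables to disk
#'
#' Emits plain-text files in the formats the analysis modules consume:
#' `repeats.bed` (name field `family|class`), `icrs.bed`, `genes.bed`,
#' `exons.bed`, `chrom_sizes.tsv`, `cpg_positions.tsv.gz`, and truth tables
#' `truth_windows.tsv`, `truth_icrs.tsv`.
#'
#' @param genome A `"synthetic_genome"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genome_annotations <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    repeats = file.path(dir, "repeats.bed"), icrs = file.path(dir, "icrs.bed"),
    genes = file.path(dir, "genes.bed"), exons = file.path(dir, "exons.bed"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    cpg_positions = file.path(dir, "cpg_positions.tsv.gz"),
    truth_windows = file.path(dir, "truth_windows.tsv"),
    truth_icrs = file.path(dir, "truth_icrs.tsv")
  )
  fwrite(genome$repeats[, .(chrom, start, end, name = paste(family, class, sep = "|"))],
         paths["repeats"], sep = "\t", col.names = FALSE)
  fwrite(genome$icrs, paths["icrs"], sep = "\t", col.names = FALSE)
  fwrite(genome$genes, paths["genes"], sep = "\t", col.names = FALSE)
  fwrite(genome$exons, paths["exons"], sep = "\t", col.names = FALSE)
  fwrite(data.table(chrom = names(genome$chrom_sizes),
                    size = as.integer(genome$chrom_sizes)),
         paths["chrom_sizes"], sep = "\t", col.names = FALSE)
  fwrite(genome$cpgs[, .(chrom, pos)], paths["cpg_positions"], sep = "\t",
         compress = "gzip")
  fwrite(genome$truth$windows, paths["truth_windows"], sep = "\t")
  fwrite(genome$truth$icrs, paths["truth_icrs"], sep = "\t")
  invisible(paths)
}
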