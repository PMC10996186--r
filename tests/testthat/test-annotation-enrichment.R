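# A hand-built 1-Mb toy chromosome with known annotation, used for
# brute-force comparisons.
toy_annotation <- function() {
  repeats <- data.table(
    chrom = "chrT",
    start = c(100000L, 300000L, 300500L, 600000L),
    end   = c(110000L, 301000L, 301500L, 640000L),
    family = c("IAP-toy", "B1-toy", "B1-toy", "L1-toy"),
    class = c("LTR", "SINE", "SINE", "LINE"))
  genes <- data.table(chrom = "chrT", start = 800000L, end = 900000L, name = "GeneA")
  exons <- data.table(chrom = "chrT", start = c(800000L, 880000L),
                      end = c(810000L, 890000L), name = "GeneA")
  annotation_set(repeats, genes = genes, exons = exons,
                 chrom_sizes = c(chrT = 1000000L))
}

# per-base precedence labelling oracle over the 1-Mb toy chromosome
oracle_context <- function(regions, ann) {
  lab <- rep("intergenic", 1000000L)
  paint <- function(tbl, value) {
    for (i in seq_len(nrow(tbl)))
      lab[(tbl$start[i] + 1):tbl$end[i]] <<-
        ifelse(lab[(tbl$start[i] + 1):tbl$end[i]] == "intergenic", value,
               lab[(tbl$start[i] + 1):tbl$end[i]])
  }
  # paint in precedence order: earlier paint wins because later ones only
  # fill bases still labelled intergenic
  for (cl in c("LTR", "LINE", "SINE", "satellite"))
    paint(ann$repeats[class == cl], cl)
  paint(ann$exons, "exon")
  gene_only <- ann$genes
  paint(gene_only, "intron")   # remaining gene bases
  sel <- unlist(lapply(seq_len(nrow(regions)),
                       function(i) (regions$start[i] + 1):regions$end[i]))
  table(factor(lab[sel])) / length(sel)
}

test_that("context proportions follow the precedence rule and sum to one", {
  ann <- toy_annotation()
  inside_ltr <- data.table(chrom = "chrT", start = 101000L, end = 105000L)
  p <- context_proportions(inside_ltr, ann)
  expect_equal(unname(p["LTR"]), 1.0)
  expect_equal(sum(p), 1.0)

  half <- data.table(chrom = "chrT", start = 620000L, end = 660000L)  # 20k LINE + 20k intergenic
  p2 <- context_proportions(half, ann)
  expect_equal(unname(p2["LINE"]), 0.5)
  expect_equal(unname(p2["intergenic"]), 0.5)
  expect_error(context_proportions(data.table(chrom = character(), start = integer(),
                                              end = integer()), ann), "non-empty")
})

test_that("context proportions match a per-base brute-force oracle", {
  ann <- toy_annotation()
  set.seed(19)
  regions <- data.table(chrom = "chrT", start = sort(sample.int(950000L, 25)))
  regions[, end := start + sample(c(5000L, 20000L, 50000L), 25, replace = TRUE)]
  regions <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end)))
  regions <- data.table(chrom = "chrT", start = GenomicRanges::start(regions) - 1L,
                        end = GenomicRanges::end(regions))
  got <- context_proportions(regions, ann)
  want <- oracle_context(regions, ann)
  for (nm in names(want)) expect_equal(unname(got[nm]), unname(want[nm]))
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("fold enrichment is 1 for the genome against itself and scales shares", {
  ann <- toy_annotation()
  genome <- data.table(chrom = "chrT", start = 0L, end = 1000000L)
  fold <- context_fold_enrichment(genome, ann)
  present <- names(fold)[!is.na(fold) & fold != 0]
  expect_true(all(abs(fold[present] - 1) < 1e-12))

  # LTR occupies 1% of the genome; a region set where it occupies 20% -> fold 20
  reg <- data.table(chrom = "chrT", start = c(100000L, 200000L), end = c(110000L, 240000L))
  f2 <- context_fold_enrichment(reg, ann)
  expect_equal(unname(f2["LTR"]), (10000 / 50000) / (10000 / 1e6))
  # satellite is absent from the toy genome -> NA
  expect_true(is.na(f2["satellite"]) || f2["satellite"] == 0)
})

test_that("repeat-family aggregation honours the 50-copy floor and a per-copy oracle", {
  set.seed(23)
  n_a <- 60; n_b <- 49
  copies <- data.table(
    chrom = "chrT",
    start = seq(0, by = 2000, length.out = n_a + n_b),
    family = c(rep("FamA", n_a), rep("FamB", n_b)),
    class = "LTR")
  copies[, end := start + 1000L]
  ann <- annotation_set(copies, chrom_sizes = c(chrT = 1e6))
  calls <- random_calls(3000, chrom = "chrT", max_pos = 250000)
  ctl <- calls
  ko <- copy(calls)[, n_meth := pmin(n_meth + 2L, n_meth + n_unmeth)]
  fam <- repeat_family_methylation(ctl, ko, ann, min_copies = 50)
  expect_equal(fam$family, "FamA")          # FamB has 49 copies
  expect_equal(fam$n_copies, 60L)

  # per-copy brute force: pool constituent-site counts over all copies
  fam_a <- copies[family == "FamA"]
  lv <- interval_levels(ctl, fam_a)
  expect_equal(fam$level_control, sum(lv$meth_reads) / sum(lv$total_reads))

  # splitting the copies into two batches and recombining counts is neutral
  lv1 <- interval_levels(ctl, fam_a[1:30]); lv2 <- interval_levels(ctl, fam_a[31:60])
  expect_equal(fam$level_control,
               (sum(lv1$meth_reads) + sum(lv2$meth_reads)) /
                 (sum(lv1$total_reads) + sum(lv2$total_reads)))

  # fully unmethylated in both genotypes -> delta 0
  un <- copy(ctl)[, n_meth := 0L]
  fam0 <- repeat_family_methylation(un, un, ann, min_copies = 50)
  expect_equal(fam0$delta_pp, 0)
})

test_that("hyper families are ranked by descending delta above a strict threshold", {
  s <- data.table(family = c("a", "b", "c"), class = "LTR", n_copies = 100L,
                  n_cpg = 10L, level_control = 0.1,
                  level_ko = c(0.40, 0.22, 0.19))
  s[, delta_pp := 100 * (level_ko - level_control)]
  r <- rank_hyper_families(s)
  expect_equal(r$family, c("a", "b"))
  expect_equal(r$rank, 1:2)
  expect_equal(nrow(rank_hyper_families(s, delta_threshold = 50)), 0L)
})

test_that("ICR fold-increase flags follow the 1.3-fold strict threshold", {
  icrs <- data.table(chrom = "chrT", start = c(0L, 10000L, 20000L),
                     end = c(5000L, 15000L, 25000L), name = c("a", "b", "c"))
  ann <- annotation_set(data.table(chrom = "chrT", start = 0L, end = 1L,
                                   family = "x", class = "LTR"),
                        icrs = icrs, chrom_sizes = c(chrT = 1e6))
  mkcalls <- function(levels) rbindlist(lapply(1:3, function(i)
    make_calls("chrT", icrs$start[i] + seq(100, 1000, by = 100),
               round(levels[i] * 100), 100 - round(levels[i] * 100))))
  r <- icr_methylation(mkcalls(c(0.10, 0.10, 0)), mkcalls(c(0.14, 0.12, 0.2)), ann)
  expect_equal(r$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(r$fold_increase[1:2], c(1.4, 1.2))
  expect_false(r$fold_defined[3])            # control level 0: fold undefined
  expect_true(is.na(r$fold_increase[3]))
})

test_that("planted ICR retention and family ranking are recovered on synthetic data", {
  g <- build_genome(tiny_spec(), seed = 41)
  ann <- annotation_set(g$repeats, icrs = g$icrs,
                        chrom_sizes = g$chrom_sizes[names(g$spec$chrom_sizes)])
  pool <- function(gt) pool_replicates(list(
    filter_coverage(simulate_sample(g, "E13.5", gt, 1, seed = 41)),
    filter_coverage(simulate_sample(g, "E13.5", gt, 2, seed = 41))))
  pc <- pool("control"); pk <- pool("KO")
  r <- icr_methylation(pc, pk, ann)
  truth <- g$truth$icrs
  expect_equal(sort(r[flagged == TRUE, name]), sort(truth[retained == TRUE, name]))
  expect_equal(nrow(r), 15L)

  # the IAP-like family carries the largest planted effect -> rank 1, with
  # the satellite block also hypermethylated; the low-copy family is absent
  fam <- repeat_family_methylation(pc, pk, ann)
  expect_false("RLTR-rare" %in% fam$family)
  hyper <- rank_hyper_families(fam)
  expect_equal(hyper$family[1], "IAPEz-like")
  expect_true("GSAT-like" %in% hyper$family)
})
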