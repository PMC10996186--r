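# Differential-expression filter on a gene-level FPKM matrix.

#' Differentially expressed genes by the joint FPKM / fold / t-test filter
#'
#' A gene is called differentially expressed when (1) its mean FPKM is at
#' least `fpkm_min` in the control or the KO group, (2) the group fold-change
#' strictly exceeds `fold_min` in either direction, and (3) a two-sided Welch
#' t-test on `log2(FPKM + pseudocount)` across replicates gives
#' `p < alpha`. Fold-changes are computed on group-mean FPKM with the same
#' pseudocount, which keeps genes silent in one group finite.
#'
#' @param fpkm Numeric matrix or data.frame of FPKM values, genes in rows
#'   (rownames = gene ids, or a `gene` column), samples in columns. Annotated
#'   small RNAs (microRNA, snRNA) are assumed excluded upstream.
#' @param group_control,group_ko Column names of the two replicate groups
#'   (at least 2 each).
#' @param fpkm_min Minimum group-mean FPKM in either group (default 1).
#' @param fold_min Fold-change threshold, strict (default 4).
#' @param alpha p-value threshold, strict (default 0.05).
#' @param pseudocount Pseudocount in FPKM units (default 0.1).
#' @return `data.table` with per-gene `mean_control`, `mean_ko`,
#'   `fold_change` (KO over control, pseudocounted), `log2_fc`, `p_value`,
#'   `de` (logical), `direction` (`"up"`/`"down"` in KO, `NA` otherwise).
#' @export
de_genes <- function(fpkm, group_control, group_ko, fpkm_min = 1, fold_min = 4,
                     alpha = 0.05, pseudocount = 0.1) {
  if (is.data.frame(fpkm) && "gene" %in% names(fpkm)) {
    genes <- as.character(fpkm$gene)
    mat <- as.matrix(as.data.frame(fpkm)[, setdiff(names(fpkm), "gene"), drop = FALSE])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(fpkm)
  }
  if (is.null(rownames(mat))) stop("fpkm needs gene identifiers (rownames or a 'gene' column)")
  miss <- setdiff(c(group_control, group_ko), colnames(mat))
  if (length(miss)) stop("sample column(s) not found: ", paste(miss, collapse = ", "))
  if (length(group_control) < 2 || length(group_ko) < 2)
    stop("each group needs at least 2 replicates for the t-test")
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")

  mc <- rowMeans(mat[, group_control, drop = FALSE])
  mk <- rowMeans(mat[, group_ko, drop = FALSE])
  lc <- log2(mat[, group_control, drop = FALSE] + pseudocount)
  lk <- log2(mat[, group_ko, drop = FALSE] + pseudocount)
  wt <- welch_p(rowMeans(lc), rowMeans(lk),
                apply(lc, 1, var), apply(lk, 1, var),
                length(group_control), length(group_ko))
  fold <- (mk + pseudocount) / (mc + pseudocount)
  out <- data.table(gene = rownames(mat), mean_control = mc, mean_ko = mk,
                    fold_change = fold, log2_fc = log2(fold), p_value = wt$p)
  out[, de := (mean_control >= fpkm_min | mean_ko >= fpkm_min) &
        (fold_change > fold_min | fold_change < 1 / fold_min) &
        p_value < alpha]
  out[, direction := fifelse(!de, NA_character_,
                             fifelse(fold_change > 1, "up", "down"))]
  out[]
}

utils::globalVariables(c("de", "log2_fc", "mean_control", "mean_ko"))
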