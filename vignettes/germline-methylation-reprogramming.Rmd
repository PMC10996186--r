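---
title: "Windowed methylation analysis of germline reprogramming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed methylation analysis of germline reprogramming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcmeth)
library(data.table)
```

## The problem

Mouse primordial germ cells (PGCs) erase most of their CpG methylation between
embryonic day E9.5 and E13.5; female germ cells then stay hypomethylated until
de novo methylation during postnatal oocyte growth. A maternal-effect factor
knockout perturbs this erasure: knockout (KO) PGCs retain methylation, most
strongly at H3K9me3-marked retrotransposons (IAP-family LTR elements, the
major satellite), at a subset of imprinting control regions (ICRs), and this
retention can persist into fully grown oocytes (FGOs). `pgcmeth` implements
the quantitative core of such a study as a reusable, tested pipeline: from
CpG-level bisulfite calls to windowed levels, differentially methylated
regions (DMRs), repeat/ICR/chromatin association, and cross-stage persistence
classification — together with a synthetic-data generator that reproduces the
statistical structure of the system so that every stage can be validated
against known truth.

## Quantities and models

**Weighted methylation level.** For any region, the level is
$\sum_i m_i / \sum_i (m_i + u_i)$ over CpG sites $i$, with $m_i$/$u_i$
methylated/unmethylated read counts. Read-count weighting is depth-robust; a
mean of per-site fractions would give shallow sites the same weight as deep
ones. Concatenating the fixed-grid windows reproduces the global level
exactly, a property the tests assert.

**Coverage filter.** Only CpG sites covered by 3–100 reads (closed interval)
are informative: the floor removes unreliable shallow calls, the ceiling
removes collapsed repeats and amplification artifacts. Replicates are pooled
by *summing counts* (not averaging levels) and the filter is re-applied to
the pooled counts. The percent column of input coverage files is never
trusted; levels are always recomputed from the counts.

**Fixed grid.** Windows of 10 kb tile each chromosome from coordinate 0 and
are identified by `(chrom, start)`; a window with fewer than five informative
CpGs is dropped. Fixed identity — rather than interval overlap — is what
makes windows comparable across samples and stages, which the fate analysis
depends on. A CpG at 1-based position $p$ belongs to the window containing
the 0-based coordinate $p-1$.

**DMR definition.** A window is differentially methylated between matched
control and KO samples when (i) the difference of weighted levels exceeds 10
percentage points in magnitude (strict inequality, so a difference of exactly
10.0 is not a DMR) and (ii) a two-sided Welch t-test gives $p < 0.05$. No
multiple-testing correction is applied: the definition is deliberately a
joint effect-size + raw-p filter. Because replicates are pooled before
windowing, the only replication unit left inside a window is the CpG site;
the t-test therefore compares the per-CpG methylation fractions of the sites
shared by both samples (windows with fewer than 2 shared sites are excluded
from the tested universe). Alternatives (across replicates, across reads)
would be selectable where replicate-level windows are retained, but pooling
matches how scarce-cell data are actually processed. Degenerate zero-variance
windows get $p = 1$ when the group means agree and $p = 0$ when they differ.
The vectorized Welch computation is cross-checked against `stats::t.test`
window by window in the test suite.

**Repeat families and ICRs.** Family-level methylation aggregates counts over
the union of a family's genomic copies (a CpG under two copies of the same
family counts once); only families with ≥ 50 genomic copies are reported,
since copy-number supports the aggregate. Hypermethylated families are those
with a KO−control difference > 10 points, ranked by the difference. ICRs are
summarized by their weighted level and the KO/control fold-increase; folds
above 1.3 (strict) are flagged, and a control level of exactly zero leaves
the fold undefined rather than infinite.

**Genomic context.** Hypermethylated regions are decomposed by base-pair
share into LTR, LINE, SINE, satellite, other-repeat, exon, intron and
intergenic using that precedence order (repeat annotation outranks genic
annotation where they overlap; the underlying data give no precedence rule,
and foregrounding repeat classes matches how such decompositions are usually
drawn). Shares sum to one, and fold-enrichment divides a category's share of
the regions by its share of the whole genome.

**Chromatin association.** Per-window ChIP enrichment is the library-size
normalized log2 IP/input ratio with a pseudocount:
$\log_2\!\frac{ip_w/IP + \varepsilon}{in_w/IN + \varepsilon}$ with
$\varepsilon = \text{pseudocount}/\sqrt{IP \cdot IN}$. Upstream figure-level
pipelines do not pin down a per-window formula, so this one is fixed here and
the pseudocount exposed; only *relative* comparisons (medians of one window
set against another) are treated as meaningful. Top-quantile selection takes
the $\lceil qN \rceil$ highest-scoring windows with ties broken by genomic
order, which makes the selection deterministic and nested across $q$.

**Fate classification.** Given per-stage hyper-window sets on the shared
grid, windows partition into: `persistent_to_FGO` (hyper at E13.5 or E16.5
and again in FGOs), `PGC_only` (hyper at E13.5/E16.5, resolved before FGO),
`FGO_only`, `E11.5_and_FGO`, and `lost_after_E11.5`. Every percentage is
reported as `100 * count / denominator` with the denominator recorded;
rounding to integers is display-only. FGO hypermethylation is assumed to use
the same DMR definition as the PGC stages.

**Expression filter.** A gene is differentially expressed when its mean FPKM
reaches 1 in either group, the group fold-change strictly exceeds 4, and a
two-sided Welch t-test on $\log_2(\text{FPKM} + 0.1)$ across replicates gives
$p < 0.05$. The 0.1 pseudocount (in FPKM units) keeps silenced genes finite;
the source analysis does not state its zero handling, so this choice is made
explicit and exposed.

## The synthetic genome

`synthetic_genome_spec()` defines the simulated study. Defaults:

* **Genome**: four 5-Mb chromosomes plus a 48.5-kb unmethylated spike-in
  contig; CpGs every ~100 bp with ±40 bp jitter (~200k dyads, 2,000 grid
  windows — sized so the full pipeline runs end-to-end in a few minutes on
  one CPU).
* **Annotations**: an IAP-like LTR family (200 copies × 3 kb, each centered
  in its own window), a 60-copy tandem satellite block, LINE-like and
  SINE-like scattered families, one 30-copy family below the reporting floor,
  40 genes with exons, and 15 named ICRs on their own windows.
* **Trajectory**: control baselines epiblast 0.70, E9.5 0.30, E10.5 0.15,
  E11.5 0.091, E12.5 0.05, E13.5 0.025, E16.5 0.022, GO 0.15; the FGO
  landscape is bimodal (47% of background windows at 0.85, the rest at 0.05,
  global ≈ 0.40). Per-window truth jitters around the baseline (SD 0.02) and
  is shared between genotypes and replicates. The printed global levels of
  the study anchor these values; they are generator conventions, not
  estimates.
* **KO effect**: +0.30 at H3K9me3-marked windows (IAP + satellite, the
  satellite at +0.26 so the IAP-like family carries the largest
  family-level effect); half of the marked windows persist through FGO, half
  resolve ("PGC only"). 300 unmarked windows are hyper at E11.5 only and
  decay to a 1–1.5 point residual ("lost"); 200 windows gain methylation only
  in KO FGOs. ICR erasure leaves a 0.12 residual at E13.5/E16.5 over 8-kb
  ICRs, which puts the 1.3-fold retention flag about three standard errors
  above the read noise of an unaffected ICR at this depth — a fully erased 2%
  denominator would make the flag a coin flip — and five ICRs retain 0.45 in
  the KO, the set that downstream flagging must recover.
* **Reads**: depth Poisson(15) floored at one read; per-site beta-binomial
  with overdispersion 0.05 (biological/within-window heterogeneity — pure
  binomial would understate replicate scatter); bisulfite conversion failure
  0.005 inflates observed levels by $(1-t)\cdot 0.005$; two replicates per
  sample. `noiseless = TRUE` replaces all draws by expected counts, the
  infinite-depth limit in which the fate classifier must recover the planted
  partition *exactly* — which the acceptance tests assert.

Everything is deterministic given the master seed, via hierarchical per-use
sub-seeds, so reruns are byte-identical (checked on pipeline manifests).

What the generator does **not** emulate: real sequence context (CpG islands,
C-density gradients), correlated erasure along chromosomes, copy-number
variation inside repeat families, strand-specific artifacts, or
hydroxymethylation. Tests passing on this generator therefore demonstrate the
*algorithmic* correctness and calibration of the pipeline under its stated
noise model, not concordance with any particular real dataset.

## Numerical choices and degenerate inputs

* Coverage bounds inclusive on both sides; the filter is idempotent.
* Strand merging is on by default (dyad counts summed onto the plus-strand
  coordinate); records not matching a known dyad pass through unchanged.
* Zero-variance t-tests: equal means → $p = 1$; unequal means → $p = 0$.
* Quantile ties broken by genomic order; `order()`'s stability provides this.
* ICR fold at control level 0: undefined, flagged as such, never infinite.
* Window size 0, negative counts, empty region sets, unknown stages and
  mismatched grids raise validation errors naming the offending input.
* Derived seeds stay below $2^{31}$ so they are valid R integer seeds.

## Problem sizes used in validation

The test-suite and acceptance checks run at desk scale: the default 20-Mb
genome (~200k CpGs, 2,000 windows) for end-to-end recall, ICR and fate
checks; a single 100-Mb chromosome (10,000 windows at mean depth 20) for the
null calibration of the DMR caller, whose false-positive rate must sit at the
nominal α = 0.05 within Monte-Carlo error; and a 1-Mb toy chromosome for
per-base and per-site brute-force oracles. Genome-scale window counts from
the original study (tens of thousands of DMRs) depend on the deposited mouse
data and are not reproducible at this scale; what is checked instead is the
arithmetic consistency of that printed count system when pushed through the
same summary and fate code paths.

## A worked example

```{r example, eval = FALSE}
genome <- build_genome(synthetic_genome_spec(), seed = 7)
ctl <- pool_replicates(lapply(1:2, function(r)
  filter_coverage(simulate_sample(genome, "E11.5", "control", r, seed = 7))))
ko <- pool_replicates(lapply(1:2, function(r)
  filter_coverage(simulate_sample(genome, "E11.5", "KO", r, seed = 7))))
global_level(ctl)            # ~0.096: the E11.5 erasure trough
global_level(ko)             # ~0.172: impaired erasure in the knockout
dmr <- call_dmrs(ctl, ko)    # 511 hyper / 0 hypo of 2000 windows
summarize_dmrs(dmr)
```

Or the whole pipeline in one call, writing per-stage outputs and a manifest:

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(list(seed = 7, out_dir = "pgcmeth_run"))
```

## Known limitations

* The site-level t-test treats CpGs within a window as exchangeable
  replicates; spatially structured methylation inside a window (e.g. a CpG
  island boundary) violates this, and the caller will average across it.
* Pooling discards replicate-level variance; with more than a handful of
  replicates a replicate-level test would be preferable.
* Context precedence is a convention; a different precedence changes the
  decomposition of bases under overlapping annotations.
* The enrichment score is one of several defensible normalizations; scores
  are comparable within a track, not across marks or experiments.
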