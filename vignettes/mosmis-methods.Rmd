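---
title: "Methods: two-pass cell-cycle phase assignment with mitotic marker lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pass cell-cycle phase assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosmis)
```

## The problem

Cell-cycle phase is one of the strongest drivers of expression variance
between single cells, and discrete phase classifiers conventionally stop at
G1/S/"G2M": the transition from G2 into mitosis is not marked by wholesale
reprogramming, so a single gene-list score cannot separate the two. Yet
genes *are* differentially expressed between mitotic and interphase cells —
spindle, kinetochore and anaphase-promoting-complex components rise in
mitosis, while replication-licensing and G1/S transcription-factor
programmes (E2F1, cyclin E, MCM genes) are relatively depleted. `mosmis`
exploits exactly that contrast, in a second assignment pass restricted to
the cells a first pass could not resolve.

## Model and procedure

### Normalization

Raw counts are relative-counts normalized: each cell's counts are divided
by the cell total, multiplied by a scale factor (default $10^4$) and
`log1p`-transformed. Cells with zero total counts are kept as all-zero rows
with a warning rather than failing, and the zero pattern of the matrix is
preserved exactly. Variance-stabilizing alternatives (rlog/vst) are not
implemented; log relative counts is the single supported transform, for
scoring and for the holdout-expression measurements alike.

### The binned-control module score

For a marker set $T$ and cell $c$ with normalized expression $x_{cg}$:

$$\mathrm{score}(c) = \frac{1}{|T|}\sum_{g \in T} x_{cg}
  \;-\; \frac{1}{|C|}\sum_{g \in C} x_{cg}$$

where the control pool $C$ is built once per (matrix, gene set, seed):
genes are ranked by mean expression across cells and split into `n_bins`
equal-frequency bins (default 24); each target gene contributes `n_ctrl`
(default 100) genes sampled from its own bin, excluding all target genes —
without replacement when the bin offers enough candidates, with replacement
otherwise — and the draws are pooled *with multiplicity*. Matching controls
on pooled mean expression makes the score a contrast against
expression-matched background: in a cell outside the programme, marker
genes sit below their bin-mates and the score goes negative.

Numerical details, fixed so that scores are exactly reproducible:

* Binning is by *rank* (stable, ties broken by column order): gene with
  rank $r$ of $G$ goes to bin $\lceil r \cdot n_\mathrm{bins} / G \rceil$.
  Rank-based binning makes scores invariant under adding a constant to
  every value, a property the test suite asserts.
* If excluding target genes empties a bin's candidate pool, candidates
  fall back to the bin minus the gene itself, then to the gene alone. This
  keeps the score defined when the target set covers a whole bin (or the
  entire gene universe, where the score is identically zero on a flat
  matrix).
* Control sampling is seeded (`module_score_config(seed = )`, default 0)
  and the caller's RNG state is restored afterwards; one `sample()` call
  per target gene, in gene-set order.

The engine is vectorized but is held, bit-for-bit, to an independently
written loop implementation of the same rules in the test suite, across
seeds and random instances.

### First pass: G1 / S / G2M

Cells are scored against the standard 43-gene S and 54-gene G2/M lists
(the Tirosh-derived lists that Seurat ships, packaged here as static
data). Assignment is by thresholded argmax: S if the S score exceeds both
the G2/M score and zero; G2M if the G2/M score is at least the S score and
positive — an exact positive tie goes to G2M; G1 when neither score is
positive. Non-finite scores are an error naming the offending cell.

### Second pass: G2 vs M

The pooled G2M cells are re-scored against the packaged mitotic list (27
genes upregulated in pH3-sorted mitotic cells, with their log2 fold
changes and adjusted p-values) and the interphase list (17 genes
downregulated in that comparison, three of them kept under Ensembl
identifiers as published). Control bins are rebuilt on the pool itself —
the relevant background for a within-pool contrast is the pool, not the
full dataset. A cell is called M when its mitotic score exceeds both the
interphase score and zero; **all other cases, including ties and
both-negative scores, resolve to G2**. The rationale for the default:
within a G2/M pool, absence of mitotic signal is the interphase-like
state, so G2 is the conservative call; a third "undecided" label would
push the ambiguity onto every downstream user.

The published table of interphase genes has 17 rows while the
accompanying text mentions 18 genes of interest; the packaged list follows
the printed table and the discrepancy is documented rather than resolved.
Likewise a few packaged padj values sit above the nominal derivation
cut-off (e.g. KIF20B at 0.01); the lists are packaged verbatim, not
re-filtered.

### Gene matching

Matrix gene symbols are upper-cased on load and matched to marker lists by
exact string equality. Duplicated symbols are made unique by suffixing
`.1`, `.2`, ... (so only the first occurrence can match a list). No alias
or identifier translation is attempted — matching stays auditable, and
murine symbols match through the upper-casing rule alone.

## Marker-list derivation and validation

`derive_phase_genesets()` filters a DESeq2-style results table: rows with
adjusted p-value strictly below `padj_max` (default 0.001; missing padj
never survives) and absolute log2 fold change of at least `lfc_min`
(default 0.58, i.e. a 1.5-fold change; the boundary is admitted) are kept
and split by fold-change sign — positive to the mitotic list, negative to
the interphase list — each sorted by ascending padj.

`kfold_holdout_validation()` is a self-consistency check of a marker pair:
each list is shuffled (seeded) and split into `k` folds (default 4) whose
sizes differ by at most one and which cover the list exactly. Per fold,
the second-pass assignment is re-run with the held-out genes removed, and
each held-out gene's mean log-normalized expression is compared between
the M- and G2-assigned cells. The test is a paired one-sided t-test
*across held-out genes* (the gene is the replicated unit being held out;
pairing is the same gene's mean in the two cell groups), in the direction
the list implies — mitotic genes higher in M-assigned cells, interphase
genes higher in G2-assigned cells. By default a fold of *both* lists is
removed simultaneously before re-assignment; `holdout = "mitotic"` or
`"interphase"` removes one list at a time, keeping the other complete. A
fold whose re-assignment leaves either cell group empty, or with fewer
than two measurable held-out genes, is reported as degenerate with missing
statistics rather than failing the run. The first-pass pool is computed
once from the full first-pass lists and shared across folds — holding out
second-pass genes cannot change who is in the pool.

## The simulator: what it emulates, and what it does not

`simulate_phased_counts()` generates the structure the assignment relies
on, with known labels:

* a shared G2/M programme (the packaged 54-gene list) expressed by M cells
  at `marker_fold` and by G2 cells at `max(1, g2m_bleed * marker_fold)`
  (default bleed 0.5) — this is what makes the first pass pool G2 with M,
  the premise of the two-pass design;
* phase-specific programmes: the S list in S cells, the 27-gene mitotic
  list in M cells only, the 17-gene interphase list in G2 cells only, all
  at `marker_fold`; a gene on several lists takes the largest applicable
  fold. G1 cells are baseline throughout;
* negative-binomial counts with variance $m + \alpha m^2$ (default
  dispersion $\alpha = 0.4$), log-normal library-size factors (default
  CV 0.3), and log-normal per-gene base means around `base_mean`
  (default 2, sdlog 1). The spread of base means matters: with flat means
  the expression bins are arbitrary and bin-matched controls carry no
  information, so out-of-phase cells would score near zero instead of
  below it. Real data has this spread over orders of magnitude.

Defaults are 100 cells per phase, 2000 background genes and a 6-fold
marker effect — deliberately strong, clean signal. `marker_fold = 1`
switches all phase signal off (the bleed collapses to 1 as well), giving
an exact null. Not emulated: dropout/zero inflation beyond what NB
sampling produces, doublets, batch effects, ambient RNA, continuous
cell-cycle progression within a phase, or correlation structure between
genes beyond the shared library factor. Passing tests on this simulator
therefore demonstrates that the procedure recovers the signal structure it
assumes; it does not certify accuracy on any real dataset, where marker
effect sizes are smaller and partially overlapping.

Problem sizes used by the test and acceptance runs — 400 cells ×
~2100 genes for label recovery, 200–400 cells for the holdout checks, 20
simulated null datasets for the false-positive rate — were chosen as the
smallest sizes at which the binomial/moment checks have useful power.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scale_factor` | 1e4 | relative-counts scale (counts per 10k) |
| `log1p` | TRUE | natural-log transform after scaling |
| `n_bins` | 24 | equal-frequency expression bins for controls |
| `n_ctrl` | 100 | control genes sampled per target gene |
| `seed` | 0 | control-sampling / shuffle seed |
| `k` | 4 | holdout folds (each gene held out exactly once) |
| `padj_max`, `lfc_min` | 0.001, 0.58 | derivation filter cut-offs |
| `marker_fold`, `g2m_bleed` | 6, 0.5 | simulator effect sizes |

`n_bins` and `n_ctrl` follow the conventional defaults of module scoring;
they are exposed because small matrices need `n_bins` ≤ number of genes
(violations are an error, not a silent clamp).

## Known limitations

* The G2-vs-M boundary is a hard argmax on two scores; cells near the
  transition carry no confidence measure beyond the score gap, which the
  output preserves (`m_score`, `g2_score` columns).
* Marker lists were derived in a human cancer cell line; applying them to
  other tissues or species assumes the mitotic programme is conserved at
  the symbol level.
* Scores are computed on log relative counts only; depth-dependent biases
  that rlog/vst would stabilize are not corrected.
* The simulator's independence assumptions (genes conditionally
  independent given phase and library factor) make it easier than real
  data; reported recovery rates are upper bounds in that sense.
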