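# mosmis — two-pass cell-cycle phase assignment that separates G2 from M

Discrete cell-cycle classifiers for single-cell RNA-seq (Seurat's
`CellCycleScoring`, Cyclone, and friends) stop at three labels: G1, S and a
pooled "G2/M", because G2 and mitotic cells share most of their
transcriptional programme. For anyone studying mitosis itself — mitotic DNA
damage response, death in prolonged mitosis, spindle-checkpoint biology —
that pooled label hides exactly the cells of interest.

`mosmis` resolves the pool. It ships marker lists of genes differentially
expressed between mitotic (phospho-histone H3 positive, pH3+) and interphase
cells — 27 mitotically upregulated genes (PLK1, CDC20, BUB1, CENPE, ...) and
17 interphase-enriched genes (E2F1, CCNE1, MCM5, ...) — and uses them in a
second assignment pass restricted to the G2/M pool.

## Method

For a cells × genes count matrix `X`:

1. **Normalize**: relative counts, `x_cg = log1p(X_cg / Σ_g X_cg · 10^4)`.
2. **First pass**: per-cell module scores for the standard Tirosh S (43
   genes) and G2/M (54 genes) lists. A module score is
   `score(c) = mean_{g∈targets} x_cg − mean_{g∈controls} x_cg`, where the
   controls are `n_ctrl = 100` genes per target gene drawn from the target's
   equal-frequency bin (of `n_bins = 24`) of pooled mean expression — so a
   positive score means enrichment relative to expression-matched
   background. Cells are assigned S (S score highest and positive), G2M
   (G2/M score ≥ S score and positive) or G1 (neither positive).
3. **Second pass**: cells labelled G2M are re-scored — with control bins
   rebuilt on the pool itself — against the mitotic and interphase marker
   lists. A cell becomes M when its mitotic score exceeds both the
   interphase score and zero, otherwise G2.
4. Final labels are the union: every cell gets exactly one of G1/S/G2/M, and
   `{G2} ∪ {M}` equals the first-pass G2/M pool exactly.

Also included: the threshold filter that derives such list pairs from any
DESeq2-style results table (padj < 0.001, |log2FC| ≥ 0.58, i.e. ≥ 1.5-fold),
a k-fold gene-holdout validation of any marker pair, PCA on marker genes for
visual checks, and a seeded negative-binomial simulator of phase-labelled
counts.

## Worked example

```r
library(mosmis)

sim <- simulate_phased_counts(simulation_config(
  n_cells_per_phase = c(G1 = 100, S = 100, G2 = 100, M = 100),
  marker_fold = 6, seed = 7))
res <- run_mosmis(sim$matrix)

head(res[res$first_pass == "G2M", ], 3)
#>          cell_id first_pass final     s_score g2m_score  g2_score    m_score
#> 201 cell_0201_G2        G2M    G2 -0.41566981 0.3136478 0.7305220 -0.2831691
#> 202 cell_0202_G2        G2M    G2 -0.06917513 0.2603252 0.7399938 -0.3351939
#> 203 cell_0203_G2        G2M    G2 -0.29413475 0.3409079 0.8659603 -0.4884216

phase_composition(res)
#>    phase   n percent
#> G1    G1 101   25.25
#> S      S 100   25.00
#> G2    G2  99   24.75
#> M      M 100   25.00

balanced_accuracy(res$final, sim$truth[res$cell_id])
#> [1] 0.9975
```

Each row carries the first-pass S/G2M scores for every cell and the
second-pass mitotic/interphase scores for pooled cells only; here the three
shown cells are truly-G2 cells whose interphase score dominates, so they
resolve to G2. On this 400-cell simulation the two-pass labels recover the
ground truth with 0.9975 balanced accuracy.

Validating a marker pair by holding out a quarter of each list per fold:

```r
rep <- kfold_holdout_validation(sim$matrix, k = 4, seed = 7)
rep$folds[rep$folds$list == "mitotic",
          c("fold", "n_held_out", "mean_M", "mean_G2", "t", "p")]
#>   fold n_held_out mean_M mean_G2    t        p
#> 1    1          7   2.59    1.55 4.91 0.001342
#> 3    2          7   2.42    1.21 6.46 0.000327
#> 5    3          7   3.29    2.13 5.85 0.000552
#> 7    4          6   2.39    1.56 5.06 0.001947
```

All four folds show the held-out mitotic genes more highly expressed in
M-assigned than G2-assigned cells (paired one-sided t-test across held-out
genes) — cells selected by 75% of the list carry the signal of the withheld
25%.

## Command line

A thin wrapper lives at `inst/cli/mosmis.R`:

```sh
Rscript inst/cli/mosmis.R simulate --out-dir sim --seed 0
Rscript inst/cli/mosmis.R assign --counts sim --format mtx --out phases.csv --seed 0
Rscript inst/cli/mosmis.R validate-kfold --counts sim --k 4 --out-prefix kf
Rscript inst/cli/mosmis.R derive-genesets --de de_results.csv --out-prefix lists
```

`assign` reads a 10x-style MTX triple or dense CSV, writes the assignment
CSV plus a JSON run manifest, and logs the per-phase composition. All
commands are seeded and reproducible from their manifest.

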