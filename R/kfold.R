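#' K-fold gene-holdout validation of a marker-list pair
#'
#' Self-consistency check of the G2-vs-M marker lists: each list is
#' shuffled (seeded) and split into `k` near-equal folds; for every fold
#' the second-pass assignment is re-run with the held-out genes removed,
#' and each held-out gene's mean log-normalized expression is compared
#' between the resulting M-assigned and G2-assigned cells. A paired,
#' one-sided t-test across the held-out genes (paired by gene) asks
#' whether mitotic genes are higher in M-assigned cells and interphase
#' genes higher in G2-assigned cells — if the remaining 75% of a list
#' still selects the right cells, the held-out 25% should follow.
#'
#' @param matrix an `ExpressionMatrix` with layer `raw_counts`.
#' @param m_set,g2_set the mitotic and interphase marker sets under test
#'   (defaults: the packaged lists).
#' @param k number of folds (default 4); every gene of each list is held
#'   out exactly once, fold sizes differ by at most one, and each list
#'   must have at least `k` genes matched in the matrix.
#' @param seed seed for the fold shuffle.
#' @param config a [mosmis_config()]; its first-pass sets define the G2/M
#'   pool (computed once, identical across folds).
#' @param holdout `"both"` removes a fold of both lists simultaneously
#'   before re-assigning; `"mitotic"`/`"interphase"` hold out one list at
#'   a time, keeping the other complete.
#' @return a `mosmis_fold_report`: list with `folds` (data frame: `list`,
#'   `fold`, `n_held_out`, `n_m_cells`, `n_g2_cells`, `mean_M`, `mean_G2`,
#'   `t`, `p`, `degenerate`), `held_out` (gene lists per fold), `k`,
#'   `seed`, `holdout`. A fold whose re-assignment leaves the M or G2
#'   group empty (or with fewer than two held-out genes measurable) is
#'   flagged degenerate with NA statistics.
#' @export
kfold_holdout_validation <- function(matrix,
                                     m_set = load_builtin_geneset("mitotic_table1"),
                                     g2_set = load_builtin_geneset("interphase_table2"),
                                     k = 4, seed = 0,
                                     config = mosmis_config(),
                                     holdout = c("both", "mitotic", "interphase")) {
  holdout <- match.arg(holdout)
  stopifnot(inherits(matrix, "ExpressionMatrix"), k >= 2)
  norm <- normalize_rc(matrix, config$normalization)
  for (s in list(m = m_set, g2 = g2_set)) {
    matched <- sum(s$genes %in% norm$gene_ids)
    if (matched < k) {
      stop("k = ", k, " exceeds the ", matched, " genes of set '", s$name,
           "' matched in the matrix")
    }
  }

  # First pass once; the pool is the same for every fold.
  s_scores <- module_score(norm, config$s_set, config$scoring)
  g2m_scores <- module_score(norm, config$g2m_set, config$scoring)
  pool <- which(assign_first_pass(s_scores, g2m_scores) == "G2M")
  sub <- subset_matrix(norm, cells = pool)

  folds_m <- partition_genes(m_set$genes, k, seed)
  folds_g2 <- partition_genes(g2_set$genes, k, seed + 1L)

  rows <- list()
  held_out <- list()
  for (f in seq_len(k)) {
    for (lst in c("mitotic", "interphase")) {
      ho <- if (lst == "mitotic") folds_m[[f]] else folds_g2[[f]]
      red_m <- m_set$genes
      red_g2 <- g2_set$genes
      if (holdout %in% c("both", "mitotic")) red_m <- setdiff(red_m, folds_m[[f]])
      if (holdout %in% c("both", "interphase")) red_g2 <- setdiff(red_g2, folds_g2[[f]])
      if (holdout == "mitotic" && lst == "interphase") next
      if (holdout == "interphase" && lst == "mitotic") next
      rows[[length(rows) + 1L]] <- holdout_fold_stats(
        sub, red_m, red_g2, ho, lst, f, config$scoring)
      held_out[[paste(lst, f, sep = "_")]] <- ho
    }
  }
  structure(list(folds = do.call(rbind, rows), held_out = held_out,
                 k = as.integer(k), seed = as.integer(seed),
                 holdout = holdout),
            class = "mosmis_fold_report")
}

# Seeded shuffle then split into k folds with sizes differing by <= 1;
# the folds exactly cover the input list and are pairwise disjoint.
partition_genes <- function(genes, k, seed) {
  perm <- with_rng_seed(seed, sample(genes))
  split(perm, rep(seq_len(k), length.out = length(perm)))
}

holdout_fold_stats <- function(sub, red_m_genes, red_g2_genes, held_out,
                               list_name, fold, scoring) {
  base <- data.frame(list = list_name, fold = fold,
                     n_held_out = length(held_out),
                     n_m_cells = NA_integer_, n_g2_cells = NA_integer_,
                     mean_M = NA_real_, mean_G2 = NA_real_,
                     t = NA_real_, p = NA_real_, degenerate = TRUE,
                     stringsAsFactors = FALSE)
  if (length(sub$cell_ids) == 0) return(base)
  red_m <- marker_gene_set("M", red_m_genes)
  red_g2 <- marker_gene_set("G2_interphase", red_g2_genes)
  second <- suppressWarnings(assign_second_pass(sub, red_m, red_g2, scoring))
  m_cells <- which(second$phase == "M")
  g2_cells <- which(second$phase == "G2")
  base$n_m_cells <- length(m_cells)
  base$n_g2_cells <- length(g2_cells)
  ho_idx <- match(held_out, sub$gene_ids)
  ho_idx <- ho_idx[!is.na(ho_idx)]
  if (length(m_cells) == 0 || length(g2_cells) == 0 || length(ho_idx) < 2) {
    return(base)
  }
  # per held-out gene: mean expression in each assigned group
  gm_M <- Matrix::colMeans(sub$values[m_cells, ho_idx, drop = FALSE])
  gm_G2 <- Matrix::colMeans(sub$values[g2_cells, ho_idx, drop = FALSE])
  base$mean_M <- mean(gm_M)
  base$mean_G2 <- mean(gm_G2)
  alt <- if (list_name == "mitotic") "greater" else "less"
  tt <- tryCatch(t.test(gm_M, gm_G2, paired = TRUE, alternative = alt),
                 error = function(e) NULL)
  if (!is.null(tt)) {
    base$t <- unname(tt$statistic)
    base$p <- tt$p.value
    base$degenerate <- FALSE
  }
  base
}

#' @export
print.mosmis_fold_report <- function(x, ...) {
  cat("K-fold gene-holdout report (k =", x$k, ", holdout =", x$holdout,
      ", seed =", x$seed, ")\n")
  print(x$folds)
  invisible(x)
}

#' Write a fold report as CSV plus a JSON summary
#'
#' @param report a `mosmis_fold_report`.
#' @param prefix output path prefix; writes `<prefix>_folds.csv` and
#'   `<prefix>_summary.json`.
#' @return invisibly, the two paths written.
#' @export
write_fold_report <- function(report, prefix) {
  stopifnot(inherits(report, "mosmis_fold_report"))
  csv <- paste0(prefix, "_folds.csv")
  js <- paste0(prefix, "_summary.json")
  write.csv(report$folds, csv, row.names = FALSE)
  ok <- report$folds[!report$folds$degenerate, , drop = FALSE]
  summary <- list(
    k = report$k, seed = report$seed, holdout = report$holdout,
    n_folds_reported = nrow(report$folds),
    n_degenerate = sum(report$folds$degenerate),
    n_significant_p05 = sum(ok$p < 0.05),
    held_out = report$held_out)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}
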