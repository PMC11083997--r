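#' Normalization settings
#'
#' Relative-counts normalization: each cell's counts are divided by the
#' cell total and multiplied by `scale_factor`, then (optionally)
#' `log(1 + x)` transformed. With `scale_factor = 1e4` and `log1p = TRUE`
#' this is the usual log-CP10K transform.
#'
#' @param scale_factor positive scale applied after dividing by cell totals.
#' @param log1p apply a natural-log `log(1 + x)` transform afterwards.
#' @return a `NormalizationConfig` list.
#' @export
normalization_config <- function(scale_factor = 1e4, log1p = TRUE) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1,
            scale_factor > 0, is.logical(log1p))
  structure(list(method = "relative_counts",
                 scale_factor = as.numeric(scale_factor),
                 log1p = isTRUE(log1p)),
            class = "NormalizationConfig")
}

#' Relative-counts normalization of a raw count matrix
#'
#' Cells with zero total counts are kept as all-zero rows (with a warning)
#' rather than producing NaNs; the zero pattern of the matrix is preserved
#' exactly.
#'
#' @param matrix an `ExpressionMatrix` with layer `raw_counts`.
#' @param config a [normalization_config()].
#' @return an `ExpressionMatrix` with layer `rc_normalized` or
#'   `log_normalized` depending on `config$log1p`.
#' @export
normalize_rc <- function(matrix, config = normalization_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(config, "NormalizationConfig"))
  if (matrix$layer != "raw_counts") {
    stop("normalize_rc expects the raw_counts layer, got ", matrix$layer)
  }
  v <- matrix$values
  totals <- Matrix::rowSums(v)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) have zero total counts and are kept ",
            "as all-zero rows: ",
            paste(head(matrix$cell_ids[empty], 5), collapse = ", "))
    totals[empty] <- 1  # keeps 0/1 = 0; rows stay all-zero
  }
  fac <- config$scale_factor / totals
  if (is(v, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = fac) %*% v
    if (config$log1p) out@x <- log1p(out@x)
    out <- as(out, "CsparseMatrix")
  } else {
    out <- v * fac
    if (config$log1p) out <- log1p(out)
  }
  structure(list(values = out, cell_ids = matrix$cell_ids,
                 gene_ids = matrix$gene_ids,
                 layer = if (config$log1p) "log_normalized" else "rc_normalized"),
            class = "ExpressionMatrix")
}

#' Module-score settings
#'
#' Parameters of the binned-control module score: genes are ranked by mean
#' expression across cells and split into `n_bins` equal-frequency bins;
#' each target gene contributes `n_ctrl` control genes sampled from its
#' bin. Sampling is seeded so scores are reproducible.
#'
#' @param n_bins number of equal-frequency expression bins (default 24).
#' @param n_ctrl control genes sampled per target gene (default 100).
#' @param seed RNG seed used for control sampling (default 0).
#' @return a `ModuleScoreConfig` list.
#' @export
module_score_config <- function(n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(n_bins >= 1, n_ctrl >= 1, is.numeric(seed), length(seed) == 1)
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)),
            class = "ModuleScoreConfig")
}

# Equal-frequency expression bins: gene with stable rank r of pooled mean
# (ties broken by column order) goes to bin ceiling(r * n_bins / n_genes).
# Rank-based, hence invariant under adding a constant to all values.
expression_bins <- function(gene_means, n_bins) {
  n_genes <- length(gene_means)
  r <- rank(gene_means, ties.method = "first")
  as.integer(ceiling(r * n_bins / n_genes))
}

# Control-gene candidates for one target gene: its bin minus all target
# genes; if that is empty, the bin minus the gene itself; if the gene is
# alone in its bin, the gene itself (score contribution then cancels).
control_candidates <- function(gene_idx, bin_members, target_idx) {
  cand <- setdiff(bin_members, target_idx)
  if (length(cand) == 0) cand <- setdiff(bin_members, gene_idx)
  if (length(cand) == 0) cand <- gene_idx
  cand
}

#' Per-cell module score for a marker gene set
#'
#' For each cell, the score is the mean (normalized) expression of the
#' matched marker genes minus the mean expression of a control pool: for
#' every marker gene, `n_ctrl` genes are sampled from the marker's
#' expression bin (excluding marker genes; without replacement when the
#' bin is large enough, with replacement otherwise) and pooled with
#' multiplicity. Positive scores indicate enrichment of the programme in
#' that cell relative to expression-matched background.
#'
#' @param matrix an `ExpressionMatrix` with a normalized layer.
#' @param geneset a [marker_gene_set()]; genes absent from the matrix are
#'   dropped with a warning, and at least one must match.
#' @param config a [module_score_config()].
#' @return named numeric vector of per-cell scores (names = cell ids).
#' @export
module_score <- function(matrix, geneset, config = module_score_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(geneset, "MarkerGeneSet"),
            inherits(config, "ModuleScoreConfig"))
  if (matrix$layer == "raw_counts") {
    stop("module_score expects a normalized layer; run normalize_rc() first")
  }
  n_genes <- length(matrix$gene_ids)
  if (config$n_bins > n_genes) {
    stop("n_bins = ", config$n_bins, " exceeds the ", n_genes,
         " genes in the matrix")
  }
  target_idx <- match(geneset$genes, matrix$gene_ids)
  missing <- geneset$genes[is.na(target_idx)]
  if (length(missing) == length(geneset$genes)) {
    stop("no genes of set '", geneset$name, "' found in the matrix")
  }
  if (length(missing)) {
    warning("dropping ", length(missing), " gene(s) of set '", geneset$name,
            "' absent from the matrix: ",
            paste(head(missing, 10), collapse = ", "))
  }
  target_idx <- target_idx[!is.na(target_idx)]

  v <- matrix$values
  gene_means <- Matrix::colMeans(v)
  bins <- expression_bins(gene_means, config$n_bins)
  bin_members <- split(seq_len(n_genes), bins)

  ctrl_pool <- with_rng_seed(config$seed, {
    pool <- vector("list", length(target_idx))
    for (i in seq_along(target_idx)) {
      g <- target_idx[i]
      cand <- control_candidates(g, bin_members[[as.character(bins[g])]],
                                 target_idx)
      pool[[i]] <- if (length(cand) >= config$n_ctrl) {
        sample(cand, config$n_ctrl, replace = FALSE)
      } else {
        sample(cand, config$n_ctrl, replace = TRUE)
      }
    }
    unlist(pool)
  })

  target_mean <- Matrix::rowMeans(v[, target_idx, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(v[, ctrl_pool, drop = FALSE])
  scores <- as.numeric(target_mean - ctrl_mean)
  names(scores) <- matrix$cell_ids
  scores
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' PCA of cells on marker genes
#'
#' Restricts the matrix to the union of the supplied marker sets, scales
#' each matched gene to zero mean and unit variance (zero-variance genes
#' dropped), and computes an exact PCA of the cells. Used to verify
#' visually that marker expression separates the phases. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param matrix an `ExpressionMatrix` (any normalized layer).
#' @param genesets list of [marker_gene_set()] objects.
#' @param n_components number of components to return; the number of
#'   matched, variable genes must be at least this.
#' @return a cells x `n_components` matrix of scores (rownames = cell ids).
#' @export
pca_on_markers <- function(matrix, genesets, n_components = 2) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), n_components >= 1)
  if (inherits(genesets, "MarkerGeneSet")) genesets <- list(genesets)
  genes <- unique(toupper(unlist(lapply(genesets, `[[`, "genes"))))
  idx <- match(genes, matrix$gene_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) < n_components) {
    stop("only ", length(idx), " marker genes matched in the matrix; ",
         n_components, " components requested")
  }
  x <- as.matrix(matrix$values[, idx, drop = FALSE])
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("all matched marker genes have zero variance; ",
            "returning an all-zero embedding")
    emb <- matrix(0, nrow = nrow(x), ncol = n_components,
                  dimnames = list(matrix$cell_ids,
                                  paste0("PC", seq_len(n_components))))
    return(emb)
  }
  if (sum(keep) < n_components) {
    stop("only ", sum(keep), " matched marker genes have non-zero variance; ",
         n_components, " components requested")
  }
  x <- scale(x[, keep, drop = FALSE])
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  emb <- p$x[, seq_len(k), drop = FALSE]
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- matrix$cell_ids
  colnames(emb) <- paste0("PC", seq_len(k))
  emb
}
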