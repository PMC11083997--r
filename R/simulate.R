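#' Configuration for the phase-labelled count simulator
#'
#' The simulator emulates the structure the two-pass assignment relies
#' on: a shared G2/M transcriptional programme expressed by both G2 and M
#' cells (so the first pass pools them), plus phase-specific programmes —
#' an S programme in S cells, a mitotic programme in M cells only and an
#' interphase programme in G2 cells only — that the second pass can
#' separate. Counts are negative binomial with a log-normal spread of
#' per-gene base means and log-normal cell library-size factors.
#'
#' @param n_cells_per_phase named vector over G1/S/G2/M (default 100
#'   cells each).
#' @param n_background_genes unregulated genes added to the marker blocks
#'   (default 2000).
#' @param marker_fold fold upregulation of a phase's own markers
#'   (default 6; 1 means no phase signal at all).
#' @param g2m_bleed fraction of `marker_fold` at which G2 cells express
#'   the shared G2/M programme (default 0.5; the effective fold is
#'   `max(1, g2m_bleed * marker_fold)`, so `marker_fold = 1` stays null).
#' @param base_mean median per-gene NB mean count (default 2).
#' @param gene_mean_sdlog log-normal sd of per-gene base means around
#'   `base_mean` (default 1), mimicking the orders-of-magnitude spread of
#'   real mean expression; required for expression-binned control genes
#'   to be informative.
#' @param dispersion NB dispersion `a` in `var = m + a * m^2` (default
#'   0.4); 0 gives Poisson counts.
#' @param library_size_cv coefficient of variation of cell library-size
#'   factors (default 0.3).
#' @param seed RNG seed; the same config yields an identical dataset.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_cells_per_phase = c(G1 = 100, S = 100,
                                                    G2 = 100, M = 100),
                              n_background_genes = 2000,
                              marker_fold = 6,
                              g2m_bleed = 0.5,
                              base_mean = 2,
                              gene_mean_sdlog = 1,
                              dispersion = 0.4,
                              library_size_cv = 0.3,
                              seed = 0) {
  phases <- c("G1", "S", "G2", "M")
  if (is.null(names(n_cells_per_phase)) ||
      !all(names(n_cells_per_phase) %in% phases)) {
    stop("n_cells_per_phase must be named over G1/S/G2/M")
  }
  n <- setNames(rep(0L, 4), phases)
  n[names(n_cells_per_phase)] <- as.integer(n_cells_per_phase)
  if (any(is.na(n)) || any(n < 0)) stop("invalid n_cells_per_phase")
  if (sum(n) == 0) stop("at least one phase must have cells")
  stopifnot(n_background_genes >= 1, marker_fold >= 1, g2m_bleed >= 0,
            base_mean > 0, gene_mean_sdlog >= 0, dispersion >= 0,
            library_size_cv >= 0)
  structure(list(n_cells_per_phase = n,
                 n_background_genes = as.integer(n_background_genes),
                 marker_fold = as.numeric(marker_fold),
                 g2m_bleed = as.numeric(g2m_bleed),
                 base_mean = as.numeric(base_mean),
                 gene_mean_sdlog = as.numeric(gene_mean_sdlog),
                 dispersion = as.numeric(dispersion),
                 library_size_cv = as.numeric(library_size_cv),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a phase-labelled single-cell count matrix
#'
#' Gene universe: the packaged S list (S programme), the packaged G2/M
#' list (shared programme, expressed by M cells at `marker_fold` and by
#' G2 cells at the bleed-through fold), the packaged mitotic list (M
#' cells only) and interphase list (G2 cells only), plus
#' `n_background_genes` unregulated genes named `BG00001`, ... A gene in
#' several lists takes the largest applicable fold for the cell's phase.
#' Counts are NB with mean `base_mean_g * fold * library_factor`.
#'
#' @param config a [simulation_config()].
#' @return a `LabeledDataset`: list with `matrix` (raw-count
#'   `ExpressionMatrix`), `truth` (per-cell phase, named by cell id) and
#'   `marker_map` (phase/programme -> gene vector).
#' @examples
#' sim <- simulate_phased_counts(simulation_config(
#'   n_cells_per_phase = c(G1 = 5, S = 5, G2 = 5, M = 5),
#'   n_background_genes = 100, seed = 42))
#' table(sim$truth)
#' @export
simulate_phased_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  s_genes <- load_builtin_geneset("seurat_s")$genes
  g2m_genes <- load_builtin_geneset("seurat_g2m")$genes
  m_genes <- load_builtin_geneset("mitotic_table1")$genes
  g2_genes <- load_builtin_geneset("interphase_table2")$genes
  bg_genes <- sprintf("BG%05d", seq_len(config$n_background_genes))
  genes <- unique(c(s_genes, g2m_genes, m_genes, g2_genes, bg_genes))
  n_genes <- length(genes)

  f <- config$marker_fold
  bleed <- max(1, config$g2m_bleed * f)
  fold_for_phase <- function(phase) {
    fold <- rep(1, n_genes)
    up <- function(set, value) pmax(fold[match(set, genes)], value)
    switch(phase,
      G1 = fold,
      S = { fold[match(s_genes, genes)] <- up(s_genes, f); fold },
      G2 = {
        fold[match(g2m_genes, genes)] <- up(g2m_genes, bleed)
        fold[match(g2_genes, genes)] <- up(g2_genes, f)
        fold
      },
      M = {
        fold[match(g2m_genes, genes)] <- up(g2m_genes, f)
        fold[match(m_genes, genes)] <- up(m_genes, f)
        fold
      })
  }
  fold_by_phase <- lapply(setNames(nm = c("G1", "S", "G2", "M")),
                          fold_for_phase)

  n_per <- config$n_cells_per_phase
  truth <- rep(names(n_per), times = n_per)
  n_cells <- length(truth)
  cell_ids <- sprintf("cell_%04d_%s", seq_len(n_cells), truth)

  counts <- with_rng_seed(config$seed, {
    gene_base <- if (config$gene_mean_sdlog > 0) {
      rlnorm(n_genes, meanlog = log(config$base_mean),
             sdlog = config$gene_mean_sdlog)
    } else rep(config$base_mean, n_genes)
    lib <- if (config$library_size_cv > 0) {
      sdl <- sqrt(log(1 + config$library_size_cv^2))
      rlnorm(n_cells, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else rep(1, n_cells)
    m <- matrix(0L, nrow = n_cells, ncol = n_genes)
    for (i in seq_len(n_cells)) {
      mu <- gene_base * fold_by_phase[[truth[i]]] * lib[i]
      m[i, ] <- if (config$dispersion > 0) {
        rnbinom(n_genes, mu = mu, size = 1 / config$dispersion)
      } else {
        rpois(n_genes, lambda = mu)
      }
    }
    m
  })

  mat <- expression_matrix(counts, cell_ids, genes, layer = "raw_counts")
  structure(list(matrix = mat,
                 truth = setNames(truth, cell_ids),
                 marker_map = list(S = s_genes, G2M_shared = g2m_genes,
                                   M = m_genes, G2 = g2_genes,
                                   background = bg_genes)),
            class = "LabeledDataset")
}

#' Balanced accuracy of an assignment against ground truth
#'
#' Mean of the per-phase recalls over the phases present in the truth.
#'
#' @param predicted character vector of assigned phases.
#' @param truth character vector of true phases (same order/length).
#' @return a single number in \[0, 1\].
#' @export
balanced_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  phases <- unique(truth)
  recalls <- vapply(phases, function(p) {
    mean(predicted[truth == p] == p)
  }, numeric(1))
  mean(recalls)
}
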