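#' Configuration for the two-pass phase assignment
#'
#' Bundles normalization and scoring settings with the four marker sets:
#' the first pass scores every cell against `s_set` and `g2m_set`
#' (defaults: the Seurat/Tirosh lists) and assigns G1/S/G2M; the second
#' pass re-scores the pooled G2/M cells against `m_set` (mitotic markers)
#' and `g2_set` (interphase markers) and resolves each to G2 or M.
#'
#' @param normalization a [normalization_config()].
#' @param scoring a [module_score_config()].
#' @param s_set,g2m_set first-pass marker sets.
#' @param m_set,g2_set second-pass marker sets; must be disjoint.
#' @return a `MosmisConfig` list.
#' @export
mosmis_config <- function(normalization = normalization_config(),
                          scoring = module_score_config(),
                          s_set = load_builtin_geneset("seurat_s"),
                          g2m_set = load_builtin_geneset("seurat_g2m"),
                          m_set = load_builtin_geneset("mitotic_table1"),
                          g2_set = load_builtin_geneset("interphase_table2")) {
  for (s in list(s_set, g2m_set, m_set, g2_set)) {
    stopifnot(inherits(s, "MarkerGeneSet"), length(s$genes) >= 1)
  }
  overlap <- intersect(m_set$genes, g2_set$genes)
  if (length(overlap)) {
    stop("m_set and g2_set must be disjoint; shared genes: ",
         paste(head(overlap, 5), collapse = ", "))
  }
  structure(list(normalization = normalization, scoring = scoring,
                 s_set = s_set, g2m_set = g2m_set,
                 m_set = m_set, g2_set = g2_set),
            class = "MosmisConfig")
}

#' First-pass G1/S/G2M assignment from module scores
#'
#' A cell is called S if its S score exceeds both its G2/M score and zero;
#' G2M if the G2/M score is at least the S score and positive (an exact
#' positive tie therefore goes to G2M); G1 when neither score is positive.
#'
#' @param s_scores,g2m_scores equal-length numeric vectors of per-cell
#'   module scores; must be finite.
#' @return character vector of `"G1"`, `"S"`, `"G2M"` per cell.
#' @export
assign_first_pass <- function(s_scores, g2m_scores) {
  stopifnot(length(s_scores) == length(g2m_scores))
  bad <- !is.finite(s_scores) | !is.finite(g2m_scores)
  if (any(bad)) {
    ids <- names(s_scores)[bad]
    if (is.null(ids)) ids <- which(bad)
    stop("non-finite phase score(s) for cell(s): ",
         paste(head(ids, 5), collapse = ", "))
  }
  out <- rep("G1", length(s_scores))
  out[g2m_scores >= s_scores & g2m_scores > 0] <- "G2M"
  out[s_scores > g2m_scores & s_scores > 0] <- "S"
  names(out) <- names(s_scores)
  out
}

#' Second-pass G2-vs-M assignment within the G2/M pool
#'
#' Re-scores the pooled cells against the mitotic and interphase marker
#' sets, with control bins rebuilt on the pool itself, and calls a cell M
#' when its mitotic score exceeds both the interphase score and zero;
#' otherwise G2 (ties and all-negative cases included — within a G2/M
#' pool, absence of mitotic signal is the interphase-like state).
#'
#' @param g2m_matrix normalized `ExpressionMatrix` restricted to the cells
#'   assigned G2M by the first pass; may have zero cells.
#' @param m_set mitotic marker set.
#' @param g2_set interphase (G2) marker set.
#' @param config a [module_score_config()].
#' @return data frame with `cell_id`, `phase` ("G2"/"M"), `m_score`,
#'   `g2_score`; zero rows if the pool is empty.
#' @export
assign_second_pass <- function(g2m_matrix, m_set, g2_set,
                               config = module_score_config()) {
  stopifnot(inherits(g2m_matrix, "ExpressionMatrix"))
  if (length(g2m_matrix$cell_ids) == 0) {
    return(data.frame(cell_id = character(), phase = character(),
                      m_score = numeric(), g2_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  m_score <- module_score(g2m_matrix, m_set, config)
  g2_score <- module_score(g2m_matrix, g2_set, config)
  phase <- ifelse(m_score > g2_score & m_score > 0, "M", "G2")
  data.frame(cell_id = g2m_matrix$cell_ids, phase = phase,
             m_score = as.numeric(m_score), g2_score = as.numeric(g2_score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full two-pass mitotic-sort phase assignment
#'
#' Normalizes the raw counts, computes S and G2/M module scores, assigns
#' G1/S/G2M, then re-scores the G2/M pool with the mitotic and interphase
#' marker lists to split it into G2 and M. Every cell receives exactly one
#' of G1/S/G2/M, and the union of the final G2 and M cells equals the
#' first-pass G2M pool. Output is deterministic for a fixed scoring seed.
#'
#' @param matrix an `ExpressionMatrix` with layer `raw_counts`.
#' @param config a [mosmis_config()].
#' @return a `mosmis_assignment` data frame with columns `cell_id`,
#'   `first_pass` (G1/S/G2M), `final` (G1/S/G2/M), `s_score`, `g2m_score`,
#'   and `g2_score`/`m_score` (NA outside the G2/M pool).
#' @examples
#' sim <- simulate_phased_counts(simulation_config(
#'   n_cells_per_phase = c(G1 = 20, S = 20, G2 = 20, M = 20),
#'   n_background_genes = 300, seed = 1))
#' res <- run_mosmis(sim$matrix)
#' table(res$final)
#' @export
run_mosmis <- function(matrix, config = mosmis_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(config, "MosmisConfig"))
  if (length(matrix$cell_ids) == 0) stop("matrix has no cells")
  if (matrix$layer != "raw_counts") {
    stop("run_mosmis expects raw counts, got layer ", matrix$layer)
  }
  norm <- normalize_rc(matrix, config$normalization)
  s_scores <- score_pass(norm, config$s_set, config$scoring, "first pass (S)")
  g2m_scores <- score_pass(norm, config$g2m_set, config$scoring,
                           "first pass (G2M)")
  first <- assign_first_pass(s_scores, g2m_scores)

  res <- data.frame(cell_id = norm$cell_ids, first_pass = first,
                    final = first, s_score = as.numeric(s_scores),
                    g2m_score = as.numeric(g2m_scores),
                    g2_score = NA_real_, m_score = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)

  pool <- which(first == "G2M")
  if (length(pool)) {
    sub <- subset_matrix(norm, cells = pool)
    second <- tryCatch(
      assign_second_pass(sub, config$m_set, config$g2_set, config$scoring),
      error = function(e) stop("second pass (G2 vs M): ",
                               conditionMessage(e), call. = FALSE))
    stopifnot(identical(second$cell_id, res$cell_id[pool]))
    res$final[pool] <- second$phase
    res$g2_score[pool] <- second$g2_score
    res$m_score[pool] <- second$m_score
  }
  class(res) <- c("mosmis_assignment", "data.frame")
  res
}

score_pass <- function(norm, geneset, scoring, label) {
  tryCatch(module_score(norm, geneset, scoring),
           error = function(e) stop(label, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Per-phase counts and percentages of an assignment
#'
#' @param assignments a `mosmis_assignment` data frame.
#' @return data frame with `phase`, `n`, `percent` over G1/S/G2/M.
#' @export
phase_composition <- function(assignments) {
  stopifnot(is.data.frame(assignments), "final" %in% names(assignments))
  phases <- c("G1", "S", "G2", "M")
  n <- vapply(phases, function(p) sum(assignments$final == p), integer(1))
  data.frame(phase = phases, n = as.integer(n),
             percent = round(100 * n / nrow(assignments), 2),
             stringsAsFactors = FALSE)
}
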