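#' Derive mitotic and interphase marker lists from a bulk DE table
#'
#' Applies the threshold filter used to build the packaged lists: rows
#' with an adjusted p-value strictly below `padj_max` and an absolute
#' log2 fold change of at least `lfc_min` survive; positive fold changes
#' (up in the mitotic fraction) go to the mitotic list, negative ones to
#' the interphase list. Each list is ordered by ascending adjusted
#' p-value. The defaults reproduce the published cut-offs: padj < 0.001
#' and |log2FC| >= 0.58, i.e. at least a 1.5-fold expression change
#' (2^0.58 ~ 1.5).
#'
#' @param de data frame with columns `gene`, `log2FoldChange` (or
#'   `log2fc`) and `padj`; genes must be unique, `padj` in \[0, 1\] where
#'   present. Rows with missing `padj` never survive.
#' @param padj_max adjusted p-value cut-off (strict), in (0, 1].
#' @param lfc_min minimum absolute log2 fold change (inclusive), > 0.
#' @return list with elements `mitotic` and `interphase`, each a
#'   [marker_gene_set()] carrying the surviving rows' statistics. If no
#'   row survives, both sets are empty and a warning is raised.
#' @examples
#' de <- data.frame(gene = c("A", "B"), log2FoldChange = c(1.2, -0.9),
#'                  padj = c(1e-4, 1e-5))
#' derive_phase_genesets(de)$mitotic$genes
#' @export
derive_phase_genesets <- function(de, padj_max = 0.001, lfc_min = 0.58) {
  stopifnot(is.data.frame(de), nrow(de) > 0,
            padj_max > 0, padj_max <= 1, lfc_min > 0)
  if (!"log2fc" %in% names(de) && "log2FoldChange" %in% names(de)) {
    de$log2fc <- de$log2FoldChange
  }
  if (!all(c("gene", "log2fc", "padj") %in% names(de))) {
    stop("DE table needs columns gene, log2FoldChange (or log2fc), padj")
  }
  if (anyDuplicated(de$gene)) {
    stop("DE table has duplicated genes: ",
         paste(head(unique(de$gene[duplicated(de$gene)]), 5), collapse = ", "))
  }
  ok_p <- !is.na(de$padj)
  if (any(de$padj[ok_p] < 0 | de$padj[ok_p] > 1)) {
    stop("padj values must lie in [0, 1]")
  }
  keep <- ok_p & de$padj < padj_max & abs(de$log2fc) >= lfc_min
  surv <- de[keep, , drop = FALSE]
  surv <- surv[order(surv$padj), , drop = FALSE]

  build <- function(rows, name) {
    stats <- data.frame(gene = rows$gene, log2fc = rows$log2fc,
                        padj = rows$padj, stringsAsFactors = FALSE)
    marker_gene_set(name, rows$gene, provenance = "derived from DE table",
                    stats = if (nrow(rows)) stats else NULL,
                    allow_empty = TRUE)
  }
  up <- surv[surv$log2fc > 0, , drop = FALSE]
  down <- surv[surv$log2fc < 0, , drop = FALSE]
  if (nrow(surv) == 0) {
    warning("no DE rows survive padj < ", padj_max, " and |log2fc| >= ",
            lfc_min, "; returning empty gene sets")
  }
  list(mitotic = build(up, "M"), interphase = build(down, "G2_interphase"))
}

#' Read a DESeq2-style results CSV
#'
#' @param path CSV with header `gene,log2FoldChange,padj` (extra columns
#'   are kept).
#' @return a data frame usable by [derive_phase_genesets()].
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2FoldChange", "padj")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  df
}
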