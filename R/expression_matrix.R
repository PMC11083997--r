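#' Construct an expression matrix
#'
#' The package's container for a cells-by-genes expression matrix. Rows are
#' cells, columns are genes; values may be a base matrix or any
#' \pkg{Matrix} sparse matrix. Gene symbols are upper-cased for matching
#' against marker lists (symbol matching is exact after upper-casing; no
#' alias or Ensembl resolution is attempted, so e.g. murine data must be
#' case-mapped by the caller). Duplicate gene symbols are made unique by
#' suffixing `.1`, `.2`, ... as common single-cell loaders do; only the
#' first occurrence of a duplicated symbol can match a marker list.
#'
#' @param values numeric matrix (cells x genes), dense or sparse.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of gene symbols, one per column
#'   (upper-cased and de-duplicated internally).
#' @param layer one of `"raw_counts"`, `"rc_normalized"`, `"log_normalized"`.
#'   The `raw_counts` layer must contain non-negative integers.
#' @return an `ExpressionMatrix` object (list with `values`, `cell_ids`,
#'   `gene_ids`, `layer`).
#' @examples
#' m <- expression_matrix(matrix(0:5, nrow = 2), c("c1", "c2"),
#'                        c("PLK1", "CDC20", "ACTB"))
#' dim(m$values)
#' @export
expression_matrix <- function(values, cell_ids, gene_ids,
                              layer = c("raw_counts", "rc_normalized",
                                        "log_normalized")) {
  layer <- match.arg(layer)
  if (!is(values, "Matrix") && !is.matrix(values)) {
    values <- as.matrix(values)
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- toupper(as.character(gene_ids))
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) [", length(cell_ids),
         "] does not match number of matrix rows [", nrow(values), "]")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) [", length(gene_ids),
         "] does not match number of matrix columns [", ncol(values), "]")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(head(unique(cell_ids[duplicated(cell_ids)]), 5), collapse = ", "))
  }
  gene_ids <- make.unique(gene_ids, sep = ".")
  obj <- structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         layer = layer),
    class = "ExpressionMatrix")
  validate_expression_matrix(obj)
  obj
}

validate_expression_matrix <- function(x) {
  v <- x$values
  mn <- if (is(v, "sparseMatrix")) min(v@x, 0) else suppressWarnings(min(v))
  if (length(v) && is.finite(mn) && mn < 0) {
    stop("expression values must be non-negative (min = ", mn, ")")
  }
  if (x$layer == "raw_counts") {
    vx <- if (is(v, "sparseMatrix")) v@x else as.vector(v)
    if (length(vx) && any(vx != floor(vx))) {
      stop("raw_counts layer contains non-integer entries")
    }
  }
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes; layer =", x$layer, "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an `ExpressionMatrix`.
#' @param cells,genes index vectors (logical, integer or character ids);
#'   `NULL` keeps everything.
#' @return an `ExpressionMatrix` on the selected cells and genes.
#' @export
subset_matrix <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ci <- resolve_index(cells, x$cell_ids, "cell")
  gi <- resolve_index(genes, x$gene_ids, "gene")
  structure(
    list(values = x$values[ci, gi, drop = FALSE],
         cell_ids = x$cell_ids[ci], gene_ids = x$gene_ids[gi],
         layer = x$layer),
    class = "ExpressionMatrix")
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      stop("unknown ", what, " ids: ",
           paste(head(idx[is.na(pos)], 5), collapse = ", "))
    }
    return(pos)
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  as.integer(idx)
}

#' Read a count matrix from disk
#'
#' Reads either a 10x-style MatrixMarket directory (`matrix.mtx` plus
#' one-column `barcodes.tsv` and a `features.tsv`/`genes.tsv` whose symbol
#' column is selectable) or a dense CSV/TSV with id header row and id first
#' column. The result always has cells as rows; use `orientation` to state
#' how the file on disk is laid out.
#'
#' @param path directory (for `mtx_dir`) or file (for `csv_dense`).
#' @param format `"mtx_dir"` or `"csv_dense"`.
#' @param orientation `"cells_by_genes"` (rows of the stored matrix are
#'   cells) or `"genes_by_cells"` (stored transposed, as 10x CellRanger
#'   writes it; the default for `mtx_dir` in practice).
#' @param feature_column which column of the features file holds the gene
#'   symbol (10x files carry Ensembl id in column 1, symbol in column 2).
#' @param sep field separator for `csv_dense` (`","` or `"\t"`).
#' @return an `ExpressionMatrix` with layer `raw_counts`.
#' @export
read_counts <- function(path,
                        format = c("mtx_dir", "csv_dense"),
                        orientation = c("cells_by_genes", "genes_by_cells"),
                        feature_column = 1L,
                        sep = ",") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx_dir") {
    read_counts_mtx(path, orientation, feature_column)
  } else {
    read_counts_dense(path, orientation, sep)
  }
}

read_counts_mtx <- function(path, orientation, feature_column) {
  if (!dir.exists(path)) stop("MTX directory not found: ", path)
  find1 <- function(patterns, what) {
    for (p in patterns) {
      hits <- list.files(path, pattern = p, full.names = TRUE)
      if (length(hits)) return(hits[[1]])
    }
    stop("no ", what, " file found in ", path,
         " (looked for ", paste(patterns, collapse = ", "), ")")
  }
  mtx_file <- find1(c("^matrix\\.mtx$", "\\.mtx$"), "matrix (.mtx)")
  bc_file  <- find1(c("^barcodes\\.tsv$", "barcodes"), "barcodes")
  ft_file  <- find1(c("^features\\.tsv$", "^genes\\.tsv$", "features", "genes"),
                    "features/genes")
  m <- as(Matrix::readMM(mtx_file), "CsparseMatrix")
  barcodes <- readLines(bc_file)
  barcodes <- barcodes[nzchar(barcodes)]
  ft <- read.delim(ft_file, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (feature_column > ncol(ft)) {
    stop("feature_column = ", feature_column, " but features file has only ",
         ncol(ft), " column(s)")
  }
  genes <- as.character(ft[[feature_column]])
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  if (nrow(m) != length(barcodes)) {
    stop("matrix has ", nrow(m), " cell rows but barcodes file lists ",
         length(barcodes), " barcodes")
  }
  if (ncol(m) != length(genes)) {
    stop("matrix has ", ncol(m), " gene columns but features file lists ",
         length(genes), " genes")
  }
  expression_matrix(m, barcodes, genes, layer = "raw_counts")
}

read_counts_dense <- function(path, orientation, sep) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  row_ids <- as.character(df[[1]])          # id column; may repeat for genes
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("counts file contains non-numeric entries: ", path)
  rownames(m) <- row_ids
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m, rownames(m), colnames(m), layer = "raw_counts")
}

#' Write phase assignments to CSV
#'
#' Writes one row per cell with header
#' `cell_id,first_pass,final,s_score,g2m_score,g2_score,m_score`, in input
#' order. Second-pass scores are empty fields for cells that never entered
#' the G2/M pool. Output is byte-stable: re-running with the same
#' assignments reproduces the file exactly.
#'
#' @param assignments a `mosmis_assignment` data frame from [run_mosmis()].
#' @param path output file.
#' @export
write_assignments_csv <- function(assignments, path) {
  if (!is.data.frame(assignments) || nrow(assignments) == 0) {
    stop("assignments must be a non-empty data frame")
  }
  cols <- c("cell_id", "first_pass", "final",
            "s_score", "g2m_score", "g2_score", "m_score")
  missing <- setdiff(cols, names(assignments))
  if (length(missing)) {
    stop("assignments is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- assignments[, cols]
  for (sc in c("s_score", "g2m_score", "g2_score", "m_score")) {
    out[[sc]] <- ifelse(is.na(out[[sc]]), "",
                        formatC(out[[sc]], digits = 10, format = "g"))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a phase-assignment CSV written by [write_assignments_csv()]
#'
#' @param path CSV file.
#' @return a data frame with the same columns as [run_mosmis()] output.
#' @export
read_assignments_csv <- function(path) {
  if (!file.exists(path)) stop("assignment file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(cell_id = "character"))
  for (sc in c("s_score", "g2m_score", "g2_score", "m_score")) {
    df[[sc]] <- suppressWarnings(as.numeric(df[[sc]]))
  }
  df
}
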