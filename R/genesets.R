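#' Construct a marker gene set
#'
#' A named, ordered list of unique gene symbols marking a cell-cycle phase,
#' optionally carrying the differential-expression statistics (log2 fold
#' change and adjusted p-value) the list was derived from.
#'
#' @param name phase label, e.g. `"M"`, `"G2_interphase"`, `"S"`, `"G2M"`.
#' @param genes character vector of gene symbols (upper-cased, must be
#'   unique and non-empty).
#' @param provenance free-text origin of the list.
#' @param stats optional data frame with columns `gene`, `log2fc`, `padj`
#'   covering every gene in `genes`.
#' @param allow_empty permit a zero-gene set (used only by
#'   [derive_phase_genesets()] when no DE rows survive the filter).
#' @return a `MarkerGeneSet` object.
#' @export
marker_gene_set <- function(name, genes, provenance = "user", stats = NULL,
                            allow_empty = FALSE) {
  genes <- toupper(as.character(genes))
  if (length(genes) == 0 && !allow_empty) {
    stop("marker gene set '", name, "' is empty")
  }
  if (anyDuplicated(genes)) {
    stop("marker gene set '", name, "' has duplicate genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (!is.null(stats)) {
    stopifnot(is.data.frame(stats),
              all(c("gene", "log2fc", "padj") %in% names(stats)))
    stats$gene <- toupper(stats$gene)
    if (!all(genes %in% stats$gene) ||
        anyNA(stats$log2fc) || anyNA(stats$padj)) {
      stop("stats must provide log2fc and padj for every gene in the set")
    }
    if (any(stats$padj < 0 | stats$padj > 1)) {
      stop("padj values must lie in [0, 1]")
    }
    stats <- stats[match(genes, stats$gene), , drop = FALSE]
    rownames(stats) <- NULL
  }
  structure(list(name = name, genes = genes, provenance = provenance,
                 stats = stats),
            class = "MarkerGeneSet")
}

#' @export
print.MarkerGeneSet <- function(x, ...) {
  cat("MarkerGeneSet '", x$name, "' (", length(x$genes), " genes; ",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

# Mitotic marker list: genes upregulated in pH3+ (mitotic) vs interphase
# HeLa fractions, padj < 0.001 pre-adjustment filter and |log2FC| >= 0.58.
.mitotic_markers <- data.frame(
  gene = c("CENPE", "KNL1", "PIMREG", "PLK1", "KIF14", "TPX2", "KIF20A",
           "SAPCD2", "KNSTRN", "PRR11", "NUF2", "ASPM", "CEP55", "BUB1",
           "SGO2", "GAS2L3", "NEK2", "HMMR", "DEPDC1", "DLGAP5", "ARL6IP1",
           "NUSAP1", "CCNA2", "VANGL1", "CDC20", "KIF4A", "KIF20B"),
  padj = c(0.000664, 0.000959, 0.000959, 0.000966, 0.000966, 0.001844,
           0.002307, 0.003489, 0.003702, 0.003702, 0.003702, 0.004089,
           0.004128, 0.004764, 0.005583, 0.005583, 0.005939, 0.005939,
           0.006015, 0.007283, 0.007283, 0.007283, 0.007506, 0.008325,
           0.008993, 0.009799, 0.01),
  log2fc = c(1.125147, 1.038927, 0.999074, 1.403274, 0.95761, 1.33757,
             1.579072, 1.203906, 1.225519, 1.214335, 0.79701, 1.173306,
             1.546348, 1.183972, 1.367488, 0.932372, 1.737096, 1.470353,
             1.184454, 1.286611, 1.211374, 0.770366, 1.448108, 0.875813,
             1.462092, 1.454416, 1.224597),
  stringsAsFactors = FALSE)

# Interphase marker list: genes downregulated in the same comparison.
# Three unnamed transcripts are kept under their Ensembl identifiers.
# The printed table has 17 rows (the accompanying text mentions 18; the
# published table is taken as authoritative and packaged verbatim).
.interphase_markers <- data.frame(
  gene = c("E2F1", "CCNE1", "FBXL20", "DTL", "ENSG00000273759", "RMI2",
           "ZMYND19", "MCM5", "ZNF367", "FRAT1", "BRD2", "ENSG00000272106",
           "PPP1R3C", "ENSG00000275484", "UNG", "IFI27L1", "CDC6"),
  padj = c(2.84e-07, 2.97e-05, 0.000966, 0.000966, 0.001844, 0.001844,
           0.003489, 0.003702, 0.003809, 0.004089, 0.005583, 0.007283,
           0.007283, 0.008993, 0.009006, 0.009278, 0.009799),
  log2fc = c(-2.17369, -2.2646, -1.54022, -1.53821, -2.59207, -1.63698,
             -0.79722, -1.53998, -1.44647, -1.81741, -1.7275, -2.14137,
             -1.51771, -2.31626, -1.44849, -2.29293, -0.95402),
  stringsAsFactors = FALSE)

# Standard Tirosh-derived S-phase list shipped with Seurat (43 genes).
.seurat_s_genes <- c(
  "MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG", "GINS2",
  "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1", "MLF1IP", "HELLS", "RFC2",
  "RPA2", "NASP", "RAD51AP1", "GMNN", "WDR76", "SLBP", "CCNE2", "UBR7",
  "POLD3", "MSH2", "ATAD2", "RAD51", "RRM2", "CDC45", "CDC6", "EXO1",
  "TIPIN", "DSCC1", "BLM", "CASP8AP2", "USP1", "CLSPN", "POLA1", "CHAF1B",
  "BRIP1", "E2F8")

# Standard Tirosh-derived G2/M list shipped with Seurat (54 genes).
.seurat_g2m_genes <- c(
  "HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2", "TOP2A", "NDC80",
  "CKS2", "NUF2", "CKS1B", "MKI67", "TMPO", "CENPF", "TACC3", "FAM64A",
  "SMC4", "CCNB2", "CKAP2L", "CKAP2", "AURKB", "BUB1", "KIF11", "ANP32E",
  "TUBB4B", "GTSE1", "KIF20B", "HJURP", "CDCA3", "HN1", "CDC20", "TTK",
  "CDC25C", "KIF2C", "RANGAP1", "NCAPD2", "DLGAP5", "CDCA2", "CDCA8",
  "ECT2", "KIF23", "HMMR", "AURKA", "PSRC1", "ANLN", "LBR", "CKAP5",
  "CENPE", "CTCF", "NEK2", "G2E3", "GAS2L3", "CBX5", "CENPA")

#' Load a packaged marker gene set
#'
#' Four lists ship with the package:
#' \describe{
#'   \item{`mitotic_table1`}{27 genes upregulated in pH3-sorted mitotic
#'     HeLa cells (with per-gene log2 fold change and adjusted p-value);
#'     the M-phase marker list for the second assignment pass.}
#'   \item{`interphase_table2`}{17 genes downregulated in the same
#'     comparison (three kept under Ensembl ids); the G2/interphase marker
#'     list for the second pass.}
#'   \item{`seurat_s`}{the standard 43-gene Tirosh-derived S-phase list
#'     Seurat ships, used for the first pass.}
#'   \item{`seurat_g2m`}{the standard 54-gene Tirosh-derived G2/M list,
#'     used for the first pass.}
#' }
#'
#' @param name one of `"mitotic_table1"`, `"interphase_table2"`,
#'   `"seurat_s"`, `"seurat_g2m"`.
#' @return a [marker_gene_set()] object.
#' @examples
#' length(load_builtin_geneset("mitotic_table1")$genes)  # 27
#' @export
load_builtin_geneset <- function(name) {
  valid <- c("mitotic_table1", "interphase_table2", "seurat_s", "seurat_g2m")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown gene set '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  switch(name,
    mitotic_table1 = marker_gene_set(
      "M", .mitotic_markers$gene, provenance = "builtin mitotic (pH3+) list",
      stats = .mitotic_markers),
    interphase_table2 = marker_gene_set(
      "G2_interphase", .interphase_markers$gene,
      provenance = "builtin interphase list",
      stats = .interphase_markers),
    seurat_s = marker_gene_set(
      "S", .seurat_s_genes, provenance = "Seurat/Tirosh S-phase list"),
    seurat_g2m = marker_gene_set(
      "G2M", .seurat_g2m_genes, provenance = "Seurat/Tirosh G2/M list"))
}

#' Read a marker gene list from a CSV file
#'
#' Accepts either a one-column file of symbols (header `gene`) or a
#' derivation output with `gene,log2FoldChange,padj` columns.
#'
#' @param path CSV file.
#' @param name phase label for the resulting set.
#' @return a [marker_gene_set()].
#' @export
read_geneset_csv <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) {
    stop("gene list CSV must have a 'gene' column: ", path)
  }
  stats <- NULL
  if (all(c("log2FoldChange", "padj") %in% names(df))) {
    stats <- data.frame(gene = df$gene, log2fc = df$log2FoldChange,
                        padj = df$padj, stringsAsFactors = FALSE)
  }
  marker_gene_set(name, df$gene, provenance = path, stats = stats)
}

#' Write a marker gene set to CSV
#'
#' @param geneset a [marker_gene_set()].
#' @param path output file; columns `gene[,log2FoldChange,padj]`.
#' @export
write_geneset_csv <- function(geneset, path) {
  stopifnot(inherits(geneset, "MarkerGeneSet"))
  if (is.null(geneset$stats)) {
    df <- data.frame(gene = geneset$genes, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = geneset$genes,
                     log2FoldChange = geneset$stats$log2fc,
                     padj = geneset$stats$padj, stringsAsFactors = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
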