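# In-code fixtures shared across test files.

# Random normalized-layer matrix with named genes, seeded.
random_norm_matrix <- function(n_cells, n_genes, seed,
                               gene_prefix = "G") {
  set.seed(seed)
  v <- matrix(round(rexp(n_cells * n_genes, rate = 0.5), 3),
              nrow = n_cells)
  expression_matrix(v,
                    cell_ids = sprintf("c%02d", seq_len(n_cells)),
                    gene_ids = sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                    layer = "log_normalized")
}

# Hand-written 10x-style MTX triple for a known 3-cell x 4-gene matrix
# (stored genes x cells, as CellRanger writes it). Returns the directory.
#   counts (cells x genes):
#     cellA: 1 0 2 0
#     cellB: 0 3 0 0
#     cellC: 4 0 0 5
write_tiny_mtx <- function(dir = tempfile("mtx")) {
  dir.create(dir)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 3 5",
               "1 1 1",
               "3 1 2",
               "2 2 3",
               "1 3 4",
               "4 3 5"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("cellA", "cellB", "cellC"), file.path(dir, "barcodes.tsv"))
  writeLines(c("PLK1", "CDC20", "ACTB", "GAPDH"),
             file.path(dir, "features.tsv"))
  dir
}

tiny_mtx_dense <- function() {
  matrix(c(1, 0, 2, 0,
           0, 3, 0, 0,
           4, 0, 0, 5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("cellA", "cellB", "cellC"),
                         c("PLK1", "CDC20", "ACTB", "GAPDH")))
}

# Small labelled simulation used by several suites (kept small for speed).
small_simulation <- function(seed, marker_fold = 6, cells = 40) {
  simulate_phased_counts(simulation_config(
    n_cells_per_phase = c(G1 = cells, S = cells, G2 = cells, M = cells),
    n_background_genes = 600, marker_fold = marker_fold, seed = seed))
}
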