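test_that("relative-counts normalization forces proportions and log1p", {
  m <- expression_matrix(matrix(c(2, 3, 5), nrow = 1), "c1",
                         c("A", "B", "C"))
  out <- normalize_rc(m, normalization_config(scale_factor = 100,
                                              log1p = FALSE))
  expect_equal(as.numeric(out$values), c(20, 30, 50))
  expect_identical(out$layer, "rc_normalized")

  m2 <- expression_matrix(matrix(c(1, 0, 0), nrow = 1), "c1",
                          c("A", "B", "C"))
  out2 <- normalize_rc(m2, normalization_config(scale_factor = 1e4,
                                                log1p = TRUE))
  expect_equal(as.numeric(out2$values), c(log(10001), 0, 0))
  expect_identical(out2$layer, "log_normalized")
})

test_that("all-zero cells survive normalization as zeros, with a warning", {
  m <- expression_matrix(matrix(c(1, 2, 0, 0), nrow = 2, byrow = TRUE),
                         c("ok", "empty"), c("A", "B"))
  expect_warning(out <- normalize_rc(m), "zero total")
  expect_equal(as.numeric(out$values[2, ]), c(0, 0))
})

test_that("normalization preserves the zero pattern (dense and sparse)", {
  set.seed(5)
  v <- matrix(rpois(600, 0.8), nrow = 20)
  dense <- expression_matrix(v, sprintf("c%d", 1:20), sprintf("g%d", 1:30))
  sp <- expression_matrix(as(Matrix::Matrix(v, sparse = TRUE),
                             "CsparseMatrix"),
                          sprintf("c%d", 1:20), sprintf("g%d", 1:30))
  for (m in list(dense, sp)) {
    out <- normalize_rc(m)
    expect_identical(as.matrix(out$values) == 0, unname(v == 0))
  }
  # dense and sparse paths agree numerically
  expect_equal(as.matrix(normalize_rc(dense)$values),
               as.matrix(normalize_rc(sp)$values), tolerance = 1e-12)
})

test_that("module_score matches the brute-force oracle across seeds", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    n_cells <- sample(5:20, 1)
    n_genes <- sample(25:50, 1)
    m <- random_norm_matrix(n_cells, n_genes, seed = seed)
    genes <- sample(m$gene_ids, 8)
    gs <- marker_gene_set("test", genes)
    cfg <- module_score_config(n_bins = 5, n_ctrl = 3, seed = seed)
    got <- module_score(m, gs, cfg)
    want <- oracle_module_score(m$values, m$gene_ids, genes,
                                n_bins = 5, n_ctrl = 3, seed = seed)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("module_score is zero when expression is flat, including for the
           whole gene universe", {
  m <- expression_matrix(matrix(2.5, nrow = 4, ncol = 30),
                         sprintf("c%d", 1:4), sprintf("g%d", 1:30),
                         layer = "log_normalized")
  gs <- marker_gene_set("some", m$gene_ids[1:6])
  expect_equal(unname(module_score(m, gs)), rep(0, 4))
  all_gs <- marker_gene_set("universe", m$gene_ids)
  expect_equal(unname(module_score(m, all_gs)), rep(0, 4))
  # all-zero matrix scores zero too
  z <- expression_matrix(matrix(0, nrow = 3, ncol = 30),
                         sprintf("c%d", 1:3), sprintf("g%d", 1:30),
                         layer = "log_normalized")
  expect_equal(unname(module_score(z, gs)), rep(0, 3))
})

test_that("module_score is invariant under a constant shift of all values", {
  m <- random_norm_matrix(12, 40, seed = 9)
  gs <- marker_gene_set("set", m$gene_ids[c(3, 11, 25, 38)])
  cfg <- module_score_config(n_bins = 6, n_ctrl = 10, seed = 4)
  base <- module_score(m, gs, cfg)
  shifted <- m
  shifted$values <- m$values + 1.7
  expect_equal(module_score(shifted, gs, cfg), base, tolerance = 1e-12)
})

test_that("module_score validates its inputs", {
  m <- random_norm_matrix(6, 30, seed = 1)
  raw <- expression_matrix(matrix(1L, 2, 30), c("a", "b"), m$gene_ids)
  gs <- marker_gene_set("set", m$gene_ids[1:3])
  expect_error(module_score(raw, gs), "normalized layer")
  expect_error(module_score(m, marker_gene_set("none", c("NOPE1", "NOPE2"))),
               "no genes of set 'none'")
  expect_error(module_score(m, gs, module_score_config(n_bins = 31)),
               "n_bins")
  expect_warning(
    module_score(m, marker_gene_set("part", c(m$gene_ids[1], "NOPE"))),
    "absent from the matrix")
})

test_that("seeded scoring is reproducible and seed-sensitive", {
  m <- random_norm_matrix(10, 45, seed = 2)
  gs <- marker_gene_set("set", m$gene_ids[1:5])
  a <- module_score(m, gs, module_score_config(seed = 7))
  b <- module_score(m, gs, module_score_config(seed = 7))
  expect_identical(a, b)
})

test_that("marker-gene PCA separates marker-driven clusters", {
  set.seed(31)
  n <- 30
  base <- matrix(rpois(2 * n * 60, 5), nrow = 2 * n)
  base[1:n, 1:10] <- matrix(rpois(n * 10, 40), nrow = n)  # cluster 1 high
  m <- expression_matrix(base, sprintf("c%d", 1:(2 * n)),
                         c(sprintf("MK%02d", 1:10), sprintf("BG%02d", 1:50)),
                         layer = "raw_counts")
  norm <- normalize_rc(m)
  gs <- marker_gene_set("mk", sprintf("MK%02d", 1:10))
  emb <- pca_on_markers(norm, list(gs), n_components = 2)
  expect_equal(dim(emb), c(2 * n, 2))
  # PC1 separates the clusters
  g1 <- emb[1:n, 1]; g2 <- emb[(n + 1):(2 * n), 1]
  expect_true(min(g1) > max(g2) || max(g1) < min(g2))
  # silhouette of the two groups on PC1 is positive
  sil <- function(a, b) {
    s <- vapply(seq_along(a), function(i) {
      wa <- mean(abs(a[i] - a[-i])); wb <- mean(abs(a[i] - b))
      (wb - wa) / max(wa, wb)
    }, numeric(1))
    mean(s)
  }
  expect_gt(sil(g1, g2), 0)
  # embedding columns are orthogonal
  expect_lt(abs(sum(emb[, 1] * emb[, 2])), 1e-8)
})

test_that("PCA handles degenerate input per contract", {
  flat <- expression_matrix(matrix(3, 8, 12), sprintf("c%d", 1:8),
                            sprintf("g%02d", 1:12),
                            layer = "log_normalized")
  gs <- marker_gene_set("all", flat$gene_ids)
  expect_warning(emb <- pca_on_markers(flat, gs, 2), "zero variance")
  expect_true(all(emb == 0))
  m <- random_norm_matrix(5, 12, seed = 3)
  expect_error(pca_on_markers(m, marker_gene_set("one", m$gene_ids[1]), 2),
               "marker genes matched")
})
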