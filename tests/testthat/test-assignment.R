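test_that("first-pass rules follow the documented preference order", {
  s <- c(0.5, -0.2, 0.3, 0.1, 0.0)
  g2m <- c(0.1, -0.1, 0.3, 0.4, 0.0)
  expect_identical(unname(assign_first_pass(s, g2m)),
                   c("S", "G1", "G2M", "G2M", "G1"))
  expect_error(assign_first_pass(c(NaN, 1), c(0, 0)), "non-finite")
  expect_error(assign_first_pass(setNames(c(NA, 1), c("cellX", "cellY")),
                                 c(0, 0)), "cellX")
})

test_that("second pass matches the brute-force two-score argmax oracle", {
  m <- random_norm_matrix(15, 40, seed = 21)
  m_genes <- m$gene_ids[c(1, 5, 9, 13)]
  g2_genes <- m$gene_ids[c(2, 6, 10)]
  cfg <- module_score_config(n_bins = 5, n_ctrl = 4, seed = 21)
  got <- assign_second_pass(m, marker_gene_set("M", m_genes),
                            marker_gene_set("G2", g2_genes), cfg)
  want <- oracle_second_pass(m$values, m$gene_ids, m_genes, g2_genes,
                             n_bins = 5, n_ctrl = 4, seed = 21)
  expect_identical(got$phase, want$phase)
  expect_equal(got$m_score, want$m_score, tolerance = 1e-10)
  expect_equal(got$g2_score, want$g2_score, tolerance = 1e-10)
})

test_that("uniform expression yields zero scores and the G2 default", {
  flat <- expression_matrix(matrix(1.5, 6, 50), sprintf("c%d", 1:6),
                            sprintf("g%02d", 1:50),
                            layer = "log_normalized")
  res <- assign_second_pass(flat, marker_gene_set("M", flat$gene_ids[1:5]),
                            marker_gene_set("G2", flat$gene_ids[6:10]),
                            module_score_config(n_bins = 4, n_ctrl = 5))
  expect_equal(res$m_score, rep(0, 6))
  expect_equal(res$g2_score, rep(0, 6))
  expect_identical(res$phase, rep("G2", 6))
})

test_that("a cell overexpressing the mitotic programme is called M", {
  sim <- small_simulation(seed = 13, marker_fold = 8, cells = 25)
  norm <- normalize_rc(sim$matrix)
  pool_ids <- names(sim$truth)[sim$truth %in% c("G2", "M")]
  sub <- subset_matrix(norm, cells = pool_ids)
  res <- assign_second_pass(sub, load_builtin_geneset("mitotic_table1"),
                            load_builtin_geneset("interphase_table2"))
  truth_pool <- sim$truth[pool_ids]
  expect_gt(mean(res$phase[truth_pool == "M"] == "M"), 0.9)
  expect_gt(mean(res$phase[truth_pool == "G2"] == "G2"), 0.9)
})

test_that("empty G2/M pool short-circuits the second pass", {
  m <- expression_matrix(matrix(numeric(0), nrow = 0, ncol = 30),
                         character(0), sprintf("g%02d", 1:30),
                         layer = "log_normalized")
  res <- assign_second_pass(m, load_builtin_geneset("mitotic_table1"),
                            load_builtin_geneset("interphase_table2"))
  expect_identical(nrow(res), 0L)
})

test_that("run_mosmis partitions cells and recovers simulated labels", {
  sim <- small_simulation(seed = 7, cells = 50)
  res <- run_mosmis(sim$matrix)
  expect_setequal(res$final[res$first_pass == "G1"], "G1")
  expect_true(all(res$final %in% c("G1", "S", "G2", "M")))
  # G2 and M finals exactly partition the first-pass G2M pool
  expect_identical(sort(res$cell_id[res$final %in% c("G2", "M")]),
                   sort(res$cell_id[res$first_pass == "G2M"]))
  expect_true(all(is.na(res$m_score[res$first_pass != "G2M"])))
  expect_true(all(!is.na(res$m_score[res$first_pass == "G2M"])))
  acc <- balanced_accuracy(res$final, sim$truth[res$cell_id])
  expect_gt(acc, 0.85)
})

test_that("run_mosmis is deterministic for a fixed seed", {
  sim <- small_simulation(seed = 19, cells = 20)
  a <- run_mosmis(sim$matrix)
  b <- run_mosmis(sim$matrix)
  expect_identical(a, b)
})

test_that("datasets with no first-pass G2M pool skip the second pass", {
  # only G1 and S cells simulated, and scores forced away from G2M by
  # removing the shared-programme signal
  sim <- simulate_phased_counts(simulation_config(
    n_cells_per_phase = c(G1 = 30, S = 30, G2 = 0, M = 0),
    n_background_genes = 600, marker_fold = 6, seed = 23))
  res <- run_mosmis(sim$matrix)
  if (!any(res$first_pass == "G2M")) {
    expect_true(all(res$final %in% c("G1", "S")))
  }
  expect_identical(res$final[res$first_pass != "G2M"],
                   res$first_pass[res$first_pass != "G2M"])
  expect_true(all(is.na(res$g2_score[res$first_pass != "G2M"])))
})

test_that("boosting mitotic markers in a cell never flips it M -> G2", {
  sim <- small_simulation(seed = 29, cells = 20)
  cfg <- mosmis_config()
  res <- run_mosmis(sim$matrix, cfg)
  pool <- res$cell_id[res$first_pass == "G2M"]
  m_cells <- res$cell_id[!is.na(res$m_score) & res$final == "M"]
  expect_gt(length(m_cells), 0)
  m_idx <- match(cfg$m_set$genes, sim$matrix$gene_ids)
  m_idx <- m_idx[!is.na(m_idx)]
  for (cell in head(m_cells, 3)) {
    for (factor in c(2, 5)) {
      boosted <- sim$matrix
      ci <- match(cell, boosted$cell_ids)
      boosted$values[ci, m_idx] <- boosted$values[ci, m_idx] * factor
      res2 <- run_mosmis(boosted, cfg)
      expect_identical(res2$final[res2$cell_id == cell], "M")
    }
  }
})

test_that("label recovery does not degrade as marker fold grows", {
  accs <- vapply(c(1, 2, 4, 8), function(f) {
    sim <- small_simulation(seed = 37, marker_fold = f, cells = 30)
    res <- run_mosmis(sim$matrix)
    balanced_accuracy(res$final, sim$truth[res$cell_id])
  }, numeric(1))
  # non-strict monotone improvement, allowing simulation noise
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[4], accs[1])
})

test_that("with no phase signal the G2-vs-M split is chance-level", {
  # under marker_fold = 1 the true label carries no expression signal, so
  # the rate of M calls must not depend on whether a pooled cell is truly
  # M or truly G2
  m_of_trueM <- 0; n_trueM <- 0; m_of_trueG2 <- 0; n_trueG2 <- 0
  for (s in 1:10) {
    sim <- simulate_phased_counts(simulation_config(
      n_cells_per_phase = c(G1 = 25, S = 25, G2 = 25, M = 25),
      n_background_genes = 600, marker_fold = 1, seed = s))
    res <- run_mosmis(sim$matrix)
    pool <- res$first_pass == "G2M"
    truth <- sim$truth[res$cell_id]
    is_m_call <- res$final == "M"
    m_of_trueM <- m_of_trueM + sum(pool & truth == "M" & is_m_call)
    n_trueM <- n_trueM + sum(pool & truth == "M")
    m_of_trueG2 <- m_of_trueG2 + sum(pool & truth == "G2" & is_m_call)
    n_trueG2 <- n_trueG2 + sum(pool & truth == "G2")
  }
  expect_gt(n_trueM, 20)
  expect_gt(n_trueG2, 20)
  p1 <- m_of_trueM / n_trueM
  p2 <- m_of_trueG2 / n_trueG2
  p <- (m_of_trueM + m_of_trueG2) / (n_trueM + n_trueG2)
  se <- sqrt(p * (1 - p) * (1 / n_trueM + 1 / n_trueG2))
  expect_lt(abs(p1 - p2), 3 * se)
})
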