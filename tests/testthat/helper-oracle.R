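# Independent brute-force reference for the binned-control module score.
# Deliberately written with explicit scalar loops and its own derivations
# of the binning and pooling rules; shares only the stated contract with
# the package implementation (and the RNG stream, which is part of that
# contract: one sample() call per target gene, in gene-set order).
oracle_module_score <- function(values, gene_ids, geneset_genes,
                                n_bins, n_ctrl, seed) {
  values <- as.matrix(values)
  n_cells <- nrow(values)
  n_genes <- ncol(values)

  means <- numeric(n_genes)
  for (j in seq_len(n_genes)) {
    s <- 0
    for (i in seq_len(n_cells)) s <- s + values[i, j]
    means[j] <- s / n_cells
  }
  # stable ascending rank (ties keep original column order)
  ord <- order(means)
  rnk <- integer(n_genes)
  for (pos in seq_len(n_genes)) rnk[ord[pos]] <- pos
  bin <- integer(n_genes)
  for (j in seq_len(n_genes)) bin[j] <- ceiling(rnk[j] * n_bins / n_genes)

  targets <- integer(0)
  for (g in geneset_genes) {
    hit <- which(gene_ids == g)
    if (length(hit)) targets <- c(targets, hit[1])
  }
  stopifnot(length(targets) > 0)

  set.seed(seed)
  pool <- integer(0)
  for (t_idx in targets) {
    cand <- integer(0)
    for (j in seq_len(n_genes)) {
      if (bin[j] == bin[t_idx] && !(j %in% targets)) cand <- c(cand, j)
    }
    if (length(cand) == 0) {
      for (j in seq_len(n_genes)) {
        if (bin[j] == bin[t_idx] && j != t_idx) cand <- c(cand, j)
      }
    }
    if (length(cand) == 0) cand <- t_idx
    drawn <- if (length(cand) >= n_ctrl) {
      sample(cand, n_ctrl, replace = FALSE)
    } else {
      sample(cand, n_ctrl, replace = TRUE)
    }
    pool <- c(pool, drawn)
  }

  scores <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    tm <- 0
    for (t_idx in targets) tm <- tm + values[i, t_idx]
    tm <- tm / length(targets)
    cm <- 0
    for (p_idx in pool) cm <- cm + values[i, p_idx]
    cm <- cm / length(pool)
    scores[i] <- tm - cm
  }
  scores
}

# Brute-force G2-vs-M call: two oracle scores + scalar argmax rule.
oracle_second_pass <- function(values, gene_ids, m_genes, g2_genes,
                               n_bins, n_ctrl, seed) {
  m_sc <- oracle_module_score(values, gene_ids, m_genes, n_bins, n_ctrl, seed)
  g2_sc <- oracle_module_score(values, gene_ids, g2_genes, n_bins, n_ctrl, seed)
  out <- character(length(m_sc))
  for (i in seq_along(m_sc)) {
    out[i] <- if (m_sc[i] > g2_sc[i] && m_sc[i] > 0) "M" else "G2"
  }
  list(phase = out, m_score = m_sc, g2_score = g2_sc)
}
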