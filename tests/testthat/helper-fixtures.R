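# shared fixture builders; everything is generated in code, no files

make_matrix <- function(nr, nc, vals, gene_prefix = "g", cell_prefix = "c") {
  matrix(vals, nr, nc,
         dimnames = list(sprintf("%s%03d", gene_prefix, seq_len(nr)),
                         sprintf("%s%03d", cell_prefix, seq_len(nc))))
}

make_em <- function(vals, nr = NULL, nc = NULL, transform = "precomputed") {
  if (is.matrix(vals)) {
    if (is.null(dimnames(vals)))
      dimnames(vals) <- list(sprintf("g%03d", seq_len(nrow(vals))),
                             sprintf("c%03d", seq_len(ncol(vals))))
    ExpressionMatrix(vals, transform = transform)
  } else {
    ExpressionMatrix(make_matrix(nr, nc, vals), transform = transform)
  }
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# brute-force interaction tally by explicit triple loop over (pair, c1, c2)
oracle_interactions <- function(binary, db, groups) {
  glev <- sort(unique(groups))
  inter <- list(); self <- list()
  for (k in seq_len(nrow(db))) {
    L <- db$ligand[k]; R <- db$receptor[k]
    if (!(L %in% rownames(binary)) || !(R %in% rownames(binary))) next
    for (g1 in glev) for (g2 in glev) {
      cnt <- 0L
      for (c1 in which(groups == g1)) for (c2 in which(groups == g2)) {
        if (c1 != c2 && binary[L, c1] && binary[R, c2]) cnt <- cnt + 1L
      }
      inter[[length(inter) + 1L]] <- data.frame(
        ligand = L, receptor = R, sender = g1, receiver = g2, count = cnt,
        stringsAsFactors = FALSE)
    }
    for (g in glev) {
      cnt <- sum(binary[L, groups == g] & binary[R, groups == g])
      self[[length(self) + 1L]] <- data.frame(
        ligand = L, receptor = R, group = g, count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  list(intercellular = do.call(rbind, inter),
       self_sufficient = do.call(rbind, self))
}

# sort interaction tables into a canonical order for comparison
canon <- function(df) {
  df <- df[do.call(order, df[setdiff(names(df), "count")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# small ascites-like config without CNV, for interaction tests
interaction_config <- function(seed = 1) {
  ascites_config(
    seed = seed, n_genes = 1000,
    groups = data.frame(name = c("tumor", "macrophage"),
                        celltype = c("tumor", "macrophage"),
                        n_cells = c(30L, 30L)),
    cnv = NULL)
}

# per-cell centering offset of the CEP from an explicit oracle loop
oracle_center <- function(z, ann, window) {
  ma <- NULL
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    if (length(idx) < window) next
    for (s in seq_len(length(idx) - window + 1))
      ma <- rbind(ma, colMeans(z[idx[s:(s + window - 1)], , drop = FALSE]))
  }
  colMeans(ma)
}
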