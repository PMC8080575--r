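make_ann <- function(genes, chrom, start = NULL) {
  if (is.null(start)) start <- seq_along(genes) * 100L
  gene_annotation(genes, chrom, start)
}

test_that("Z-normalization standardizes per gene, clips, and zeroes flat genes", {
  set.seed(31)
  vals <- make_matrix(10, 6, rexp(60))
  vals[4, ] <- 2                       # zero-variance gene
  em <- make_em(vals)
  ann <- make_ann(rownames(vals), rep("1", 10))
  z <- zscore_clip(em, ann, clip = 3)

  # brute-force per-row oracle: (x - mean) / population sd, then clamp
  oracle <- t(apply(vals, 1, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else pmin(pmax((x - mean(x)) / s, -3), 3)
  }))
  dimnames(oracle) <- dimnames(vals)
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_equal(z[4, ], setNames(rep(0, 6), colnames(vals)))

  # an extreme outlier is clamped to the bound
  vals2 <- make_matrix(1, 10, c(rep(0, 9), 100))
  em2 <- make_em(vals2)
  z2 <- zscore_clip(em2, make_ann(rownames(vals2), "2"), clip = 3)
  expect_equal(unname(z2[1, 10]), 3)

  # non-autosomal genes are dropped
  annx <- make_ann(rownames(vals), c(rep("1", 9), "X"))
  expect_message(zx <- zscore_clip(em, annx), "dropped")
  expect_equal(nrow(zx), 9)

  one_cell <- make_em(matrix(1, 3, 1,
                             dimnames = list(paste0("g", 1:3), "c1")))
  expect_error(zscore_clip(one_cell, make_ann(paste0("g", 1:3), "1")),
               "2 cells")
})

test_that("CEP moving averages match an explicit-loop oracle at window 3", {
  set.seed(32)
  genes <- sprintf("g%02d", 1:12)
  z <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(genes, sprintf("c%d", 1:5)))
  ann <- make_ann(genes, c(rep("1", 7), rep("2", 5)))
  res <- compute_cep(z, ann, window = 3)

  # oracle: explicit loop over fully contained windows, then centering
  ma <- NULL
  for (idx in list(1:7, 8:12)) {
    for (s in seq_len(length(idx) - 2)) {
      ma <- rbind(ma, colMeans(z[idx[s:(s + 2)], , drop = FALSE]))
    }
  }
  expected <- sweep(ma, 2, colMeans(ma), "-")
  expect_equal(unname(res$cep), unname(expected), tolerance = 1e-12)
  expect_equal(nrow(res$cep), 5 + 3)  # 7-gene chrom: 5 windows; 5-gene: 3

  # a chromosome with exactly `window` genes yields one window whose
  # pre-centering value is the mean of its Z values
  res2 <- compute_cep(z, ann, window = 5)
  uncentered <- sweep(res2$cep, 2, -oracle_center(z, ann, 5), "-")
  chr2 <- res2$windows$chrom == "2"
  expect_equal(sum(chr2), 1)
  expect_equal(unname(uncentered[chr2, ]), unname(colMeans(z[8:12, ])),
               tolerance = 1e-12)
})

test_that("CEP is centered per cell and invariant to input order", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:40)
  z <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(genes, sprintf("c%d", 1:8)))
  ann <- make_ann(genes, rep(c("1", "2"), each = 20))
  res <- compute_cep(z, ann, window = 4)
  expect_true(all(abs(colMeans(res$cep)) < 1e-9))

  # shuffling cells
  perm <- sample(ncol(z))
  res_c <- compute_cep(z[, perm], ann, window = 4)
  expect_equal(res_c$cep[, colnames(z)], res$cep)

  # shuffling gene rows (annotation defines the sort)
  gperm <- sample(nrow(z))
  res_g <- compute_cep(z[gperm, ], ann, window = 4)
  expect_equal(res_g$cep, res$cep)

  # constant matrix: all CEP zero, MS zero
  zc <- matrix(1.3, 40, 8, dimnames = dimnames(z))
  resc <- compute_cep(zc, ann, window = 4)
  expect_lt(max(abs(resc$cep)), 1e-12)
  expect_lt(max(resc$ms), 1e-24)

  expect_error(compute_cep(z, ann, window = 50), "smaller window")
})

test_that("instability score is the mean of squared CEP values", {
  res <- structure(list(cep = matrix(c(1, -1), 2, 1,
                                     dimnames = list(NULL, "c1"))),
                   class = "CEPResult")
  expect_equal(unname(cnv_instability_ms(res)), 1)

  set.seed(34)
  m <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("c", 1:3)))
  res2 <- structure(list(cep = m), class = "CEPResult")
  expect_equal(cnv_instability_ms(res2), colMeans(m^2))
})

test_that("planted gains are recovered monotonically in amplitude", {
  amps <- c(1.2, 1.5, 2.0)
  seg_cep <- numeric(3); seg_ms <- numeric(3)
  for (i in seq_along(amps)) {
    cfg <- ascites_config(
      seed = 35, n_genes = 2000,
      groups = data.frame(name = c("tumor", "macrophage"),
                          celltype = c("tumor", "macrophage"),
                          n_cells = c(30L, 40L)),
      cnv = data.frame(chrom = "1", first_gene = 10L, n_genes_seg = 150L,
                       factor = amps[i], group = "tumor"),
      lr = NULL)
    sim <- simulate_ascites(cfg)
    em <- pseudo_tpm_normalize(sim$counts)
    z <- zscore_clip(em, sim$annotation)
    res <- compute_cep(z, sim$annotation, window = 100)
    w <- res$windows
    seg <- sim$truth$cnv
    inwin <- w$chrom == seg$chrom & w$first >= seg$gene_from &
      w$last <= seg$gene_to
    tum <- sim$cell_groups == "tumor"
    seg_cep[i] <- mean(res$cep[inwin, tum])
    seg_ms[i] <- mean(res$ms[tum])
  }
  expect_true(all(diff(seg_cep) > 0))
  expect_true(all(diff(seg_ms) > 0))
  expect_true(all(seg_cep > 0))
})

test_that("correlation clustering separates planted clones exactly", {
  # three clones with distinct CNV profiles
  cfg <- ascites_config(
    seed = 36, n_genes = 2000,
    groups = data.frame(name = c("cloneA", "cloneB", "cloneC"),
                        celltype = "tumor", n_cells = c(20L, 20L, 20L)),
    cnv = data.frame(chrom = c("1", "2", "3"),
                     first_gene = c(5L, 5L, 5L),
                     n_genes_seg = c(120L, 120L, 100L),
                     factor = c(2.0, 0.4, 2.0),
                     group = c("cloneA", "cloneB", "cloneC")),
    lr = NULL)
  sim <- simulate_ascites(cfg)
  em <- pseudo_tpm_normalize(sim$counts)
  z <- zscore_clip(em, sim$annotation)
  res <- compute_cep(z, sim$annotation, window = 80)
  cl <- cep_correlation_clusters(res, k = 3)
  expect_equal(adjusted_rand_index(cl$clusters, sim$cell_clones), 1)

  # identical cells correlate at 1; a cell against its negation at -1
  cep2 <- structure(list(cep = cbind(a = rnorm(30), b = 0, c = 0)),
                    class = "CEPResult")
  cep2$cep[, "b"] <- cep2$cep[, "a"]
  cep2$cep[, "c"] <- -cep2$cep[, "a"]
  cl2 <- expect_silent(cep_correlation_clusters(cep2, k = 2))
  expect_equal(cl2$correlation["a", "b"], 1)
  expect_equal(cl2$correlation["a", "c"], -1)

  # zero-variance profile: correlations zeroed with a warning
  cep3 <- structure(list(cep = cbind(a = rnorm(10), flat = 0)),
                    class = "CEPResult")
  expect_warning(cl3 <- cep_correlation_clusters(cep3, k = 2),
                 "zero-variance")
  expect_equal(cl3$correlation["a", "flat"], 0)
})

test_that("Welch test separates instability between groups", {
  set.seed(37)
  ms <- c(rnorm(20, 0, 0.001), rnorm(20, 1, 0.001))
  labels <- rep(c("mac", "tumor"), each = 20)
  res <- compare_ms_groups(ms, labels, c("tumor", "mac"))
  expect_lt(res$p, 0.01)
  expect_gt(res$t, 0)

  same <- c(1, 2, 3, 1, 2, 3)
  res0 <- compare_ms_groups(same, rep(c("a", "b"), each = 3), c("a", "b"))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  expect_error(
    compare_ms_groups(ms, c("solo", labels[-1]), c("solo", "tumor")),
    "solo")
})
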