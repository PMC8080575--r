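test_that("size factors track sequencing depth under both schemes", {
  set.seed(51)
  a <- rpois(40, 20) + 1
  counts <- cbind(c1 = a, c2 = a, c3 = 2 * a)
  rownames(counts) <- sprintf("g%02d", 1:40)

  for (scheme in c("tmm", "median_ratio")) {
    sf <- size_factors(counts, scheme)
    expect_equal(sf[["c1"]], sf[["c2"]], tolerance = 1e-10)
    expect_equal(sf[["c3"]] / sf[["c1"]], 2, tolerance = 1e-8)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  }

  # median-of-ratios equals its direct formula
  set.seed(52)
  counts2 <- matrix(rpois(40 * 6, 30) + 1, 40, 6,
                    dimnames = list(sprintf("g%02d", 1:40),
                                    sprintf("c%d", 1:6)))
  sf2 <- size_factors(counts2, "median_ratio")
  geo <- exp(rowMeans(log(counts2)))
  raw <- apply(counts2 / geo, 2, median)
  expect_equal(unname(sf2), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)

  sparse <- counts2; sparse[cbind(1:40, rep_len(1:6, 40))] <- 0
  expect_error(size_factors(sparse, "median_ratio"), "all-positive")

  # independent cross-check against DESeq2's estimator (which uses the
  # median of log ratios; on matrices with an odd number of all-positive
  # genes the two medians coincide)
  counts3 <- counts2[1:39, ]
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts3)
  mine <- size_factors(counts3, "median_ratio")
  expect_equal(unname(mine), unname(ref / exp(mean(log(ref)))),
               tolerance = 1e-10)
})

test_that("the NB LRT recovers a planted fold change accurately", {
  set.seed(53)
  n <- 80
  groups <- rep(c("g1", "g2"), each = 40)
  mu <- rlnorm(500, 3, 0.8)        # well-expressed genes
  counts <- matrix(rnbinom(500 * n, mu = mu, size = 1 / 0.2), 500, n,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("c%02d", 1:n)))
  # plant log2FC = 3 in 20 genes (higher in g2)
  idx <- 1:20
  counts[idx, groups == "g2"] <-
    rnbinom(20 * 40, mu = 8 * mu[idx], size = 1 / 0.2)
  de <- nb_lrt_de(counts, groups, scheme = "tmm")
  planted <- match(sprintf("g%03d", idx), de$gene)
  expect_true(all(de$fdr[planted] < 0.05))
  expect_lt(max(abs(de$log2fc[planted] - 3)), 0.5)
  expect_identical(attr(de, "levels"), c("g1", "g2"))
  expect_true(all(de$p >= 0 & de$p <= 1))
  # FDR monotone in p
  ord <- order(de$p)
  expect_true(all(diff(de$fdr[ord]) >= -1e-12))
})

test_that("permuting group labels yields uniform p-values", {
  set.seed(54)
  n <- 60
  mu <- rlnorm(400, 2, 1)
  counts <- matrix(rnbinom(400 * n, mu = mu, size = 1 / 0.3), 400, n,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("c%02d", 1:n)))
  groups <- sample(rep(c("a", "b"), each = 30))
  de <- nb_lrt_de(counts, groups, scheme = "median_ratio")
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the LRT agrees with edgeR as an independent reference", {
  set.seed(55)
  n <- 40
  groups <- rep(c("A", "B"), each = 20)
  mu <- rlnorm(300, 3, 0.8)
  counts <- matrix(rnbinom(300 * n, mu = mu, size = 1 / 0.2), 300, n,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   sprintf("c%02d", 1:n)))
  counts[1:15, groups == "B"] <-
    rnbinom(15 * 20, mu = 10 * mu[1:15], size = 1 / 0.2)
  de <- nb_lrt_de(counts, groups, scheme = "tmm")

  y <- edgeR::DGEList(counts = round(counts), group = groups)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  design <- model.matrix(~ groups)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit)
  tab <- lrt$table[de$gene, ]

  # the two engines agree on which genes are differential
  expect_gt(cor(-log10(de$p + 1e-300), -log10(tab$PValue + 1e-300),
                method = "spearman"), 0.9)
  sig_mine <- de$gene[de$fdr < 0.05 & abs(de$log2fc) > 2]
  sig_edger <- rownames(tab)[p.adjust(tab$PValue, "BH") < 0.05 &
                               abs(tab$logFC) > 2]
  expect_setequal(sig_mine, sig_edger)
  expect_gt(cor(de$log2fc, tab$logFC), 0.98)
})

fake_de <- function(genes, logfc, fdr, donor, scheme) {
  d <- data.frame(gene = genes, base_mean = 10, log2fc = logfc,
                  dispersion = 0.1, stat = 1, p = fdr, fdr = fdr,
                  stringsAsFactors = FALSE)
  attr(d, "donor") <- donor
  attr(d, "scheme") <- scheme
  class(d) <- c("DEResult", "data.frame")
  d
}

test_that("signature extraction intersects methods and donors", {
  genes <- c("shared_up", "tmm_only", "donor1_only", "shared_dn", "null")
  mk <- function(donor, tmm_extra) {
    up <- c(3, if (tmm_extra) 3 else 0,
            if (donor == "d1") 3 else 0, -3, 0)
    list(fake_de(genes, up, c(0.01, 0.01, 0.01, 0.01, 0.9), donor, "tmm"),
         fake_de(genes, replace(up, 2, 0),
                 c(0.01, 0.9, 0.01, 0.01, 0.9), donor, "median_ratio"))
  }
  de_list <- c(mk("d1", TRUE), mk("d2", TRUE))
  sig <- extract_signature(de_list)
  expect_identical(sig$up$genes, "shared_up")   # scheme- and donor-common
  expect_identical(sig$down$genes, "shared_dn")

  # order invariance over donors and schemes
  sig_r <- extract_signature(rev(de_list))
  expect_setequal(sig_r$up$genes, sig$up$genes)

  # monotonicity: relaxing cutoffs never shrinks the signature
  sig_lo <- extract_signature(de_list, lfc_min = 1, fdr_max = 0.2)
  expect_true(all(sig$up$genes %in% sig_lo$up$genes))

  # exclusion list removes dissociation-induced genes
  expect_warning(sig_ex <- extract_signature(de_list, exclude = "shared_up"),
                 "empty up-signature")
  expect_length(sig_ex$up$genes, 0)

  expect_error(extract_signature(de_list[c(1, 3)]), "schemes")
})

test_that("M1/M2 extraction recovers planted shared genes and no decoys", {
  ref <- simulate_reference_macrophages(reference_config(seed = 56))
  sig <- extract_m1_m2_signatures(ref$counts, ref$donor, ref$state)
  m1_rec <- mean(ref$truth$m1_shared %in% sig$M1$genes)
  m2_rec <- mean(ref$truth$m2_shared %in% sig$M2$genes)
  expect_gte(m1_rec, 0.9)
  expect_gte(m2_rec, 0.9)
  decoys <- unlist(c(ref$truth$m1_decoys, ref$truth$m2_decoys))
  expect_length(intersect(c(sig$M1$genes, sig$M2$genes), decoys), 0)
  expect_length(attr(sig$de[[1]], "excluded_genes"),
                sum(rowSums(round(ref$counts[, ref$donor == "donor1"])) == 0))
})

test_that("signature scores are subset means over detected genes", {
  vals <- make_matrix(4, 2, c(2, 4, 9, 9, 6, 0, 9, 9))
  rownames(vals) <- c("s1", "s2", "x1", "x2")
  em <- make_em(vals)
  sc <- signature_score(em, c("s1", "s2"))
  expect_equal(unname(sc$score), c(3, 3))

  # absent genes are dropped and genes_used decremented
  sc2 <- signature_score(em, c("s1", "s2", "missing"))
  expect_equal(unname(sc2$score), c(3, 3))
  expect_equal(sc2$genes_used, 2)
  expect_identical(sc2$genes_missing, "missing")
  expect_error(signature_score(em, c("nope1", "nope2")), "nope1")

  set.seed(57)
  big <- make_matrix(60, 100, rexp(6000))
  emb <- make_em(big)
  genes <- sample(rownames(big), 15)
  expect_equal(signature_score(emb, genes)$score,
               colMeans(big[genes, ]))
  # invariance to non-signature perturbation and gene order
  big2 <- big; big2[setdiff(rownames(big), genes), ] <- 0
  expect_equal(signature_score(make_em(big2), rev(genes))$score,
               signature_score(emb, genes)$score)
})

test_that("score rescaling maps the range onto [-1, 1]", {
  expect_equal(rescale_scores(c(0, 5, 10)), c(-1, 0, 1))
  set.seed(58)
  x <- rnorm(50)
  r <- rescale_scores(x)
  expect_equal(range(r), c(-1, 1))
  expect_equal(r, 2 * (x - min(x)) / (max(x) - min(x)) - 1)
  expect_error(rescale_scores(rep(2, 5)), "constant")
})

test_that("polarization fit returns OLS slope with a covering CI", {
  x <- seq(0, 1, length.out = 20)
  f1 <- suppressWarnings(polarization_fit(x, x))  # exact fit warns in summary
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  f2 <- suppressWarnings(polarization_fit(x, 2 * x + 1))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)

  set.seed(59)
  xs <- rnorm(200)
  ys <- 1.5 * xs + rnorm(200, 0, 0.1)
  f3 <- polarization_fit(xs, ys)
  expect_true(f3$slope_ci[1] <= 1.5 && 1.5 <= f3$slope_ci[2])
  expect_equal(f3$mean_diff, mean(ys - xs))
  expect_error(polarization_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("reference overlap is exact set intersection", {
  sig <- signature_set("M2", c("A", "B", "C"))
  refs <- list(bulk = c("B", "C", "D"), curated = c("X", "Y"))
  ov <- overlap_with_reference(sig, refs)
  expect_equal(ov$n_overlap, c(2, 0))
  expect_setequal(attr(ov, "pooled"), c("B", "C"))
  expect_equal(overlap_with_reference(sig, list(same = sig$genes))$n_overlap,
               3)
})
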