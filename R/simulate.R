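#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the ascites cell-population simulator
#'
#' Defaults emulate the cell populations of gastric-cancer malignant
#' ascites profiled on a full-length platform: four patient-specific
#' epithelial tumor clones (70 cells in total), a macrophage population
#' (75 cells) and a small mesothelial population (5 cells), over 5000
#' genes. All tumor cells share a 300-gene trunk gain at factor 1.5 on
#' chromosome 1, and each patient clone additionally carries its own
#' contiguous gain or loss, reproducing the patient-specific chromosomal
#' expression patterns and elevated copy-number fluctuation of tumor
#' cells. Ligand-receptor planting places high CCL3/CCR1 expression in
#' macrophages and IL1B (macrophage) with IL1R2 (tumor).
#'
#' @param seed Integer RNG seed; fixes all outputs.
#' @param n_genes Number of genes (default 5000).
#' @param groups data.frame with `name` (clone/population label),
#'   `celltype` (`tumor`, `macrophage`, `mesothelial`, ...), `n_cells`.
#' @param cnv data.frame with `chrom`, `first_gene`, `n_genes_seg`,
#'   `factor` (> 0 multiplicative), `group`; gene positions are indices
#'   within the chromosome, and `group` matches either a group name (one
#'   clone) or a celltype (all clones of that type, e.g. a trunk event).
#' @param lr data.frame planting ligand-receptor co-expression: `ligand`,
#'   `receptor`, `sender`, `receiver` (celltypes), `amplitude` (mean count
#'   in the expressing cells).
#' @param mean_log,mean_sdlog Log-normal parameters of baseline gene mean
#'   counts.
#' @param dispersion_log,dispersion_sdlog Log-normal parameters of
#'   per-gene NB dispersions.
#' @return A list of class `SimulationConfig`.
#' @export
ascites_config <- function(seed = 1,
                           n_genes = 5000,
                           groups = data.frame(
                             name = c("tumor_p1", "tumor_p2", "tumor_p3",
                                      "tumor_p4", "macrophage",
                                      "mesothelial"),
                             celltype = c("tumor", "tumor", "tumor",
                                          "tumor", "macrophage",
                                          "mesothelial"),
                             n_cells = c(18L, 18L, 17L, 17L, 75L, 5L)),
                           cnv = data.frame(
                             chrom = c("1", "7", "3", "11", "19"),
                             first_gene = c(100L, 1L, 50L, 30L, 60L),
                             n_genes_seg = c(300L, 200L, 200L, 250L, 250L),
                             factor = c(1.5, 1.8, 0.5, 1.8, 0.5),
                             group = c("tumor", "tumor_p1", "tumor_p2",
                                       "tumor_p3", "tumor_p4")),
                           lr = data.frame(
                             ligand = c("CCL3", "IL1B"),
                             receptor = c("CCR1", "IL1R2"),
                             sender = c("macrophage", "macrophage"),
                             receiver = c("macrophage", "tumor"),
                             amplitude = c(25, 25)),
                           mean_log = 0, mean_sdlog = 1,
                           dispersion_log = log(0.15),
                           dispersion_sdlog = 0.4) {
  stopifnot(all(groups$n_cells >= 1L), is.null(cnv) || all(cnv$factor > 0))
  if (is.null(groups$celltype)) groups$celltype <- groups$name
  structure(as.list(environment()), class = "SimulationConfig")
}

block_annotation <- function(n_genes) {
  # autosome blocks proportional to approximate protein-coding gene counts
  w <- c(2050, 1300, 1080, 760, 880, 1050, 920, 680, 790, 740, 1320,
         1030, 330, 620, 610, 860, 1190, 280, 1470, 550, 240, 450)
  sizes <- floor(n_genes * w / sum(w))
  rem <- n_genes - sum(sizes)
  if (rem) {
    top <- order(n_genes * w / sum(w) - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1L
  }
  chrom <- rep(as.character(1:22), times = sizes)
  start <- unlist(lapply(sizes, function(s) seq_len(s) * 1000L))
  gene_annotation(sprintf("gene%05d", seq_len(n_genes)), chrom, start)
}

#' Simulate an ascites-like single-cell count matrix
#'
#' Draws negative-binomial counts with log-normal baseline gene means and
#' per-gene dispersions. Copy-number segments multiply the affected
#' group's means over a contiguous run of genome-ordered genes;
#' ligand-receptor plantings raise the mean of specific genes in specific
#' groups. Gene blocks are assigned to autosomes 1..22 so that every
#' chromosome comfortably exceeds a 150-gene CEP window at the default
#' 5000 genes.
#'
#' @param cfg An [ascites_config()].
#' @return List with `counts` (gene x cell matrix), `cell_groups` (named
#'   celltype per cell), `cell_clones` (clone/population label per cell),
#'   `annotation` ([gene_annotation()]), and `truth` (the planted CNV
#'   segments with absolute gene indices, and the LR table).
#' @export
simulate_ascites <- function(cfg = ascites_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed, {
    ann <- block_annotation(cfg$n_genes)
    genes <- ann$gene_id
    # rename planted ligand/receptor genes so tests can address them
    if (!is.null(cfg$lr) && nrow(cfg$lr)) {
      lr_genes <- unique(c(cfg$lr$ligand, cfg$lr$receptor))
      slot <- cfg$n_genes - length(lr_genes) + seq_along(lr_genes)
      genes[slot] <- lr_genes
      ann$gene_id <- genes
    }
    mu <- stats::rlnorm(cfg$n_genes, cfg$mean_log, cfg$mean_sdlog)
    phi <- stats::rlnorm(cfg$n_genes, cfg$dispersion_log, cfg$dispersion_sdlog)

    clone_of <- rep(cfg$groups$name, times = cfg$groups$n_cells)
    celltype_of <- rep(cfg$groups$celltype, times = cfg$groups$n_cells)
    n_cells <- length(clone_of)
    cells <- sprintf("cell%04d", seq_len(n_cells))

    mu_mat <- matrix(mu, cfg$n_genes, n_cells)
    cnv_truth <- NULL
    if (!is.null(cfg$cnv) && nrow(cfg$cnv)) {
      for (k in seq_len(nrow(cfg$cnv))) {
        seg <- cfg$cnv[k, ]
        on_chrom <- which(ann$chrom == as.character(seg$chrom))
        span <- seg$first_gene:(seg$first_gene + seg$n_genes_seg - 1L)
        if (max(span) > length(on_chrom))
          stop("CNV segment exceeds chromosome ", seg$chrom, call. = FALSE)
        idx <- on_chrom[span]
        cols <- clone_of == seg$group | celltype_of == seg$group
        if (!any(cols))
          stop("CNV segment group '", seg$group, "' matches no cells",
               call. = FALSE)
        mu_mat[idx, cols] <- mu_mat[idx, cols] * seg$factor
        cnv_truth <- rbind(cnv_truth,
          data.frame(chrom = as.character(seg$chrom),
                     gene_from = min(idx), gene_to = max(idx),
                     factor = seg$factor, group = seg$group,
                     stringsAsFactors = FALSE))
      }
    }
    if (!is.null(cfg$lr) && nrow(cfg$lr)) {
      for (k in seq_len(nrow(cfg$lr))) {
        p <- cfg$lr[k, ]
        mu_mat[match(p$ligand, genes), celltype_of == p$sender] <- p$amplitude
        mu_mat[match(p$receptor, genes),
               celltype_of == p$receiver] <- p$amplitude
      }
    }
    counts <- matrix(
      stats::rnbinom(length(mu_mat), mu = mu_mat,
                     size = rep(1 / phi, n_cells)),
      cfg$n_genes, n_cells, dimnames = list(genes, cells))
    list(counts = counts,
         cell_groups = stats::setNames(celltype_of, cells),
         cell_clones = stats::setNames(clone_of, cells),
         annotation = ann,
         truth = list(cnv = cnv_truth, lr = cfg$lr))
  })
}

#' Configuration for the reference-macrophage simulator
#'
#' Defaults emulate an in-vitro differentiated M1/M2 reference captured
#' from two healthy donors (97 M1 and 45 M2 cells in total), with 60
#' shared M1-high genes and 20 shared M2-high genes planted at log2 fold
#' change 3, plus 30 donor-specific decoy DE genes per donor that a
#' cross-donor intersection should reject. Donor-specific baseline
#' variability is modeled as a per-donor log-normal multiplicative factor
#' on every gene.
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes (default 2000).
#' @param donors data.frame with `donor`, `n_m1`, `n_m2`.
#' @param n_m1_shared,n_m2_shared Numbers of shared planted M1-high /
#'   M2-high genes.
#' @param n_decoys_per_donor Donor-specific DE genes per donor (half
#'   M1-high, half M2-high).
#' @param lfc Planted log2 fold change (default 3).
#' @param dispersion NB dispersion of all genes (default 0.2).
#' @param donor_sdlog Log-normal sd of the per-donor gene baseline factor
#'   (default 0.3).
#' @param mean_log,mean_sdlog Log-normal parameters of baseline gene mean
#'   counts; the defaults (1.5, 1.5) emulate deep full-length expected
#'   counts in which a sizable fraction of genes is detected in every
#'   cell, as the median-of-ratios normalization assumes.
#' @param planted_mean_log,planted_mean_sdlog Log-normal parameters for
#'   planted-gene baseline means (kept away from zero so effects are
#'   detectable).
#' @return A `SimulationConfig` list.
#' @export
reference_config <- function(seed = 1,
                             n_genes = 2000,
                             donors = data.frame(
                               donor = c("donor1", "donor2"),
                               n_m1 = c(49L, 48L), n_m2 = c(23L, 22L)),
                             n_m1_shared = 60, n_m2_shared = 20,
                             n_decoys_per_donor = 30,
                             lfc = 3, dispersion = 0.2,
                             donor_sdlog = 0.3,
                             mean_log = 1.5, mean_sdlog = 1.5,
                             planted_mean_log = 2,
                             planted_mean_sdlog = 0.5) {
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate two-donor M1/M2 reference macrophages
#'
#' @param cfg A [reference_config()].
#' @return List with `counts`, `donor` (per-cell), `state` (per-cell
#'   `"M1"`/`"M2"`), and `truth` (gene id vectors: `m1_shared`,
#'   `m2_shared`, and per-donor decoy lists `m1_decoys`, `m2_decoys`).
#' @export
simulate_reference_macrophages <- function(cfg = reference_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"), nrow(cfg$donors) >= 2L)
  with_seed(cfg$seed, {
    genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
    n_special <- cfg$n_m1_shared + cfg$n_m2_shared +
      cfg$n_decoys_per_donor * nrow(cfg$donors)
    if (n_special > cfg$n_genes)
      stop("more planted genes than genes", call. = FALSE)
    pool <- sample.int(cfg$n_genes, n_special)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    m1_idx <- take(cfg$n_m1_shared)
    m2_idx <- take(cfg$n_m2_shared)
    decoys <- lapply(seq_len(nrow(cfg$donors)), function(d) {
      half <- cfg$n_decoys_per_donor %/% 2L
      list(m1 = take(half), m2 = take(cfg$n_decoys_per_donor - half))
    })
    names(decoys) <- cfg$donors$donor

    mu <- stats::rlnorm(cfg$n_genes, cfg$mean_log, cfg$mean_sdlog)
    planted <- c(m1_idx, m2_idx, unlist(decoys))
    mu[planted] <- stats::rlnorm(length(planted), cfg$planted_mean_log,
                                 cfg$planted_mean_sdlog)

    mats <- list(); donor_lab <- character(); state_lab <- character()
    for (d in seq_len(nrow(cfg$donors))) {
      dn <- cfg$donors$donor[d]
      donor_fac <- stats::rlnorm(cfg$n_genes, 0, cfg$donor_sdlog)
      n1 <- cfg$donors$n_m1[d]; n2 <- cfg$donors$n_m2[d]
      mu_m1 <- mu * donor_fac; mu_m2 <- mu * donor_fac
      up1 <- c(m1_idx, decoys[[dn]]$m1)
      up2 <- c(m2_idx, decoys[[dn]]$m2)
      mu_m1[up1] <- mu_m1[up1] * 2^cfg$lfc
      mu_m2[up2] <- mu_m2[up2] * 2^cfg$lfc
      m <- cbind(
        matrix(stats::rnbinom(cfg$n_genes * n1, mu = mu_m1,
                              size = 1 / cfg$dispersion), cfg$n_genes, n1),
        matrix(stats::rnbinom(cfg$n_genes * n2, mu = mu_m2,
                              size = 1 / cfg$dispersion), cfg$n_genes, n2))
      mats[[d]] <- m
      donor_lab <- c(donor_lab, rep(dn, n1 + n2))
      state_lab <- c(state_lab, rep(c("M1", "M2"), c(n1, n2)))
    }
    counts <- do.call(cbind, mats)
    dimnames(counts) <- list(genes,
                             sprintf("mac%04d", seq_len(ncol(counts))))
    list(counts = counts,
         donor = stats::setNames(donor_lab, colnames(counts)),
         state = stats::setNames(state_lab, colnames(counts)),
         truth = list(
           m1_shared = genes[m1_idx],
           m2_shared = genes[m2_idx],
           m1_decoys = lapply(decoys, function(d) genes[d$m1]),
           m2_decoys = lapply(decoys, function(d) genes[d$m2])))
  })
}

#' Configuration for the bulk survival-cohort simulator
#'
#' Defaults emulate a TCGA-style cohort of 300 tumors whose hazard depends
#' on an M2-signature score: signature genes track a latent per-sample M2
#' activity, survival is exponential with log-hazard proportional to the
#' standardized score, and an independent censoring mechanism censors the
#' stated fraction of samples. `coef` is expressed as the log hazard ratio
#' between the top and bottom score quartiles: internally the standardized
#' score is divided by the expected quartile-mean gap of a standard normal
#' (about 2.54), so `coef = log(2.5)` yields an empirical high-vs-low
#' quartile hazard ratio near 2.5.
#'
#' @param seed RNG seed.
#' @param n_samples Cohort size (default 300).
#' @param coef Log hazard ratio between extreme score quartiles (default
#'   `log(2.5)`; 0 gives the null of score-independent survival).
#' @param baseline_hazard Baseline event rate per day (default
#'   `log(2)/730`, a two-year median).
#' @param censoring Fraction of samples censored, in [0, 1) (default 0.2).
#' @param n_background Non-signature noise genes (default 500).
#' @param activity_loading Per-gene loading of signature genes on the
#'   latent activity, in E units per activity sd (default 0.5).
#' @param noise_sd Residual sd of expression in E units (default 0.3).
#' @return A `SimulationConfig` list.
#' @export
cohort_config <- function(seed = 1, n_samples = 300, coef = log(2.5),
                          baseline_hazard = log(2) / 730, censoring = 0.2,
                          n_background = 500, activity_loading = 0.5,
                          noise_sd = 0.3) {
  if (censoring < 0 || censoring >= 1)
    stop("censoring fraction must be in [0, 1)", call. = FALSE)
  stopifnot(is.finite(coef))
  structure(as.list(environment()), class = "SimulationConfig")
}

# expected gap between the mean of the top and bottom quartile of N(0,1)
quartile_gap_normal <- function() 2 * stats::dnorm(stats::qnorm(0.75)) / 0.25

#' Simulate a bulk cohort with signature-linked survival
#'
#' @param cfg A [cohort_config()].
#' @param signature A [signature_set()] or character vector of signature
#'   gene ids to embed in the expression matrix.
#' @return A [survival_cohort()]; the latent activity and true group-free
#'   linear predictor are attached as attribute `"truth"`.
#' @export
simulate_bulk_cohort <- function(cfg = cohort_config(), signature) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- if (inherits(signature, "SignatureSet")) signature$genes
           else unique(as.character(signature))
  if (!length(genes)) stop("signature must be non-empty", call. = FALSE)
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    ids <- sprintf("sample%04d", seq_len(n))
    activity <- stats::rnorm(n)
    base <- stats::runif(length(genes), 2, 4)
    e_sig <- outer(base, rep(1, n)) +
      cfg$activity_loading * outer(rep(1, length(genes)), activity) +
      matrix(stats::rnorm(length(genes) * n, 0, cfg$noise_sd),
             length(genes), n)
    bg <- matrix(stats::rnorm(cfg$n_background * n, 2, 0.8),
                 cfg$n_background, n)
    expr <- pmax(rbind(e_sig, bg), 0)
    dimnames(expr) <- list(
      c(genes, sprintf("bg%05d", seq_len(cfg$n_background))), ids)

    score <- colMeans(expr[genes, , drop = FALSE])
    u <- as.vector(scale(score)) / quartile_gap_normal()
    hazard <- cfg$baseline_hazard * exp(cfg$coef * u)
    t_event <- stats::rexp(n, rate = hazard)
    censored <- stats::runif(n) < cfg$censoring
    t_obs <- ifelse(censored, stats::runif(n) * t_event, t_event)
    clin <- data.frame(sample_id = ids,
                       os_days = pmax(t_obs, 1e-3),
                       os_event = as.integer(!censored),
                       stage = sample(c("I", "II", "III", "IV"), n,
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
    cohort <- survival_cohort(expr, clin, cohort = "synthetic",
                              transform = "precomputed")
    attr(cohort, "truth") <- list(activity = stats::setNames(activity, ids),
                                  linear_predictor = cfg$coef * u)
    cohort
  })
}
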