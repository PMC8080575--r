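#' Z-normalize autosomal gene expression with clipping
#'
#' Standardizes each autosomal gene's expression across cells
#' ((x - mean) / sd, population sd with denominator n) and clamps the
#' result to `[-clip, clip]`. Zero-variance genes map to all-zero rows.
#' This is the first step of chromosomal expression pattern (CEP)
#' inference; restricting to autosomes avoids sex-linked dosage effects.
#'
#' @param em An [ExpressionMatrix()] with at least 2 cells.
#' @param annotation A [gene_annotation()] table; only genes annotated on
#'   chromosomes 1..22 are retained. Genes missing from the annotation are
#'   dropped with a message.
#' @param clip Symmetric clamp bound in Z units (default 3).
#' @return Numeric gene x cell matrix of clipped Z-scores, rows ordered as
#'   in the input.
#' @export
zscore_clip <- function(em, annotation, clip = 3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2L)
    stop("Z-normalization needs at least 2 cells", call. = FALSE)
  aut <- annotation[annotation$chrom %in% as.character(1:22), , drop = FALSE]
  keep <- em$gene_ids %in% aut$gene_id
  n_missing <- sum(!keep)
  if (n_missing)
    message(n_missing, " gene(s) not annotated on autosomes dropped from CEP")
  if (!any(keep))
    stop("no genes left after restricting to annotated autosomes",
         call. = FALSE)
  x <- em$values[keep, , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans(x * x) - mu * mu)  # population sd (ddof = 0)
  z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  pmin(pmax(z, -clip), clip)
}

#' Compute chromosomal expression patterns (CEP)
#'
#' Within each chromosome, genes are sorted by start coordinate (ties by
#' gene id) and moving averages of the clipped Z-scores are taken over
#' every fully contained window of `window` consecutive genes. Each cell's
#' genome-wide mean window value is then subtracted (per-cell centering),
#' yielding a copy-number proxy profile. Chromosomes with fewer genes than
#' `window` contribute no windows.
#'
#' @param z Clipped Z-score matrix from [zscore_clip()].
#' @param annotation A [gene_annotation()] covering the rows of `z`.
#' @param window Number of consecutive genes per window (default 150).
#' @return A `CEPResult`: list with `windows` (data.frame of chrom and the
#'   first/last sorted-gene index of each window), `cep` (window x cell
#'   centered matrix), `ms` (per-cell mean of squared CEP values), and
#'   `params`.
#' @export
compute_cep <- function(z, annotation, window = 150) {
  stopifnot(is.matrix(z), window >= 1)
  ann <- annotation[match(rownames(z), annotation$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id))
    stop("annotation is missing genes present in the Z matrix", call. = FALSE)
  chrom_num <- suppressWarnings(as.integer(ann$chrom))
  if (anyNA(chrom_num))
    stop("CEP requires autosomal chromosomes labeled 1..22", call. = FALSE)
  ord <- order(chrom_num, ann$start, ann$gene_id)
  z <- z[ord, , drop = FALSE]
  chrom_sorted <- chrom_num[ord]

  win_list <- list()
  cep_list <- list()
  for (ch in sort(unique(chrom_sorted))) {
    idx <- which(chrom_sorted == ch)
    n <- length(idx)
    if (n < window) next
    # moving average via cumulative sums over the gene dimension
    cs <- apply(z[idx, , drop = FALSE], 2L, cumsum)
    cs <- rbind(0, cs)
    nwin <- n - window + 1L
    ma <- (cs[(window + 1L):(n + 1L), , drop = FALSE] -
             cs[1L:nwin, , drop = FALSE]) / window
    win_list[[length(win_list) + 1L]] <- data.frame(
      chrom = as.character(ch),
      first = idx[seq_len(nwin)],
      last = idx[seq_len(nwin) + window - 1L])
    cep_list[[length(cep_list) + 1L]] <- ma
  }
  if (!length(cep_list))
    stop("no chromosome has >= ", window,
         " genes; use a smaller window", call. = FALSE)
  windows <- do.call(rbind, win_list)
  cep <- do.call(rbind, cep_list)
  rownames(cep) <- sprintf("%s:%d-%d", windows$chrom, windows$first,
                           windows$last)
  colnames(cep) <- colnames(z)
  cep <- sweep(cep, 2L, colMeans(cep), "-")  # per-cell centering
  res <- structure(
    list(windows = windows, cep = cep, ms = NULL,
         params = list(window = window, n_windows = nrow(cep),
                       centering = "per_cell_mean", sd_ddof = 0)),
    class = "CEPResult")
  res$ms <- cnv_instability_ms(res)
  res
}

#' @method print CEPResult
#' @export
#' @noRd
print.CEPResult <- function(x, ...) {
  cat(sprintf("CEPResult: %d windows (size %d) x %d cells\n",
              nrow(x$cep), x$params$window, ncol(x$cep)))
  invisible(x)
}

#' Per-cell copy-number instability score (mean of squares)
#'
#' MS_j = mean over windows of CEP_wj^2. Aneuploid tumor cells show high
#' MS; diploid stroma and immune cells stay near zero.
#'
#' @param cep_result A `CEPResult` from [compute_cep()].
#' @return Named numeric vector of per-cell MS values (>= 0).
#' @export
cnv_instability_ms <- function(cep_result) {
  stopifnot(inherits(cep_result, "CEPResult"))
  colMeans(cep_result$cep^2)
}

#' Correlation matrix and hierarchical clusters of CEP profiles
#'
#' Pearson correlation between cells over the window dimension, then
#' agglomerative clustering on distance 1 - r cut at `k` clusters.
#' Zero-variance profiles get correlation 0 with a warning.
#'
#' @param cep_result A `CEPResult` with >= 2 cells and >= 2 windows.
#' @param k Number of clusters to cut.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `correlation` (cell x cell matrix) and `clusters`
#'   (named integer vector).
#' @export
cep_correlation_clusters <- function(cep_result, k, linkage = "average") {
  stopifnot(inherits(cep_result, "CEPResult"))
  cep <- cep_result$cep
  if (ncol(cep) < 2L || nrow(cep) < 2L)
    stop("need >= 2 cells and >= 2 windows for correlation clustering",
         call. = FALSE)
  sds <- apply(cep, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(cep))
  if (any(sds == 0)) {
    warning("zero-variance CEP profile(s): ",
            paste(colnames(cep)[sds == 0], collapse = ", "),
            "; correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  clusters <- stats::cutree(hc, k = k)
  list(correlation = r, clusters = clusters)
}

#' Welch t-test of CNV instability between two cell groups
#'
#' Compares MS between the two named groups with a Welch two-sample
#' t-test; cells in other groups are ignored (e.g. a small mesothelial
#' population excluded from testing).
#'
#' @param ms Named per-cell MS vector.
#' @param labels Per-cell group labels, aligned with `ms`.
#' @param groups Character vector of the two group labels to compare; the
#'   statistic is mean(first) - mean(second).
#' @return List with `t`, `p`, `df` and the two group means.
#' @export
compare_ms_groups <- function(ms, labels, groups) {
  stopifnot(length(ms) == length(labels), length(groups) == 2L)
  a <- ms[labels == groups[1L]]
  b <- ms[labels == groups[2L]]
  for (g in seq_along(groups)) {
    n <- c(length(a), length(b))[g]
    if (n < 2L)
      stop(sprintf("group '%s' has %d cell(s); need >= 2", groups[g], n),
           call. = FALSE)
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       means = stats::setNames(c(mean(a), mean(b)), groups))
}
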