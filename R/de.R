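#' Between-cell normalization size factors for count data
#'
#' Two schemes are provided. `"tmm"` combines library depth with a trimmed
#' mean of M-values composition factor: M and A values are computed against
#' a reference cell (the cell whose total count is closest to the median
#' total), genes are trimmed 30% two-sided on M and 5% two-sided on A, and
#' the factor is the precision-weighted mean of the remaining M values.
#' `"median_ratio"` is the median-of-ratios estimator: each cell's median
#' ratio of counts to the per-gene geometric mean, over genes with
#' all-positive counts. Both sets of factors are rescaled to geometric
#' mean 1 and absorb sequencing depth, so doubling every count of a cell
#' doubles its factor.
#'
#' @param counts Numeric gene x cell matrix of (expected) counts, >= 0,
#'   each cell with a positive total.
#' @param scheme `"tmm"` or `"median_ratio"`.
#' @param trim_m,trim_a Two-sided trim fractions for the TMM scheme
#'   (defaults 0.3 and 0.05).
#' @return Named positive numeric vector of per-cell size factors with
#'   geometric mean 1.
#' @export
size_factors <- function(counts, scheme = c("tmm", "median_ratio"),
                         trim_m = 0.3, trim_a = 0.05) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(counts), all(counts >= 0))
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("every cell must have a positive total count", call. = FALSE)
  sf <- switch(scheme,
    tmm = {
      ref <- which.min(abs(tot - stats::median(tot)))
      f <- vapply(seq_len(ncol(counts)), function(j) {
        tmm_factor(counts[, j], counts[, ref], tot[j], tot[ref],
                   trim_m, trim_a)
      }, numeric(1L))
      tot * f
    },
    median_ratio = {
      pos <- rowSums(counts > 0) == ncol(counts)
      if (!any(pos))
        stop("median_ratio: no gene has all-positive counts; ",
             "supply a matrix with shared detected genes", call. = FALSE)
      geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
      apply(counts[pos, , drop = FALSE], 2L,
            function(y) stats::median(y / geo))
    })
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

tmm_factor <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  if (!any(keep)) return(1)
  p <- y[keep] / n
  pr <- yr[keep] / nr
  m <- log2(p / pr)
  a <- 0.5 * log2(p * pr)
  # asymptotic delta-method weights (inverse variance of M)
  w <- (n - y[keep]) / (n * y[keep]) + (nr - yr[keep]) / (nr * yr[keep])
  lo_m <- stats::quantile(m, trim_m, names = FALSE)
  hi_m <- stats::quantile(m, 1 - trim_m, names = FALSE)
  lo_a <- stats::quantile(a, trim_a, names = FALSE)
  hi_a <- stats::quantile(a, 1 - trim_a, names = FALSE)
  sel <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a & is.finite(w) & w > 0
  if (!any(sel)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

# Vectorized Newton fit of per-gene NB intercept models.
# Mean model: mu_gj = exp(eta_g) * sf_j, dispersion phi_g fixed.
# Returns list(eta, loglik) for a gene x cell count matrix.
nb_fit_intercept <- function(y, sf, phi, max_iter = 50L, tol = 1e-10) {
  eta <- log(pmax(rowSums(y), 0.5) / sum(sf))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf
    denom <- 1 + phi * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  list(eta = eta, loglik = nb_rowloglik(y, mu, phi))
}

nb_rowloglik <- function(y, mu, phi) {
  n <- ncol(y)
  size <- rep(ifelse(phi > 1e-8, 1 / phi, Inf), times = n)
  ll <- ifelse(is.finite(size),
               stats::dnbinom(as.vector(y), size = size,
                              mu = as.vector(mu), log = TRUE),
               stats::dpois(as.vector(y), lambda = as.vector(mu), log = TRUE))
  rowSums(matrix(ll, nrow = nrow(y)))
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per-gene negative-binomial GLM with log link and the log size factor as
#' offset; the full model fits one mean per group, the null model a common
#' mean. The likelihood-ratio statistic 2(ll_full - ll_null) is referred
#' to chi-square with 1 df. Tagwise dispersions are moment estimates from
#' the pooled within-group variance of normalized counts, shrunk toward a
#' mean-dispersion trend (`a + b/mean`, least squares); the shrinkage
#' weight is configurable. Fractional expected counts (RSEM-style) are
#' rounded half-to-even before fitting. All-zero genes are excluded from
#' testing and recorded.
#'
#' @param counts Gene x cell matrix of expected counts.
#' @param groups Two-level factor (or coercible) over cells; both levels
#'   need >= 2 cells. The reported log2 fold change is second level vs
#'   first level, computed from size-factor-normalized group means with
#'   pseudocount 0.5.
#' @param scheme Normalization scheme for [size_factors()].
#' @param shrink_weight Weight in [0, 1] pulling tagwise dispersions toward
#'   the trend (default 0.35).
#' @param donor,label Optional metadata tags stored on the result.
#' @return data.frame of class `DEResult` with columns `gene`, `base_mean`,
#'   `log2fc`, `dispersion`, `stat`, `p`, `fdr`; attributes `donor`,
#'   `scheme`, `levels`, `excluded_genes` (all-zero genes), and
#'   `logfc_direction`.
#' @export
nb_lrt_de <- function(counts, groups, scheme = c("tmm", "median_ratio"),
                      shrink_weight = 0.35, donor = NA_character_,
                      label = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(counts))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("both groups need >= 2 cells", call. = FALSE)
  y <- round(counts)  # round-half-even; NB likelihood needs integers
  excluded <- rownames(y)[rowSums(y) == 0]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  if (!nrow(y)) stop("all genes have zero counts", call. = FALSE)
  sf <- size_factors(counts, scheme = scheme)

  g1 <- groups == levels(groups)[1L]
  g2 <- !g1
  z <- sweep(y, 2L, sf, "/")
  m1 <- rowMeans(z[, g1, drop = FALSE]); m2 <- rowMeans(z[, g2, drop = FALSE])
  v1 <- row_var(z[, g1, drop = FALSE]); v2 <- row_var(z[, g2, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(g2)
  v_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m_bar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  c1 <- mean(1 / sf)
  phi_raw <- pmax((v_pool - m_bar * c1) / m_bar^2, 0)
  phi <- shrink_dispersion(phi_raw, m_bar, shrink_weight)

  fit0 <- nb_fit_intercept(y, sf, phi)
  fit1 <- nb_fit_intercept(y[, g1, drop = FALSE], sf[g1], phi)
  fit2 <- nb_fit_intercept(y[, g2, drop = FALSE], sf[g2], phi)
  stat <- pmax(2 * (fit1$loglik + fit2$loglik - fit0$loglik), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  res <- data.frame(
    gene = rownames(y),
    base_mean = m_bar,
    log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
    dispersion = phi,
    stat = stat,
    p = p,
    fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "donor") <- donor
  attr(res, "scheme") <- scheme
  attr(res, "levels") <- levels(groups)
  attr(res, "excluded_genes") <- excluded
  attr(res, "logfc_direction") <-
    sprintf("positive = higher in '%s' (vs '%s')",
            levels(groups)[2L], levels(groups)[1L])
  if (!is.null(label)) attr(res, "label") <- label
  class(res) <- c("DEResult", "data.frame")
  res
}

row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

shrink_dispersion <- function(phi_raw, mean_norm, weight, floor = 1e-8) {
  ok <- mean_norm > 0 & is.finite(phi_raw)
  trend <- rep(stats::median(phi_raw[ok]), length(phi_raw))
  if (sum(ok) >= 10L) {
    fit <- stats::lm(phi_raw[ok] ~ I(1 / mean_norm[ok]))
    co <- stats::coef(fit)
    trend <- pmax(co[1L] + co[2L] / mean_norm, 0)
  }
  pmax((1 - weight) * phi_raw + weight * trend, floor)
}
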