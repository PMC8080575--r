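#' Quartile-based high/low group assignment
#'
#' Labels samples `"high"` when their score strictly exceeds the 75th
#' percentile and `"low"` when strictly below the 25th percentile
#' (percentiles by type-7 linear interpolation); samples in between,
#' including boundary ties, are `"excluded"`. Translation of the scores
#' leaves the grouping unchanged.
#'
#' @param scores Numeric per-sample scores (n >= 8, not all identical).
#' @return Character vector in \{"high", "low", "excluded"\}, named like
#'   `scores`.
#' @export
quartile_groups <- function(scores) {
  if (inherits(scores, "SignatureScore")) scores <- scores$score
  if (length(scores) < 8L)
    stop("quartile stratification needs >= 8 samples", call. = FALSE)
  if (diff(range(scores)) == 0)
    stop("all scores identical; quartile groups undefined", call. = FALSE)
  qs <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  out <- rep("excluded", length(scores))
  out[scores > qs[2L]] <- "high"
  out[scores < qs[1L]] <- "low"
  stats::setNames(out, names(scores))
}

#' Kaplan-Meier curves and log-rank test for high vs low groups
#'
#' Fits product-limit survival curves per group and compares the high and
#' low groups with the two-group log-rank test (chi-square, 1 df);
#' `"excluded"` samples are ignored.
#'
#' @param cohort A [survival_cohort()].
#' @param groups Character vector from [quartile_groups()], aligned with the
#'   cohort samples (or named by sample id).
#' @return Object of class `KMResult`: list with `groups`, `curves`
#'   (data.frame: group, time, surv, n_risk, n_event), `chisq`, `p`, `n`.
#' @export
km_logrank <- function(cohort, groups) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  clin <- cohort$clinical
  if (!is.null(names(groups)))
    groups <- groups[clin$sample_id]
  stopifnot(length(groups) == nrow(clin))
  use <- groups %in% c("high", "low")
  n_high <- sum(groups == "high"); n_low <- sum(groups == "low")
  if (n_high == 0L || n_low == 0L)
    stop("both 'high' and 'low' groups must be non-empty", call. = FALSE)
  time <- clin$os_days[use]; event <- clin$os_event[use]
  g <- factor(groups[use], levels = c("low", "high"))
  if (sum(event) < 1L)
    stop("need at least one event for the log-rank test", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  curves <- data.frame(
    group = rep(sub("^g=", "", names(sf$strata)),
                times = sf$strata),
    time = sf$time, surv = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event,
    stringsAsFactors = FALSE)
  structure(
    list(groups = groups,
         curves = curves,
         chisq = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n = c(high = n_high, low = n_low,
               excluded = sum(groups == "excluded"))),
    class = "KMResult")
}

#' @method print KMResult
#' @export
#' @noRd
print.KMResult <- function(x, ...) {
  cat(sprintf("KMResult: high n=%d, low n=%d (excluded %d); log-rank chisq=%.3f, p=%.3g\n",
              x$n["high"], x$n["low"], x$n["excluded"], x$chisq, x$p))
  invisible(x)
}

#' Survival stratification by a signature score
#'
#' Scores the cohort with [signature_score()], stratifies with
#' [quartile_groups()] and tests with [km_logrank()].
#'
#' @param cohort A [survival_cohort()].
#' @param signature A [signature_set()] or character vector of gene ids.
#' @return A `KMResult`; the scores used are attached as attribute
#'   `"score"`.
#' @export
signature_survival <- function(cohort, signature) {
  sc <- signature_score(cohort$expression, signature)
  res <- km_logrank(cohort, quartile_groups(sc$score))
  attr(res, "score") <- sc$score
  attr(res, "genes_used") <- sc$genes_used
  res
}

#' Survival stratification by a single gene
#'
#' Applies [quartile_groups()] to one gene's expression and runs
#' [km_logrank()]; used to test the prognostic value of individual
#' signature genes (e.g. CD68, CD163).
#'
#' @param cohort A [survival_cohort()].
#' @param gene Gene id present in the cohort expression matrix.
#' @return A `KMResult`.
#' @export
gene_level_survival <- function(cohort, gene) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  if (!gene %in% rownames(cohort$expression$values))
    stop("gene '", gene, "' not present in the cohort", call. = FALSE)
  e <- cohort$expression$values[gene, ]
  km_logrank(cohort, quartile_groups(e))
}

#' Leave-one-out robustness of a signature's survival association
#'
#' For each gene in the signature, re-scores the cohort with the signature
#' minus that gene, re-stratifies and reports the log-rank p-value; a
#' robust association keeps all leave-one-out p-values small.
#'
#' @param cohort A [survival_cohort()].
#' @param signature A [signature_set()] or character vector (>= 2 genes).
#' @return data.frame with `left_out`, `p`, `chisq`, `genes_used`.
#' @export
leave_one_out_signature_survival <- function(cohort, signature) {
  genes <- if (inherits(signature, "SignatureSet")) signature$genes
           else unique(as.character(signature))
  if (length(genes) < 2L)
    stop("leave-one-out needs a signature of >= 2 genes", call. = FALSE)
  rows <- lapply(genes, function(g) {
    sc <- signature_score(cohort$expression, setdiff(genes, g))
    km <- km_logrank(cohort, quartile_groups(sc$score))
    data.frame(left_out = g, p = km$p, chisq = km$chisq,
               genes_used = sc$genes_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
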