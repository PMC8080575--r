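#' Construct a signature gene set
#'
#' @param name Signature name (e.g. `"M1"`, `"M2"`).
#' @param genes Character vector of gene ids (deduplicated).
#' @param provenance Optional list describing how the set was derived.
#' @return Object of class `SignatureSet`.
#' @export
signature_set <- function(name, genes, provenance = list()) {
  structure(list(name = name, genes = unique(as.character(genes)),
                 provenance = provenance),
            class = "SignatureSet")
}

#' @method print SignatureSet
#' @export
#' @noRd
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Extract up/down signatures by dual-method, dual-donor intersection
#'
#' Within each donor, candidate up-genes are the intersection over
#' normalization schemes of genes with `log2fc > lfc_min` and
#' `fdr < fdr_max`; the final up-signature is the intersection of the
#' per-donor candidates across donors (analogously for down-genes with
#' `log2fc < -lfc_min`). Requiring agreement between both normalization
#' schemes and both donors suppresses method- and donor-specific false
#' positives.
#'
#' @param de_list List of [nb_lrt_de()] results, each tagged with `donor`
#'   and `scheme` attributes; every donor must contribute exactly the same
#'   set of (>= 2) schemes.
#' @param lfc_min Log2 fold-change cutoff (default 2).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param names Length-2 character: names for the up and down signatures.
#' @param exclude Optional character vector of genes to drop from the final
#'   signatures (e.g. dissociation-induced immediate-early genes such as
#'   EGR1, FOS, FOSB, JUN); default none.
#' @return List with elements `up` and `down`, both [signature_set()]s
#'   (possibly empty, with a warning).
#' @export
extract_signature <- function(de_list, lfc_min = 2, fdr_max = 0.05,
                              names = c("up", "down"),
                              exclude = character()) {
  donors <- vapply(de_list, function(d) as.character(attr(d, "donor")),
                   character(1L))
  schemes <- vapply(de_list, function(d) as.character(attr(d, "scheme")),
                    character(1L))
  if (anyNA(donors) || any(!nzchar(donors)))
    stop("every DE result must carry a donor tag", call. = FALSE)
  scheme_sets <- split(schemes, donors)
  n_schemes <- unique(vapply(scheme_sets, length, integer(1L)))
  if (length(n_schemes) != 1L || n_schemes < 2L ||
      any(vapply(scheme_sets, anyDuplicated, integer(1L)) > 0L))
    stop("each donor needs the same >= 2 distinct normalization schemes",
         call. = FALSE)

  pick <- function(d, dir) {
    hit <- d$fdr < fdr_max &
      (if (dir > 0) d$log2fc > lfc_min else d$log2fc < -lfc_min)
    d$gene[hit]
  }
  per_donor <- function(dir) {
    lapply(split(de_list, donors), function(tables)
      Reduce(intersect, lapply(tables, pick, dir = dir)))
  }
  up <- Reduce(intersect, per_donor(1))
  down <- Reduce(intersect, per_donor(-1))
  up <- setdiff(up, exclude)
  down <- setdiff(down, exclude)
  if (!length(up)) warning("empty up-signature after intersection")
  if (!length(down)) warning("empty down-signature after intersection")
  prov <- list(donors = unique(donors), schemes = sort(unique(schemes)),
               lfc_min = lfc_min, fdr_max = fdr_max, excluded = exclude)
  list(up = signature_set(names[1L], up, prov),
       down = signature_set(names[2L], down, prov))
}

#' Extract M1/M2 macrophage signatures from reference counts
#'
#' Convenience pipeline: for each donor, runs [nb_lrt_de()] under both
#' normalization schemes contrasting M1 vs M2 cells (positive fold change =
#' higher in M1), then intersects with [extract_signature()]. The up-set is
#' the M1 signature, the down-set the M2 signature.
#'
#' @param counts Gene x cell expected-count matrix of reference
#'   macrophages.
#' @param donor Per-cell donor labels.
#' @param state Per-cell polarization labels, values `"M1"`/`"M2"`.
#' @param lfc_min,fdr_max Cutoffs passed to [extract_signature()].
#' @param shrink_weight Passed to [nb_lrt_de()].
#' @param exclude Genes removed from final signatures (default none).
#' @return List with `M1` and `M2` [signature_set()]s plus `de` (the four
#'   DE tables).
#' @export
extract_m1_m2_signatures <- function(counts, donor, state, lfc_min = 2,
                                     fdr_max = 0.05, shrink_weight = 0.35,
                                     exclude = character()) {
  stopifnot(length(donor) == ncol(counts), length(state) == ncol(counts))
  if (!all(state %in% c("M1", "M2")))
    stop("`state` must be 'M1' or 'M2'", call. = FALSE)
  de <- list()
  for (d in unique(donor)) {
    sel <- donor == d
    for (sch in c("tmm", "median_ratio")) {
      de[[paste(d, sch, sep = ".")]] <- nb_lrt_de(
        counts[, sel, drop = FALSE],
        groups = factor(state[sel], levels = c("M2", "M1")),
        scheme = sch, shrink_weight = shrink_weight, donor = d)
    }
  }
  sig <- extract_signature(de, lfc_min = lfc_min, fdr_max = fdr_max,
                           names = c("M1", "M2"), exclude = exclude)
  list(M1 = sig$up, M2 = sig$down, de = de)
}

#' Score cells or samples with a gene signature
#'
#' The signature score E_s is the mean E value over the signature genes
#' detected in the matrix; genes absent from the matrix are dropped and
#' the number of genes actually used is reported.
#'
#' @param em An [ExpressionMatrix()].
#' @param signature A [signature_set()] or a character vector of gene ids.
#' @return Object of class `SignatureScore`: list with `score` (named
#'   per-cell numeric), `genes_used`, `genes_missing`, `signature` name.
#' @export
signature_score <- function(em, signature) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  genes <- if (inherits(signature, "SignatureSet")) signature$genes
           else unique(as.character(signature))
  name <- if (inherits(signature, "SignatureSet")) signature$name else "custom"
  present <- intersect(genes, em$gene_ids)
  if (!length(present))
    stop("no signature gene present in the matrix; missing: ",
         paste(utils::head(genes, 10L), collapse = ", "), call. = FALSE)
  score <- colMeans(em$values[present, , drop = FALSE])
  structure(list(score = score, genes_used = length(present),
                 genes_missing = setdiff(genes, present), signature = name),
            class = "SignatureScore")
}

#' @method print SignatureScore
#' @export
#' @noRd
print.SignatureScore <- function(x, ...) {
  cat(sprintf("SignatureScore '%s': %d cells, %d genes used\n",
              x$signature, length(x$score), x$genes_used))
  invisible(x)
}

#' Rescale scores to [-1, 1]
#'
#' Affine map sending the observed minimum to -1 and maximum to +1.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Numeric vector in [-1, 1].
#' @export
rescale_scores <- function(scores) {
  if (inherits(scores, "SignatureScore")) scores <- scores$score
  rng <- range(scores)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("constant scores cannot be rescaled to [-1, 1]", call. = FALSE)
  2 * (scores - rng[1L]) / (rng[2L] - rng[1L]) - 1
}

#' Linear polarization fit of M2 on M1 scores
#'
#' Ordinary least squares of the per-cell M2 signature score on the M1
#' score, summarizing how macrophages incline toward the M2 axis. Returns
#' the slope with 95% confidence interval and the mean score difference
#' mean(M2 - M1).
#'
#' @param m1_scores,m2_scores Per-cell numeric scores (length >= 3; M1
#'   scores must vary).
#' @return List with `slope`, `intercept`, `slope_ci` (length 2),
#'   `mean_diff`, and the `lm` fit.
#' @export
polarization_fit <- function(m1_scores, m2_scores) {
  if (inherits(m1_scores, "SignatureScore")) m1_scores <- m1_scores$score
  if (inherits(m2_scores, "SignatureScore")) m2_scores <- m2_scores$score
  stopifnot(length(m1_scores) == length(m2_scores))
  if (length(m1_scores) < 3L)
    stop("need >= 3 cells for the polarization fit", call. = FALSE)
  if (stats::var(m1_scores) == 0)
    stop("M1 scores are constant; slope undefined", call. = FALSE)
  fit <- stats::lm(m2_scores ~ m1_scores)
  ci <- stats::confint(fit)["m1_scores", ]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       slope_ci = unname(ci),
       mean_diff = mean(m2_scores - m1_scores),
       fit = fit)
}

#' Overlap of a signature with reference gene sets
#'
#' @param sig A [signature_set()] or character vector.
#' @param refs Named list of reference gene sets (character vectors).
#' @return data.frame with `reference`, `n_overlap`, `genes`
#'   (comma-collapsed); attribute `pooled` holds the overlap with the union
#'   of all references.
#' @export
overlap_with_reference <- function(sig, refs) {
  genes <- if (inherits(sig, "SignatureSet")) sig$genes else unique(sig)
  rows <- lapply(names(refs), function(nm) {
    ov <- intersect(genes, refs[[nm]])
    data.frame(reference = nm, n_overlap = length(ov),
               genes = paste(ov, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- intersect(genes, unique(unlist(refs)))
  out
}
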