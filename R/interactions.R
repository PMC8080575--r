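#' Binarize expression calls
#'
#' A gene is called expressed in a cell iff E is strictly greater than
#' `threshold` (default 1, the confident-expression cutoff used for
#' ligand-receptor calls).
#'
#' @param em An [ExpressionMatrix()].
#' @param threshold Expression cutoff in E units (>= 0).
#' @return Logical gene x cell matrix.
#' @export
binarize_expression <- function(em, threshold = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"), threshold >= 0)
  em$values > threshold
}

#' Count ligand-receptor interactions between cell groups
#'
#' For each ligand-receptor pair (L, R) and ordered group direction
#' (sender g1 -> receiver g2), the intercellular count is the number of
#' ordered cell pairs (c1, c2) with c1 != c2, c1 in g1 expressing L and
#' c2 in g2 expressing R. The self-sufficient count per group is the
#' number of single cells expressing both L and R; such cells still
#' partner in intercellular counts with other cells.
#'
#' @param binary Logical gene x cell matrix from [binarize_expression()].
#' @param db A [pair_database()]. Pairs whose ligand or receptor is absent
#'   from the matrix are skipped and listed in the result.
#' @param groups Per-cell group labels (named by cell id or aligned with
#'   the matrix columns); every cell must be labeled.
#' @param threshold Threshold recorded in the tally metadata.
#' @return An `InteractionTally`: list with `intercellular` (long
#'   data.frame: ligand, receptor, sender, receiver, count),
#'   `self_sufficient` (ligand, receptor, group, count), `skipped_pairs`,
#'   `groups` (group sizes) and `threshold`.
#' @export
count_interactions <- function(binary, db, groups, threshold = 1) {
  stopifnot(is.matrix(binary), is.logical(binary))
  if (!is.null(names(groups)))
    groups <- groups[colnames(binary)]
  if (length(groups) != ncol(binary) || anyNA(groups) ||
      any(!nzchar(as.character(groups))))
    stop("every cell must carry a group label", call. = FALSE)
  groups <- as.character(groups)
  db <- as.data.frame(db)
  present <- db$ligand %in% rownames(binary) &
    db$receptor %in% rownames(binary)
  skipped <- db[!present, , drop = FALSE]
  db <- db[present, , drop = FALSE]
  if (!nrow(db))
    stop("no database pair has both genes in the matrix", call. = FALSE)

  glev <- sort(unique(groups))
  gmat <- vapply(glev, function(g) groups == g, logical(ncol(binary)))
  # expresser counts per gene x group
  n_expr <- binary %*% gmat                       # genes x groups
  lig <- db$ligand; rec <- db$receptor
  both <- binary[lig, , drop = FALSE] & binary[rec, , drop = FALSE]
  n_both <- both %*% gmat                         # pairs x groups

  inter <- expand.grid(pair = seq_len(nrow(db)),
                       sender = glev, receiver = glev,
                       stringsAsFactors = FALSE)
  cnt <- n_expr[lig, , drop = FALSE][cbind(inter$pair,
                                           match(inter$sender, glev))] *
    n_expr[rec, , drop = FALSE][cbind(inter$pair, match(inter$receiver, glev))]
  same <- inter$sender == inter$receiver
  cnt[same] <- cnt[same] -
    n_both[cbind(inter$pair[same], match(inter$sender[same], glev))]
  intercellular <- data.frame(
    ligand = lig[inter$pair], receptor = rec[inter$pair],
    sender = inter$sender, receiver = inter$receiver,
    count = as.integer(cnt), stringsAsFactors = FALSE)

  self_sufficient <- data.frame(
    ligand = rep(lig, times = length(glev)),
    receptor = rep(rec, times = length(glev)),
    group = rep(glev, each = nrow(db)),
    count = as.integer(n_both), stringsAsFactors = FALSE)

  structure(
    list(intercellular = intercellular, self_sufficient = self_sufficient,
         skipped_pairs = skipped,
         groups = table(groups), threshold = threshold),
    class = "InteractionTally")
}

#' @method print InteractionTally
#' @export
#' @noRd
print.InteractionTally <- function(x, ...) {
  cat(sprintf("InteractionTally: %d pairs x %d groups (threshold %g)\n",
              length(unique(paste(x$self_sufficient$ligand,
                                  x$self_sufficient$receptor))),
              length(x$groups), x$threshold))
  if (nrow(x$skipped_pairs))
    cat(nrow(x$skipped_pairs), "pair(s) skipped (gene absent)\n")
  invisible(x)
}

#' Top interaction pairs for one direction
#'
#' @param tally An `InteractionTally`.
#' @param sender,receiver Group labels defining the direction
#'   (sender -> receiver).
#' @param n Number of pairs to return (default 10); fewer if the tally has
#'   fewer pairs. Ties are broken by (ligand, receptor) lexicographic order.
#' @return data.frame of ligand, receptor, count, sorted by count
#'   descending.
#' @export
rank_top_pairs <- function(tally, sender, receiver, n = 10) {
  stopifnot(inherits(tally, "InteractionTally"), n >= 1)
  known <- names(tally$groups)
  if (!(sender %in% known) || !(receiver %in% known))
    stop("unknown direction; known groups: ", paste(known, collapse = ", "),
         call. = FALSE)
  d <- tally$intercellular
  d <- d[d$sender == sender & d$receiver == receiver, , drop = FALSE]
  d <- d[order(-d$count, d$ligand, d$receptor), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d[, c("ligand", "receptor", "count")], n)
}

#' Select salient genes by expression level and breadth
#'
#' Among a gene subset, returns the genes whose mean E across the supplied
#' cells strictly exceeds the `q` quantile of the subset's mean values
#' (type-7 linear interpolation) and whose fraction of expressing cells
#' (E > `expr_threshold`) strictly exceeds `min_frac`. Used to label the
#' strongly and commonly expressed interacting genes of a cell group.
#'
#' @param em An [ExpressionMatrix()], already restricted to the cell group
#'   of interest (or use `cells`).
#' @param genes Character vector of candidate gene ids (must be non-empty
#'   after intersection with the matrix).
#' @param q Quantile cutoff on mean expression in [0, 1].
#' @param min_frac Minimum expressing-cell fraction in [0, 1].
#' @param cells Optional cell ids to restrict to.
#' @param expr_threshold Expression call cutoff (default 1).
#' @return Character vector of salient gene ids.
#' @export
label_salient_genes <- function(em, genes, q, min_frac, cells = NULL,
                                expr_threshold = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            q >= 0, q <= 1, min_frac >= 0, min_frac <= 1)
  genes <- intersect(genes, em$gene_ids)
  if (!length(genes)) stop("empty gene subset", call. = FALSE)
  x <- em$values[genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  mean_e <- rowMeans(x)
  frac <- rowMeans(x > expr_threshold)
  cutoff <- stats::quantile(mean_e, q, type = 7, names = FALSE)
  genes[mean_e > cutoff & frac > min_frac]
}
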