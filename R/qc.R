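#' Filter unreliable cells and genes from an expression matrix
#'
#' Applies the two-stage quality filter used for full-length single-cell
#' data: cells expressing fewer than `min_genes` genes are removed first,
#' then genes expressed in fewer than `min_cells` of the retained cells are
#' removed. "Expressed" means E strictly greater than `expr_threshold`
#' (default 1, the confident-expression cutoff). The filter runs in a
#' single pass (cells, then genes) and is idempotent.
#'
#' @param em An [ExpressionMatrix()].
#' @param min_genes Minimum number of expressed genes for a cell to be kept
#'   (default 1000).
#' @param min_cells Minimum number of retained cells a gene must be
#'   expressed in to be kept (default 10; small cohorts may use 2).
#' @param expr_threshold Confident-expression cutoff in E units (default 1).
#' @return A list with `matrix` (the filtered [ExpressionMatrix()]) and
#'   `report` (a `QCReport`).
#' @export
filter_cells_genes <- function(em, min_genes = 1000, min_cells = 10,
                               expr_threshold = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (min_genes < 0 || min_cells < 0 || expr_threshold < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  expr <- em$values > expr_threshold
  keep_cells <- colSums(expr) >= min_genes
  keep_genes <- rowSums(expr[, keep_cells, drop = FALSE]) >= min_cells
  if (!any(keep_cells) || !any(keep_genes))
    stop("QC filter removed every cell or every gene; relax thresholds",
         call. = FALSE)
  out <- subset_expression(em, genes = which(keep_genes),
                           cells = which(keep_cells))
  report <- qc_report(
    cells_in = ncol(em$values), genes_in = nrow(em$values),
    cells_out = ncol(out$values), genes_out = nrow(out$values),
    removed_cell_ids = em$cell_ids[!keep_cells],
    removed_gene_ids = em$gene_ids[!keep_genes],
    thresholds = list(min_genes = min_genes, min_cells = min_cells,
                      expr_threshold = expr_threshold,
                      order = "cells_first_single_pass"))
  list(matrix = out, report = report)
}

qc_report <- function(cells_in, genes_in, cells_out, genes_out,
                      removed_cell_ids, removed_gene_ids, thresholds) {
  structure(
    list(cells_in = cells_in, cells_out = cells_out,
         genes_in = genes_in, genes_out = genes_out,
         removed_cell_ids = removed_cell_ids,
         removed_gene_ids = removed_gene_ids,
         thresholds = thresholds),
    class = "QCReport")
}

#' @method print QCReport
#' @export
#' @noRd
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: cells %d -> %d, genes %d -> %d\n",
              x$cells_in, x$cells_out, x$genes_in, x$genes_out))
  invisible(x)
}

#' Serialize a QCReport to JSON
#'
#' @param report A `QCReport`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "QCReport"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Quality-filter droplet-protocol cells on count statistics
#'
#' Keeps exactly the cells satisfying all three inclusive criteria:
#' `min_counts <= nCounts <= max_counts`,
#' `min_features <= nFeatures <= max_features`, and mitochondrial
#' percentage `<= max_mito_pct`. nFeatures counts genes with count > 0;
#' the mitochondrial percentage is 100 x (counts in `mito_gene_ids`) /
#' (total counts).
#'
#' @param counts Numeric gene x cell matrix of UMI counts with dimnames.
#' @param mito_gene_ids Character vector of mitochondrial gene ids; ids
#'   absent from the matrix are ignored, and an empty overlap triggers a
#'   warning (the mito criterion then passes trivially).
#' @param min_counts,max_counts Inclusive bounds on per-cell total counts
#'   (defaults 1000 and 150000).
#' @param min_features,max_features Inclusive bounds on per-cell detected
#'   gene numbers (defaults 200 and 10000).
#' @param max_mito_pct Inclusive upper bound on mitochondrial percentage
#'   (default 20).
#' @return A list with `counts` (filtered matrix) and `report` (`QCReport`;
#'   no genes are removed by this filter).
#' @export
filter_droplet_cells <- function(counts, mito_gene_ids = character(),
                                 min_counts = 1000, max_counts = 150000,
                                 min_features = 200, max_features = 10000,
                                 max_mito_pct = 20) {
  validate_nonneg_matrix(counts, "count")
  mito <- intersect(mito_gene_ids, rownames(counts))
  if (length(mito_gene_ids) && !length(mito))
    warning("none of `mito_gene_ids` found in the matrix; ",
            "mitochondrial criterion passes for every cell")
  n_counts <- colSums(counts)
  n_features <- colSums(counts > 0)
  mito_pct <- if (length(mito)) {
    100 * colSums(counts[mito, , drop = FALSE]) / pmax(n_counts, 1)
  } else rep(0, ncol(counts))
  keep <- n_counts >= min_counts & n_counts <= max_counts &
    n_features >= min_features & n_features <= max_features &
    mito_pct <= max_mito_pct
  report <- qc_report(
    cells_in = ncol(counts), genes_in = nrow(counts),
    cells_out = sum(keep), genes_out = nrow(counts),
    removed_cell_ids = colnames(counts)[!keep],
    removed_gene_ids = character(),
    thresholds = list(min_counts = min_counts, max_counts = max_counts,
                      min_features = min_features,
                      max_features = max_features,
                      max_mito_pct = max_mito_pct))
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Construct a marker rule for threshold-based cell typing
#'
#' A rule assigns its label to a cell when every clause holds. Clauses
#' compare a gene's E value to a threshold with `>`, `<` or `==`
#' (equality is tested as |E| < 1e-12 against a zero threshold, absorbing
#' float noise in "not detected" clauses).
#'
#' @param label Cell-type label the rule assigns.
#' @param genes Character vector of gene ids, one per clause.
#' @param comparators Character vector in `c(">", "<", "==")`.
#' @param thresholds Numeric thresholds in E units.
#' @return A `MarkerRule` object.
#' @examples
#' macrophage_rule <- marker_rule(
#'   "macrophage",
#'   genes = c("CD86", "MUC16", "EPCAM", "CD3D"),
#'   comparators = c(">", "<", "==", "=="),
#'   thresholds = c(2, 1.1, 0, 0))
#' @export
marker_rule <- function(label, genes, comparators, thresholds) {
  stopifnot(is.character(label), length(label) == 1L,
            length(genes) == length(comparators),
            length(genes) == length(thresholds))
  if (!all(comparators %in% c(">", "<", "==")))
    stop("comparators must be one of '>', '<', '=='", call. = FALSE)
  structure(list(label = label,
                 clauses = data.frame(gene = as.character(genes),
                                      comparator = comparators,
                                      threshold = as.numeric(thresholds),
                                      stringsAsFactors = FALSE)),
            class = "MarkerRule")
}

#' Call cell types from marker threshold rules
#'
#' Each cell is labeled with the unique rule whose clauses all hold;
#' cells matching zero or two-or-more rules are `"unassigned"` and the
#' ambiguous ones are flagged.
#'
#' @param em An [ExpressionMatrix()].
#' @param rules A list of [marker_rule()] objects.
#' @return A data.frame with `cell_id`, `label` and logical `ambiguous`.
#' @export
call_cell_types_by_markers <- function(em, rules) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (inherits(rules, "MarkerRule")) rules <- list(rules)
  need <- unique(unlist(lapply(rules, function(r) r$clauses$gene)))
  missing <- setdiff(need, em$gene_ids)
  if (length(missing))
    stop("marker rule gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  hits <- vapply(rules, function(r) {
    ok <- rep(TRUE, ncol(em$values))
    for (k in seq_len(nrow(r$clauses))) {
      e <- em$values[r$clauses$gene[k], ]
      th <- r$clauses$threshold[k]
      ok <- ok & switch(r$clauses$comparator[k],
                        ">" = e > th,
                        "<" = e < th,
                        "==" = abs(e - th) < 1e-12)
    }
    ok
  }, logical(ncol(em$values)))
  hits <- matrix(hits, ncol = length(rules))
  n_match <- rowSums(hits)
  labels <- rep("unassigned", ncol(em$values))
  one <- n_match == 1L
  labels[one] <- vapply(which(one), function(i) {
    rules[[which(hits[i, ])]]$label
  }, character(1L))
  data.frame(cell_id = em$cell_ids, label = labels,
             ambiguous = n_match >= 2L, stringsAsFactors = FALSE)
}
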