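#' ExpressionMatrix: a gene x cell matrix of log-scale expression values
#'
#' Lightweight container for transformed expression values E (log2 scale),
#' with unique gene and cell identifiers, per-cell metadata, and a tag
#' recording which normalization produced the values.
#'
#' @param values Numeric gene x cell matrix with unique rownames (gene ids)
#'   and colnames (cell or sample ids). All entries must be finite and
#'   non-negative.
#' @param transform One of `"tpm"`, `"pseudotpm"`, `"precomputed"`: the
#'   normalization that produced `values`.
#' @param cell_meta Optional data.frame of per-cell metadata with one row
#'   per column of `values`, in the same order. A `cell_id` column is added
#'   if absent. Defaults to a bare frame of cell ids.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_meta`, `transform`.
#' @export
ExpressionMatrix <- function(values,
                             transform = c("precomputed", "tpm", "pseudotpm"),
                             cell_meta = NULL) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and cell ids as colnames",
         call. = FALSE)
  check_ids_unique(rownames(values), "gene")
  check_ids_unique(colnames(values), "cell")
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "expression values must be finite and >= 0; first offender: gene '%s', cell '%s' (value %g)",
      rownames(values)[i[1L]], colnames(values)[i[2L]], values[bad[1L]]),
      call. = FALSE)
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(values),
                            stringsAsFactors = FALSE)
  } else {
    if (!is.data.frame(cell_meta) || nrow(cell_meta) != ncol(values))
      stop("`cell_meta` must be a data.frame with one row per cell",
           call. = FALSE)
    if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- colnames(values)
    if (!identical(as.character(cell_meta$cell_id), colnames(values)))
      stop("`cell_meta$cell_id` must match the matrix column names in order",
           call. = FALSE)
  }
  structure(
    list(values = values,
         gene_ids = rownames(values),
         cell_ids = colnames(values),
         cell_meta = cell_meta,
         transform = transform),
    class = "ExpressionMatrix")
}

check_ids_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  invisible(ids)
}

#' @method print ExpressionMatrix
#' @export
#' @noRd
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (transform: %s)\n",
              nrow(x$values), ncol(x$values), x$transform))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra))
    cat("cell_meta columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by genes and/or cells
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,cells Character vectors of ids (or logical/integer indices)
#'   to retain; `NULL` keeps everything.
#' @return A new `ExpressionMatrix`.
#' @export
subset_expression <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$values)) else cells
  v <- x$values[gi, ci, drop = FALSE]
  meta <- x$cell_meta[match(colnames(v), x$cell_meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  ExpressionMatrix(v, transform = x$transform, cell_meta = meta)
}

#' Log-normalize a TPM matrix
#'
#' Computes E = log2(TPM/10 + 1) elementwise, the transform used for
#' full-length (SMART-seq style) single-cell data where TPM inflation is
#' damped by the divisor 10.
#'
#' @param tpm Numeric gene x cell matrix of TPM values (finite, >= 0), with
#'   gene ids as rownames and cell ids as colnames.
#' @param cell_meta Optional per-cell metadata passed to [ExpressionMatrix()].
#' @return An [ExpressionMatrix()] with `transform = "tpm"`.
#' @examples
#' m <- matrix(c(0, 10, 70, 10), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' log_normalize_tpm(m)$values
#' @export
log_normalize_tpm <- function(tpm, cell_meta = NULL) {
  validate_nonneg_matrix(tpm, "TPM")
  ExpressionMatrix(log2(tpm / 10 + 1), transform = "tpm",
                   cell_meta = cell_meta)
}

#' Pseudo-TPM normalize a UMI count matrix
#'
#' Rescales each cell's UMI counts to a total of 10,000 (pseudo-TPM), then
#' computes E = log2(pseudoTPM + 1). This is the droplet-protocol analogue
#' of [log_normalize_tpm()].
#'
#' @param umi Numeric gene x cell matrix of UMI counts (finite, >= 0), with
#'   dimnames as in [log_normalize_tpm()]. Every cell must have a positive
#'   total count.
#' @param cell_meta Optional per-cell metadata.
#' @return An [ExpressionMatrix()] with `transform = "pseudotpm"`.
#' @export
pseudo_tpm_normalize <- function(umi, cell_meta = NULL) {
  validate_nonneg_matrix(umi, "UMI")
  tot <- colSums(umi)
  if (any(tot <= 0))
    stop("all-zero cell column(s): ",
         paste(utils::head(colnames(umi)[tot <= 0], 5L), collapse = ", "),
         call. = FALSE)
  pseudo <- sweep(umi, 2L, tot, "/") * 1e4
  ExpressionMatrix(log2(pseudo + 1), transform = "pseudotpm",
                   cell_meta = cell_meta)
}

validate_nonneg_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("%s input must be a numeric matrix", what), call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("%s matrix must have gene rownames and cell colnames", what),
         call. = FALSE)
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("%s values must be finite and >= 0; offender: gene '%s', cell '%s'",
                 what, rownames(m)[i[1L]], colnames(m)[i[2L]]), call. = FALSE)
  }
  invisible(m)
}
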