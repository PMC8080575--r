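#' Read a gene x cell expression/count matrix from TSV
#'
#' Expects genes as rows: first column gene ids, remaining columns one per
#' cell with cell ids in the header row.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene rownames and cell colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  check_ids_unique(genes, "gene")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a gene x cell matrix to TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the leading id column (default `"gene_id"`).
#' @export
write_expression_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket expression matrix with label files
#'
#' Reads a triplet `.mtx` file plus `genes.tsv` and `cells.tsv` label files
#' (one id per line, first column used) from the same directory.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param genes_path,cells_path Label file paths; default to `genes.tsv` and
#'   `cells.tsv` next to `mtx_path`.
#' @return Dense numeric matrix with gene rownames and cell colnames.
#' @export
read_expression_mtx <- function(mtx_path,
                                genes_path = file.path(dirname(mtx_path), "genes.tsv"),
                                cells_path = file.path(dirname(mtx_path), "cells.tsv")) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.delim(cells_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("label files do not match matrix dimensions", call. = FALSE)
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as MatrixMarket triplets with label files
#'
#' @param m Matrix with dimnames.
#' @param dir Output directory (created if missing); writes `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @export
write_expression_mtx <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `gene_id`, `chrom`, `start` (1-based). For CEP
#' analysis chromosomes are the autosomes 1..22; entries on other
#' chromosomes are allowed here and dropped by [zscore_clip()].
#'
#' @param path Path to a TSV with a header row.
#' @return data.frame with character `gene_id`, character `chrom`,
#'   integer `start`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "start") %in% names(df)))
    stop("annotation needs columns gene_id, chrom, start", call. = FALSE)
  gene_annotation(df$gene_id, df$chrom, df$start)
}

#' Construct a gene annotation table
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chrom Chromosome labels (`"1"`..`"22"` for autosomes; `"chr"`
#'   prefixes are stripped).
#' @param start 1-based start coordinates.
#' @return data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start) {
  gene_id <- as.character(gene_id)
  check_ids_unique(gene_id, "annotation gene")
  chrom <- sub("^chr", "", as.character(chrom))
  start <- as.integer(start)
  if (any(is.na(start) | start < 1))
    stop("annotation starts must be positive integers", call. = FALSE)
  structure(data.frame(gene_id = gene_id, chrom = chrom, start = start,
                       stringsAsFactors = FALSE),
            class = c("GeneAnnotation", "data.frame"))
}

#' Read a ligand-receptor pair database
#'
#' TSV with header columns `ligand`, `receptor`, `source` (source optional,
#' defaults to `"custom"`). Duplicate (ligand, receptor) pairs are collapsed
#' to one entry, keeping the first source tag.
#'
#' @param path Path to the TSV.
#' @return data.frame of class `PairDatabase` with columns `ligand`,
#'   `receptor`, `source`.
#' @export
read_pair_db <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("pair table needs columns ligand, receptor", call. = FALSE)
  pair_database(df$ligand, df$receptor,
                if ("source" %in% names(df)) df$source else "custom")
}

#' Construct a ligand-receptor pair database
#'
#' @param ligand,receptor Character vectors of gene ids.
#' @param source Source tag per pair (e.g. `"fantom5"`, `"cytokine_supp"`).
#' @return data.frame of class `PairDatabase`; duplicates removed.
#' @export
pair_database <- function(ligand, receptor, source = "custom") {
  ligand <- as.character(ligand); receptor <- as.character(receptor)
  if (any(!nzchar(ligand)) || any(!nzchar(receptor)))
    stop("ligand/receptor gene ids must be non-empty", call. = FALSE)
  df <- data.frame(ligand = ligand, receptor = receptor,
                   source = rep_len(as.character(source), length(ligand)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("ligand", "receptor")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PairDatabase", "data.frame"))
}

#' Merge pair databases
#'
#' @param ... `PairDatabase` objects; the union is returned with duplicate
#'   (ligand, receptor) pairs counted once.
#' @return A `PairDatabase`.
#' @export
merge_pair_dbs <- function(...) {
  dfs <- lapply(list(...), as.data.frame)
  all <- do.call(rbind, dfs)
  pair_database(all$ligand, all$receptor, all$source)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then gene ids,
#'   tab separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "asceco") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bulk survival cohort
#'
#' @param expression_path TSV of gene x sample expression (see
#'   [read_expression_tsv()]); values are E units (log2(TPM/10+1)) unless
#'   `transform` says otherwise.
#' @param clinical_path TSV with columns `sample_id`, `os_days`,
#'   `os_event` (1 = death) and optional `stage`.
#' @param cohort Cohort tag (e.g. `"STAD"`).
#' @param transform Passed to [ExpressionMatrix()].
#' @return A [survival_cohort()].
#' @export
read_cohort <- function(expression_path, clinical_path, cohort = "cohort",
                        transform = "precomputed") {
  expr <- read_expression_tsv(expression_path)
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  survival_cohort(expr, clin, cohort = cohort, transform = transform)
}

#' Construct a bulk survival cohort
#'
#' @param expression Gene x sample numeric matrix in E units.
#' @param clinical data.frame with `sample_id`, `os_days` (> 0), `os_event`
#'   in \{0, 1\}, optional `stage`; one row per expression column.
#' @param cohort Cohort tag.
#' @param transform Provenance of the expression values.
#' @return Object of class `SurvivalCohort`: list with `expression`
#'   ([ExpressionMatrix()]) and `clinical`.
#' @export
survival_cohort <- function(expression, clinical, cohort = "cohort",
                            transform = "precomputed") {
  if (!all(c("sample_id", "os_days", "os_event") %in% names(clinical)))
    stop("clinical table needs sample_id, os_days, os_event", call. = FALSE)
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ,
                       drop = FALSE]
  if (anyNA(clinical$sample_id))
    stop("clinical table missing samples present in the expression matrix",
         call. = FALSE)
  if (any(clinical$os_days <= 0))
    stop("survival times must be > 0", call. = FALSE)
  if (!all(clinical$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1", call. = FALSE)
  rownames(clinical) <- NULL
  meta <- data.frame(cell_id = colnames(expression), clinical[-1L],
                     stringsAsFactors = FALSE)
  structure(
    list(expression = ExpressionMatrix(expression, transform = transform,
                                       cell_meta = meta),
         clinical = clinical, cohort = cohort),
    class = "SurvivalCohort")
}

#' @method print SurvivalCohort
#' @export
#' @noRd
print.SurvivalCohort <- function(x, ...) {
  cat(sprintf("SurvivalCohort '%s': %d samples x %d genes, %d events\n",
              x$cohort, nrow(x$clinical), nrow(x$expression$values),
              sum(x$clinical$os_event)))
  invisible(x)
}
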