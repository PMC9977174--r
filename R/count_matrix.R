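#' Construct a validated gene-by-unit count matrix
#'
#' The package's common container for expression counts is a sparse
#' `Matrix::dgCMatrix` with genes in rows and units (cells or spots) in
#' columns, identified by unique dimnames. This constructor coerces a
#' dense or sparse matrix, attaches identifiers and enforces the
#' invariants: non-negative integral entries, unique gene and unit ids,
#' dimensions matching the id vectors.
#'
#' @param values Matrix-like object of counts, genes x units.
#' @param gene_ids Character vector of gene identifiers (default: rownames).
#' @param unit_ids Character vector of cell/spot identifiers (default:
#'   colnames).
#' @return A `dgCMatrix` with validated dimnames.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         unit_ids = colnames(values)) {
  x <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(unit_ids)) {
    stop("gene and unit identifiers are required (dimnames or arguments)")
  }
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (length(gene_ids) != nrow(x) || length(unit_ids) != ncol(x)) {
    stop("identifier lengths must match matrix dimensions")
  }
  dimnames(x) <- list(gene_ids, unit_ids)
  assert_count_matrix(x)
  x
}

#' Validate count-matrix invariants
#'
#' Checks that `x` is a numeric matrix (dense or sparse) of non-negative
#' integral values with unique, non-missing gene and unit identifiers.
#' Called internally by every function that consumes counts.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly.
#' @export
assert_count_matrix <- function(x) {
  vals <- if (methods::is(x, "sparseMatrix")) x@x else as.vector(x)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("counts must be non-negative integers")
  }
  gid <- rownames(x); uid <- colnames(x)
  if (is.null(gid) || is.null(uid) || anyNA(gid) || anyNA(uid)) {
    stop("counts must carry gene and unit identifiers as dimnames")
  }
  if (anyDuplicated(gid)) stop("gene identifiers must be unique")
  if (anyDuplicated(uid)) stop("unit identifiers must be unique")
  invisible(x)
}

dense_counts <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Read a count matrix from disk
#'
#' Supports the two on-disk layouts used by the package: Matrix Market
#' sparse triplets (`.mtx`, with companion one-column gene and unit id
#' files) and dense delimited text (`.csv`/`.tsv`, first column = gene id,
#' header = unit ids). Gzip-compressed files (`.gz`) are read
#' transparently.
#'
#' @param path Path to the matrix file.
#' @param gene_file,unit_file Companion identifier files (required for
#'   MTX input; one id per line, extra tab-separated columns ignored).
#' @return A validated sparse count matrix, genes x units.
#' @export
read_counts <- function(path, gene_file = NULL, unit_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.mtx$", base)) {
    if (is.null(gene_file) || is.null(unit_file)) {
      stop("MTX input requires `gene_file` and `unit_file`")
    }
    m <- Matrix::readMM(path)
    genes <- utils::read.table(gene_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    units <- utils::read.table(unit_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    count_matrix(m, gene_ids = genes, unit_ids = units)
  } else {
    sep <- if (grepl("\\.tsv$|\\.txt$", base)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    count_matrix(m, gene_ids = genes, unit_ids = colnames(m))
  }
}

#' Write a count matrix to disk
#'
#' @param x Count matrix (genes x units).
#' @param path Output path; `.mtx` writes Matrix Market plus
#'   `<prefix>.genes.tsv` / `<prefix>.units.tsv`, `.csv`/`.tsv` writes a
#'   dense table with gene ids in the first column.
#' @return Character vector of files written, invisibly.
#' @export
write_counts <- function(x, path) {
  assert_count_matrix(x)
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.mtx$", base)) {
    Matrix::writeMM(methods::as(x, "generalMatrix"), path)
    prefix <- sub("\\.mtx$", "", base)
    gf <- paste0(prefix, ".genes.tsv")
    uf <- paste0(prefix, ".units.tsv")
    writeLines(rownames(x), gf)
    writeLines(colnames(x), uf)
    invisible(c(path, gf, uf))
  } else {
    sep <- if (grepl("\\.tsv$|\\.txt$", base)) "\t" else ","
    df <- data.frame(gene = rownames(x), as.matrix(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
  }
}

#' Read per-unit labels from a two-column CSV
#'
#' Expects a header row and two columns: unit identifier and label
#' (cell type or layer).
#'
#' @param path CSV path (gzip transparent).
#' @return Named character vector, names = unit ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file must have two columns (unit, label)")
  out <- as.character(df[[2]])
  names(out) <- as.character(df[[1]])
  if (anyDuplicated(names(out))) stop("duplicate unit ids in label file")
  out
}

#' Write per-unit labels as a two-column CSV
#'
#' @param labels Named vector (names = unit ids).
#' @param path Output CSV path.
#' @param label_name Column name for the label column.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, label_name = "label") {
  df <- data.frame(unit_id = names(labels), lab = as.character(labels),
                   stringsAsFactors = FALSE)
  names(df)[2] <- label_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
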