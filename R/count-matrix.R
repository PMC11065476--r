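#' Single-cell count matrix container
#'
#' Thin wrapper around a features-by-cells matrix (dense or sparse) with an
#' omic tag. Cells need not match across omics: unpaired scRNA / scATAC /
#' methylation data are supported throughout, since each layer is inferred
#' from its own omic independently.
#'
#' @param counts Numeric matrix or `Matrix::dgCMatrix`, features in rows
#'   (rownames = feature ids), cells in columns (colnames = cell ids). All
#'   entries must be finite and non-negative.
#' @param omic One of `"rna"`, `"atac"`, `"methylation"`, `"other"`.
#' @return Object of class `scrw_counts`.
#' @export
count_matrix <- function(counts, omic = c("rna", "atac", "methylation", "other")) {
  omic <- match.arg(omic)
  stopifnot(is.matrix(counts) || is(counts, "Matrix"))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count_matrix: counts must have feature rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("count_matrix: duplicated feature or cell ids")
  }
  v <- if (is(counts, "Matrix")) counts@x else counts
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("count_matrix: counts must be finite and non-negative")
  }
  structure(list(counts = counts, omic = omic), class = "scrw_counts")
}

#' @export
print.scrw_counts <- function(x, ...) {
  cat(sprintf("<count matrix [%s]> %d features x %d cells\n", x$omic,
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.scrw_counts <- function(x) dim(x$counts)

features <- function(x) rownames(x$counts)
cells <- function(x) colnames(x$counts)

#' Read a count matrix from MatrixMarket or dense TSV
#'
#' The MTX route expects the usual sidecar files: `features.tsv` (feature
#' ids, first column used) and `barcodes.tsv` next to the matrix, or passed
#' explicitly. The TSV route expects features in rows (first column =
#' feature id, header row = cell ids).
#'
#' @param path Path to the `.mtx` or `.tsv` file.
#' @param format `"mtx"` or `"tsv"` (default: guessed from the extension).
#' @param omic Omic tag, see [count_matrix()].
#' @param features_path,barcodes_path Sidecar paths for MTX (defaults:
#'   `features.tsv` / `barcodes.tsv` in the matrix directory).
#' @return An `scrw_counts`.
#' @export
read_count_matrix <- function(path, format = NULL,
                              omic = c("rna", "atac", "methylation", "other"),
                              features_path = NULL, barcodes_path = NULL) {
  omic <- match.arg(omic)
  format <- format %||%
    (if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv")
  if (format == "mtx") {
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    features_path <- features_path %||% file.path(dirname(path), "features.tsv")
    barcodes_path <- barcodes_path %||% file.path(dirname(path), "barcodes.tsv")
    feats <- readr::read_tsv(features_path, col_names = FALSE,
                             col_types = readr::cols(.default = "c"))[[1]]
    cells <- readr::read_tsv(barcodes_path, col_names = FALSE,
                             col_types = readr::cols(.default = "c"))[[1]]
    if (length(feats) != nrow(m)) {
      abort(sprintf("read_count_matrix: features sidecar has %d ids but matrix has %d rows",
                    length(feats), nrow(m)))
    }
    if (length(cells) != ncol(m)) {
      abort(sprintf("read_count_matrix: barcodes sidecar has %d ids but matrix has %d columns",
                    length(cells), ncol(m)))
    }
    dimnames(m) <- list(feats, cells)
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.character(tb[[1]])
    m <- as.matrix(tb[-1])
    rownames(m) <- ids
  }
  count_matrix(m, omic = omic)
}

#' Write a count matrix
#'
#' `format = "mtx"` writes the matrix plus `features.tsv`/`barcodes.tsv`
#' sidecars; `format = "tsv"` writes a dense features-by-cells table.
#'
#' @param x An `scrw_counts`.
#' @param path Output path (`.mtx` or `.tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(as(as(x$counts, "dMatrix"), "CsparseMatrix"), path)
    dir <- dirname(path)
    readr::write_tsv(tibble(id = features(x)),
                     file.path(dir, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble(id = cells(x)),
                     file.path(dir, "barcodes.tsv"), col_names = FALSE)
  } else {
    tb <- as_tibble(as.matrix(x$counts), rownames = "feature")
    readr::write_tsv(tb, path)
  }
  invisible(path)
}
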