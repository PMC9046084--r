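# ---- readers / writers for the standard exchange formats ----------------
#
# Sparse single-cell counts travel as MatrixMarket (genes x cells) plus
# one-column gene and barcode files, the 10x convention; dense matrices as
# TSV/CSV with a header row of gene ids; labels as two-column CSV
# (cell_id, label).

#' Read a sparse single-cell count matrix (MatrixMarket)
#'
#' @param mtx_file MatrixMarket file, genes as rows and cells as columns.
#' @param genes_file One gene id per line.
#' @param barcodes_file One cell id per line.
#' @return Dense cells x genes matrix with ids.
#' @export
read_counts_mtx <- function(mtx_file, genes_file, barcodes_file) {
  m <- Matrix::readMM(mtx_file)
  genes <- readLines(genes_file)
  cells <- readLines(barcodes_file)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("matrix dimensions do not match gene/barcode files")
  }
  out <- t(as.matrix(m))
  dimnames(out) <- list(cells, genes)
  out
}

#' Write a sparse single-cell count matrix (MatrixMarket)
#'
#' @param counts Cells x genes matrix.
#' @param dir Output directory; writes `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return Invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense expression matrix from TSV/CSV
#'
#' The header row holds gene ids; the first column holds row (sample or
#' cell) ids.
#'
#' @param file Path; delimiter inferred from the extension (`.csv` comma,
#'   otherwise tab).
#' @return Numeric matrix with ids.
#' @export
read_dense_matrix <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a matrix as CSV with a gene header
#'
#' @param x Matrix (e.g. profiles, fractions) with dimnames.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_matrix_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = TRUE)
  invisible(file)
}

#' Read a matrix written by [write_matrix_csv()]
#'
#' @param file CSV path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(file) {
  as.matrix(utils::read.csv(file, row.names = 1L, check.names = FALSE))
}

#' Read a two-column label file
#'
#' @param file CSV with columns `cell_id` and a label column (second
#'   column used).
#' @return Named character vector (names = cell ids).
#' @export
read_labels <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns (cell_id, label)")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a two-column label file
#'
#' @param labels Named character vector (names = cell ids).
#' @param file Output CSV path.
#' @return Invisibly, the path.
#' @export
write_labels <- function(labels, file) {
  utils::write.csv(
    data.frame(cell_id = names(labels), label = unname(labels),
               stringsAsFactors = FALSE),
    file, row.names = FALSE)
  invisible(file)
}
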