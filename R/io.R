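# Readers and writers for the supported on-disk formats: delimited text
# (comma/tab autodetected, orientation flag) and MatrixMarket triplets with
# companion gene/barcode lists. All matrices are handled cells x genes in
# memory.

#' Read a count matrix
#'
#' Delimited text (separator autodetected between tab and comma, first row
#' and column treated as identifiers) or MatrixMarket \code{.mtx} with
#' companion gene and barcode files (10x convention: genes in rows,
#' barcodes in columns; transposed to cells x genes on read).
#'
#' @param path matrix file (\code{.mtx} triggers MatrixMarket mode)
#' @param cellsInRows for delimited input, whether rows are cells
#' @param genesFile,barcodesFile companion identifier files for
#'   MatrixMarket input; default to \code{genes.tsv}/\code{barcodes.tsv}
#'   next to the matrix
#' @return cells x genes numeric matrix with identifiers as dimnames
#' @export
readCountMatrix <- function(path, cellsInRows = TRUE, genesFile = NULL,
                            barcodesFile = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    dir <- dirname(path)
    if (is.null(genesFile)) genesFile <- file.path(dir, "genes.tsv")
    if (is.null(barcodesFile)) barcodesFile <- file.path(dir, "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesFile)
    cells <- readLines(barcodesFile)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("matrix dimensions do not match gene/barcode lists")
    dimnames(m) <- list(genes, cells)
    return(t(m))
  }
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!cellsInRows) m <- t(m)
  m
}

#' Write a count (or expression) matrix as delimited text, cells x genes
#'
#' @param X cells x genes matrix
#' @param path output file
#' @param sep field separator (default tab)
#' @export
writeCountMatrix <- function(X, path, sep = "\t") {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("gene_", seq_len(ncol(X)))
  utils::write.table(data.frame(cell_id = rownames(X), X,
                                check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated counts as MatrixMarket with companion id lists
#'
#' @param X cells x genes matrix
#' @param dir output directory (created if needed); writes
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv} in the 10x
#'   genes-in-rows convention
#' @export
writeCountMatrixMM <- function(X, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  X <- .as_count_matrix(X)
  Matrix::writeMM(Matrix::Matrix(t(X), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(X), file.path(dir, "genes.tsv"))
  writeLines(rownames(X), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a label file
#'
#' One label per cell: either a single column, or two columns
#' (cell identifier, label) with an optional header.
#'
#' @param path label file
#' @return vector of labels, named when cell identifiers are present
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = grepl("cell|label|cluster", first,
                                               ignore.case = TRUE),
                          sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) >= 2L) stats::setNames(df[[2L]], df[[1L]]) else df[[1L]]
}

#' Write cluster labels as two-column delimited text
#'
#' @param labels vector of labels, named by cell identifier (unnamed labels
#'   get positional identifiers)
#' @param path output file
#' @export
writeLabels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("cell_", seq_along(labels))
  utils::write.table(data.frame(cell_id = ids, cluster = as.vector(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
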