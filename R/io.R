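#' Read a MatrixMarket count matrix with gene / barcode sidecar files
#'
#' Reads the standard MTX triplet (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`)
#' layout. The MTX is expected genes x cells (rows = genes), as written by
#' common pipelines; set `transpose = TRUE` if cells are rows.
#'
#' @param dir Directory containing the three files, or explicit paths via the
#'   other arguments.
#' @param mtx,genes,barcodes File names within `dir`.
#' @param transpose If `TRUE`, the stored matrix is cells x genes.
#' @param ... Passed to [CellScoutSet()] (`colData`, `batchLevels`, ...).
#' @return A [CellScoutSet].
#' @export
readMTXSet <- function(dir, mtx = "matrix.mtx", genes = "genes.tsv",
                       barcodes = "barcodes.tsv", transpose = FALSE, ...) {
  m <- Matrix::readMM(file.path(dir, mtx))
  g <- read.table(file.path(dir, genes), header = FALSE,
                  stringsAsFactors = FALSE)[[1]]
  b <- read.table(file.path(dir, barcodes), header = FALSE,
                  stringsAsFactors = FALSE)[[1]]
  if (transpose) m <- Matrix::t(m)
  if (nrow(m) != length(g))
    stop("gene file length (", length(g), ") != matrix rows (", nrow(m), ")")
  if (ncol(m) != length(b))
    stop("barcode file length (", length(b), ") != matrix cols (", ncol(m), ")")
  dimnames(m) <- list(g, b)
  CellScoutSet(methods::as(m, "CsparseMatrix"), ...)
}

#' Write a CellScoutSet as MatrixMarket triplet files
#'
#' @param x A [CellScoutSet].
#' @param dir Output directory (created if needed). Also writes
#'   `metadata.csv` with the colData.
#' @return `dir`, invisibly.
#' @export
writeMTXSet <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cts <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(methods::as(methods::as(cts, "sparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (ncol(cd))
    write.csv(cd, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Read a dense CSV/TSV count table
#'
#' Header row holds gene names; first column holds cell ids (cells as rows),
#' i.e. the transpose of the internal genes x cells layout.
#'
#' @param path CSV or TSV file path (delimiter inferred from the extension).
#' @param ... Passed to [CellScoutSet()].
#' @return A [CellScoutSet].
#' @export
readDenseSet <- function(path, ...) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- t(as.matrix(df))  # to genes x cells
  CellScoutSet(m, ...)
}
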