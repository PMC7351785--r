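#' Library-size input normalization
#'
#' Rescales each cell's raw counts to a common total of 1e4, using all genes
#' in the denominator (not only the selected subset, which would skew the
#' scale). This is the transform applied to encoder inputs.
#'
#' @param x A numeric vector of raw counts over all genes, or a genes x cells
#'   matrix (each column a cell).
#' @return Same shape as `x`, each cell summing to 1e4.
#' @examples
#' normalizeInput(c(1, 1, 2))  # 2500 2500 5000
#' @export
normalizeInput <- function(x) {
  if (is.matrix(x) || methods::is(x, "Matrix")) {
    tot <- Matrix::colSums(x)
    zero <- which(tot == 0)
    if (length(zero))
      stop("all-zero cell(s), cannot normalize: ",
           paste(head(colnamesOrIdx(x, zero), 5), collapse = ", "))
    sweepCols(x, 1e4 / tot)
  } else {
    tot <- sum(x)
    if (tot == 0) stop("all-zero cell, cannot normalize")
    1e4 * x / tot
  }
}

colnamesOrIdx <- function(x, idx) {
  cn <- colnames(x)
  if (is.null(cn)) as.character(idx) else cn[idx]
}

sweepCols <- function(x, fac) {
  if (methods::is(x, "sparseMatrix")) {
    x %*% Matrix::Diagonal(x = fac)
  } else {
    sweep(x, 2, fac, "*")
  }
}

#' Size factor over the selected genes
#'
#' The size factor s of a cell is the sum of its raw counts over the selected
#' (informative) gene subset. It is fed to the decoder so that sequencing
#' depth is decoupled from the embedding.
#'
#' @param x Numeric vector over genes, or genes x cells matrix.
#' @param genes Character or integer index of the selected genes (rows).
#' @return Numeric scalar (vector input) or per-cell numeric vector.
#' @export
sizeFactor <- function(x, genes) {
  if (length(genes) == 0) stop("selected gene set is empty")
  if (is.matrix(x) || methods::is(x, "Matrix")) {
    as.numeric(Matrix::colSums(x[genes, , drop = FALSE]))
  } else {
    sum(x[genes])
  }
}
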