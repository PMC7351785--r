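#' CellScoutSet: raw counts with batch design and annotations
#'
#' `CellScoutSet` extends
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' with the conventions the rest of the package relies on: a `"counts"` assay
#' of nonnegative values (genes as rows, cells as columns; sparse
#' [Matrix::dgCMatrix] preserved), unique gene and cell names, a logical
#' `rowData` column `selected` marking the informative-gene subset, and a set
#' of `colData` columns registered as categorical batch levels (e.g. donor,
#' dataset). Optional per-cell annotations (discrete labels, ontology term
#' IDs, continuous probability vectors) are ordinary `colData` columns.
#'
#' @param counts Matrix-like, genes x cells, nonnegative, with unique
#'   rownames (genes) and colnames (cells).
#' @param colData Optional data.frame / DataFrame of per-cell metadata.
#' @param batchLevels Character vector naming `colData` columns that encode
#'   batch membership; each is coerced to a factor.
#' @param selectedGenes Optional character vector (subset of rownames) of
#'   informative genes.
#'
#' @return A `CellScoutSet` object.
#' @examples
#' m <- matrix(rpois(60, 3), nrow = 6,
#'             dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
#' cs <- CellScoutSet(m, colData = data.frame(donor = rep(c("a", "b"), 5)),
#'                    batchLevels = "donor")
#' selectedGenes(cs) <- c("g1", "g3")
#' @export
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
setClass("CellScoutSet", contains = "SingleCellExperiment")

.validCellScoutSet <- function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (min0(cts) < 0) msg <- c(msg, "counts must be nonnegative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell ids must be present and unique")
  sel <- SummarizedExperiment::rowData(object)$selected
  if (!is.null(sel) && !is.logical(sel))
    msg <- c(msg, "rowData column 'selected' must be logical")
  bl <- S4Vectors::metadata(object)$batchLevels
  if (!is.null(bl)) {
    missing <- setdiff(bl, colnames(SummarizedExperiment::colData(object)))
    if (length(missing))
      msg <- c(msg, paste0("batch level(s) not in colData: ",
                           paste(missing, collapse = ", ")))
    for (lv in intersect(bl, colnames(SummarizedExperiment::colData(object)))) {
      v <- SummarizedExperiment::colData(object)[[lv]]
      if (anyNA(v))
        msg <- c(msg, paste0("batch level '", lv, "' has missing assignments"))
    }
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("CellScoutSet", .validCellScoutSet)

# minimum that works for both dense and dgCMatrix without densifying
min0 <- function(m) {
  if (methods::is(m, "sparseMatrix")) min(0, min(m@x, na.rm = TRUE))
  else min(m)
}

#' @rdname CellScoutSet-class
#' @export
CellScoutSet <- function(counts, colData = NULL, batchLevels = character(0),
                         selectedGenes = NULL) {
  if (is.null(rownames(counts)))
    stop("counts must have rownames (gene names)")
  if (is.null(colnames(counts)))
    stop("counts must have colnames (cell ids)")
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(counts))
  colData <- S4Vectors::DataFrame(colData, row.names = colnames(counts))
  for (lv in batchLevels) {
    if (!lv %in% colnames(colData))
      stop("batch level '", lv, "' not found in colData")
    colData[[lv]] <- factor(colData[[lv]])
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = colData)
  SummarizedExperiment::rowData(sce)$selected <-
    if (is.null(selectedGenes)) rep(FALSE, nrow(sce))
    else rownames(sce) %in% selectedGenes
  S4Vectors::metadata(sce)$batchLevels <- as.character(batchLevels)
  methods::new("CellScoutSet", sce)
}

#' @rdname accessors
#' @export
setMethod("selectedGenes", "CellScoutSet", function(x) {
  rownames(x)[SummarizedExperiment::rowData(x)$selected]
})

#' @rdname accessors
#' @export
setReplaceMethod("selectedGenes", "CellScoutSet", function(x, value) {
  bad <- setdiff(value, rownames(x))
  if (length(bad))
    stop("selected genes not present: ", paste(head(bad, 5), collapse = ", "))
  SummarizedExperiment::rowData(x)$selected <- rownames(x) %in% value
  methods::validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("batchLevels", "CellScoutSet", function(x) {
  as.character(S4Vectors::metadata(x)$batchLevels)
})

#' @rdname accessors
#' @export
setReplaceMethod("batchLevels", "CellScoutSet", function(x, value) {
  S4Vectors::metadata(x)$batchLevels <- as.character(value)
  methods::validObject(x)
  x
})

#' One-hot batch design for one batch level
#'
#' Returns the cells x B indicator matrix for a registered batch level, plus
#' the relative batch proportions w (which sum to 1).
#'
#' @param x A [CellScoutSet].
#' @param level Name of a registered batch level.
#' @return A list with `onehot` (cells x B binary matrix), `weights`
#'   (named numeric, sums to 1) and `levels`.
#' @export
batchOneHot <- function(x, level) {
  if (!level %in% batchLevels(x))
    stop("'", level, "' is not a registered batch level")
  f <- factor(SummarizedExperiment::colData(x)[[level]])
  oh <- matrix(0L, ncol(x), nlevels(f),
               dimnames = list(colnames(x), levels(f)))
  oh[cbind(seq_along(f), as.integer(f))] <- 1L
  w <- as.numeric(table(f)) / length(f)
  names(w) <- levels(f)
  list(onehot = oh, weights = w, levels = levels(f))
}

setMethod("show", "CellScoutSet", function(object) {
  methods::callNextMethod()
  cat("selectedGenes(", sum(SummarizedExperiment::rowData(object)$selected),
      "): ", paste(head(selectedGenes(object), 4), collapse = " "),
      if (length(selectedGenes(object)) > 4) "..." else "", "\n", sep = "")
  cat("batchLevels(", length(batchLevels(object)), "): ",
      paste(batchLevels(object), collapse = " "), "\n", sep = "")
})
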