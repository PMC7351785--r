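#' @import methods
#' @importFrom stats rnorm rpois rnbinom rgamma runif var sd quantile setNames
#' @importFrom utils read.table write.table read.csv write.csv head
NULL

#' Accessor generics for CellScout classes
#'
#' `selectedGenes()` returns the ordered informative-gene subset of a
#' [CellScoutSet] (or the gene contract of a [CellScoutModel]);
#' `batchLevels()` returns the names of the batch levels (colData columns
#' treated as categorical batch assignments, e.g. donor or dataset).
#'
#' @param x A `CellScoutSet` or `CellScoutModel`.
#' @param value Replacement value.
#' @return `selectedGenes`: a character vector of gene names;
#'   `batchLevels`: a character vector of batch-level names.
#' @name accessors
#' @aliases selectedGenes batchLevels selectedGenes<- batchLevels<-
NULL

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setGeneric("selectedGenes<-", function(x, value) standardGeneric("selectedGenes<-"))

#' @rdname accessors
#' @export
setGeneric("batchLevels", function(x) standardGeneric("batchLevels"))

#' @rdname accessors
#' @export
setGeneric("batchLevels<-", function(x, value) standardGeneric("batchLevels<-"))
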