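#' Encoder gradient along an embedding deviation
#'
#' Backpropagates a unit-normalized embedding-space deviation through the
#' encoder to gene space: returns `t(dl/dx~) %*% unit(hitEmbedding -
#' queryEmbedding)`, evaluated on the cell's deterministic encoding path
#' (normalized input, no Poisson perturbation), with the log1p input
#' transform's chain rule included. The result is one value per model gene:
#' genes whose increased expression moves the cell's embedding along the
#' deviation direction.
#'
#' @param model A [CellScoutModel].
#' @param x Raw counts for the cell: a named vector over genes, or a genes x
#'   cells matrix / [CellScoutSet] with `cell` selecting the column.
#' @param queryEmbedding,hitEmbedding Length-D embedding vectors; the
#'   deviation is `hitEmbedding - queryEmbedding` and must be nonzero.
#' @param cell Column index/id when `x` holds several cells.
#' @param space `"log"` (default): gradient with respect to the encoder's
#'   log1p-transformed input, so gene importance is comparable across
#'   expression levels; `"raw"`: chain rule through log1p included, gradient
#'   with respect to the normalized count vector (which down-weights genes
#'   the cell already expresses highly by 1/(1+x)).
#' @return Named numeric vector over the model's genes.
#' @export
deviationGradient <- function(model, x, queryEmbedding, hitEmbedding,
                              cell = 1, space = c("log", "raw")) {
  space <- match.arg(space)
  delta <- hitEmbedding - queryEmbedding
  nd <- sqrt(sum(delta^2))
  if (nd == 0) stop("zero embedding deviation: direction undefined")
  delta <- delta / nd
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1,
                                                    dimnames = list(names(x), "cell"))
  if (methods::is(x, "CellScoutSet"))
    x <- SummarizedExperiment::assay(x, "counts")
  prep <- prepEncoderInput(model, x[, cell, drop = FALSE])
  xt <- prep$xhat  # 1 x |G*|, point path
  cache <- encForward(model@params, log1p(xt))
  bk <- encBackward(model@params, cache, matrix(delta, 1), inputGrad = TRUE)
  g <- as.numeric(bk$dX)
  if (space == "raw") g <- g / (1 + as.numeric(xt))  # log1p chain rule
  setNames(g, model@genes)
}

#' Rank cell-typing-important genes for one cell type
#'
#' Holds out the target cell type as query and the remaining cells as
#' reference, runs consensus querying, and for every query cell and each of
#' its hits backpropagates the embedding deviation (query minus hit, i.e.
#' pointing from the surrounding reference types toward the target type)
#' through the encoder. Gradients are averaged over hits, query cells and
#' models; genes are returned in decreasing mean-gradient order, so top genes
#' are those whose high expression is what places cells with the target
#' type's profile where they sit in the embedding.
#'
#' Significant consensus hits are used when a query cell has any; otherwise
#' that cell's Euclidean candidates stand in (a held-out type can be rejected
#' outright by a specific ensemble).
#'
#' @param x A labeled [CellScoutSet].
#' @param models A [CellScoutModel] or list of them.
#' @param cellType Target label (must occur in `labelColumn`).
#' @param labelColumn colData column holding cell-type labels (default
#'   `"cell_type"`).
#' @param k,cutoff,nPairs,M,seed Passed to [consensusQuery()].
#' @return data.frame with columns `gene` and `score`, ordered by decreasing
#'   score (a permutation of the model's gene set).
#' @export
rankGenesForCellType <- function(x, models, cellType,
                                 labelColumn = "cell_type", k = 50,
                                 cutoff = 0.05, nPairs = 2000, M = NULL,
                                 seed = 0) {
  if (methods::is(models, "CellScoutModel")) models <- list(models)
  labels <- as.character(SummarizedExperiment::colData(x)[[labelColumn]])
  if (!cellType %in% labels)
    stop("cell type '", cellType, "' not present in column '",
         labelColumn, "'")
  isTarget <- labels == cellType
  query <- x[, isTarget]
  reference <- x[, !isTarget]
  hits <- consensusQuery(models, query, reference, k = k, cutoff = cutoff,
                         nPairs = nPairs, M = M, seed = seed)
  cts <- SummarizedExperiment::assay(query, "counts")
  acc <- numeric(length(models[[1]]@genes))
  nTerms <- 0
  for (m in seq_along(models)) {
    model <- models[[m]]
    embQ <- encodeCells(model, query)
    embR <- encodeCells(model, reference)
    for (q in unique(hits$query)) {
      h <- hits[hits$query == q, , drop = FALSE]
      if (any(h$significant)) h <- h[h$significant, , drop = FALSE]
      qEmb <- embQ[q, ]
      for (r in h$ref) {
        # deviation points from the hit toward the target-type query cell
        g <- deviationGradient(model, cts, queryEmbedding = embR[r, ],
                               hitEmbedding = qEmb, cell = q)
        acc <- acc + g
        nTerms <- nTerms + 1
      }
    }
  }
  if (nTerms == 0) stop("no hits available for gradient computation")
  score <- acc / nTerms
  ord <- order(score, decreasing = TRUE)
  data.frame(gene = models[[1]]@genes[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
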