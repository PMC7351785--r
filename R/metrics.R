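#' Average precision of an ordered neighbor list
#'
#' Running precision averaged over the ranks where the neighbor label matches
#' the cell's own label; 0 when no neighbor matches.
#'
#' @param trueLabel The cell's label.
#' @param neighborLabels Labels of its ordered nearest neighbors.
#' @return Scalar in `[0, 1]`.
#' @export
averagePrecision <- function(trueLabel, neighborLabels) {
  hit <- neighborLabels == trueLabel
  if (!any(hit)) return(0)
  prec <- cumsum(hit) / seq_along(hit)
  sum(prec[hit]) / sum(hit)
}

# Euclidean kNN indices for all cells, self excluded (n x k matrix)
.knnMatrix <- function(emb, k) {
  n <- nrow(emb)
  d2 <- outer(rowSums(emb^2), rowSums(emb^2), "+") - 2 * emb %*% t(emb)
  diag(d2) <- Inf
  nn <- vapply(seq_len(n), function(i)
    order(d2[i, ], seq_len(n))[seq_len(k)], integer(k))
  matrix(nn, ncol = k, byrow = TRUE)
}

#' Mean average precision of an embedding
#'
#' Cell-type resolution metric: mean over cells of the average precision of
#' their K Euclidean nearest neighbors (self excluded), with K = 1% of the
#' cell count by default (at least 1). With K = 1 this reduces to
#' nearest-neighbor accuracy.
#'
#' @param embeddings Cells x D matrix.
#' @param labels Per-cell labels.
#' @param kFraction K as a fraction of N (default 0.01).
#' @param k Explicit K overriding `kFraction`.
#' @return Scalar in `[0, 1]`.
#' @export
mapScore <- function(embeddings, labels, kFraction = 0.01, k = NULL) {
  n <- nrow(embeddings)
  if (n < 2) stop("need at least 2 cells")
  if (is.null(k)) k <- max(1, round(kFraction * n))
  labels <- as.character(labels)
  nn <- .knnMatrix(embeddings, k)
  mean(vapply(seq_len(n), function(i)
    averagePrecision(labels[i], labels[nn[i, ]]), numeric(1)))
}

# the alignment-score formula itself, exposed for analytic evaluation
#' Alignment score formula
#'
#' `1 - (xbar - k/N) / (k - k/N)`, clipped to `[0, 1]`: 1 at perfect batch
#' mixing (`xbar = k/N` same-batch neighbors among k) and 0 at total
#' separation (`xbar = k`). `N` is the number of batches.
#'
#' @param xbar Average number of same-batch cells among k nearest neighbors.
#' @param k Neighborhood size.
#' @param nBatches Number of batches N.
#' @return Scalar in `[0, 1]`.
#' @export
alignmentScoreValue <- function(xbar, k, nBatches) {
  v <- 1 - (xbar - k / nBatches) / (k - k / nBatches)
  min(1, max(0, v))
}

#' Batch-mixing alignment score of an embedding
#'
#' Batches are first subsampled (without replacement, seeded) to the size of
#' the smallest batch; the average number of same-batch cells among each
#' cell's k nearest neighbors is then mapped through [alignmentScoreValue()].
#'
#' @param embeddings Cells x D matrix.
#' @param batchLabels Per-cell batch assignments (>= 2 batches).
#' @param k Neighborhood size (default 1% of the subsampled total, >= 1).
#' @param seed Subsampling seed.
#' @return Scalar in `[0, 1]`; 1 = perfect mixing.
#' @export
seuratAlignmentScore <- function(embeddings, batchLabels, k = NULL, seed = 0) {
  f <- factor(batchLabels)
  N <- nlevels(f)
  if (N < 2) stop("need at least 2 batches")
  set.seed(seed)
  sz <- min(table(f))
  idx <- unlist(lapply(levels(f), function(lv)
    sample(which(f == lv), sz)))
  emb <- embeddings[idx, , drop = FALSE]
  fb <- f[idx]
  n <- length(idx)
  if (is.null(k)) k <- max(1, round(0.01 * n))
  if (sz < k + 1)
    stop("a batch has fewer than k + 1 cells after subsampling; use a ",
         "smaller k")
  nn <- .knnMatrix(emb, k)
  same <- vapply(seq_len(n), function(i) sum(fb[nn[i, ]] == fb[i]),
                 numeric(1))
  alignmentScoreValue(mean(same), k, N)
}

#' Mean balanced accuracy against an expected-prediction matrix
#'
#' A prediction is correct iff the binary expected-prediction matrix M has a
#' 1 at (actual type, predicted type); the `"rejected"` column accommodates
#' negative types. Per-type accuracies are averaged unweighted within the
#' positive and negative type sets, and the overall score is the mean of the
#' two set-level MBAs (negative types would otherwise dominate).
#'
#' @param actual,predicted Per-cell character vectors (`predicted` may
#'   contain `"rejected"` / `"ambiguous"`).
#' @param M Binary matrix, rownames = actual types, colnames = predictions
#'   (including `"rejected"`).
#' @param positiveTypes,negativeTypes Type sets T+ and T-.
#' @return List with `mbaPositive`, `mbaNegative` and `overall`.
#' @export
mba <- function(actual, predicted, M, positiveTypes, negativeTypes) {
  predicted[predicted %in% "ambiguous"] <- "rejected"
  badA <- setdiff(unique(actual), rownames(M))
  badP <- setdiff(unique(predicted), colnames(M))
  if (length(badA) || length(badP))
    stop("labels not indexable in M: ",
         paste(c(badA, badP), collapse = ", "))
  accOf <- function(t) {
    sel <- actual == t
    mean(M[cbind(rep(t, sum(sel)), predicted[sel])] == 1)
  }
  mbaOf <- function(types) {
    types <- intersect(types, unique(actual))
    if (!length(types)) return(NA_real_)
    mean(vapply(types, accOf, numeric(1)))
  }
  pos <- mbaOf(positiveTypes)
  neg <- mbaOf(negativeTypes)
  list(mbaPositive = pos, mbaNegative = neg,
       overall = mean(c(pos, neg), na.rm = TRUE))
}

#' Jensen-Shannon divergence between probability vectors
#'
#' Natural-log JSD with the 0 log 0 = 0 convention: symmetric, zero iff the
#' distributions are equal, at most log 2.
#'
#' @param p,q Probability vectors on the simplex, same length.
#' @param tol Simplex-validity tolerance (default 1e-6).
#' @return Scalar in `[0, log 2]`.
#' @export
jsd <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0)) stop("negative probability entries")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("inputs must sum to 1")
  m <- (p + q) / 2
  term <- function(a) {
    pos <- a > 0
    sum(a[pos] * log(a[pos] / m[pos]))
  }
  0.5 * (term(p) + term(q))
}

#' Class enrichment ratio among rejected cells
#'
#' Implements the ratio exactly as printed in its source: the class's overall
#' fraction divided by its fraction among rejected cells. Note the direction:
#' a class over-represented among rejections yields a value below 1; the
#' conventional enrichment-in-rejections measure is its reciprocal, exposed
#' as [rejectionEnrichment()].
#'
#' @param nClassTotal,nTotal Class count and total count overall.
#' @param nClassRejected,nRejected Class count and total count among
#'   rejected cells.
#' @return Positive scalar.
#' @export
enrichmentRatio <- function(nClassTotal, nTotal, nClassRejected, nRejected) {
  if (any(c(nClassTotal, nTotal, nClassRejected, nRejected) <= 0))
    stop("all counts must be positive")
  (nClassTotal / nTotal) / (nClassRejected / nRejected)
}

#' @rdname enrichmentRatio
#' @export
rejectionEnrichment <- function(nClassTotal, nTotal, nClassRejected,
                                nRejected) {
  1 / enrichmentRatio(nClassTotal, nTotal, nClassRejected, nRejected)
}
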