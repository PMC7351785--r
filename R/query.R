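#' PosteriorEmbedding: point estimates plus posterior samples
#'
#' Per-cell deterministic point estimates (the Poisson step skipped) and M
#' stochastic posterior samples of the embedding, as produced by
#' [posteriorSamples()].
#'
#' @slot points N x D matrix of point estimates (rownames = cell ids).
#' @slot samples N x M x D array of posterior samples.
#' @export
setClass("PosteriorEmbedding",
         representation(points = "matrix", samples = "array"))

setValidity("PosteriorEmbedding", function(object) {
  d <- dim(object@samples)
  if (length(d) != 3) return("samples must be an N x M x D array")
  if (d[1] != nrow(object@points) || d[3] != ncol(object@points))
    return("samples dimensions do not match points")
  if (!all(is.finite(object@points)) || !all(is.finite(object@samples)))
    return("embeddings must be finite")
  TRUE
})

setMethod("show", "PosteriorEmbedding", function(object) {
  d <- dim(object@samples)
  cat("PosteriorEmbedding:", d[1], "cells, D =", d[3],
      ", M =", d[2], "posterior samples\n")
})

#' Sample the posterior embedding distribution
#'
#' Point estimates use the deterministic path; the M samples re-run the
#' encoder on independent Poisson perturbations of the normalized profile,
#' which is how embedding uncertainty is quantified.
#'
#' @param model A [CellScoutModel].
#' @param x A [CellScoutSet] or genes x cells matrix.
#' @param M Number of posterior samples per cell (default: model config).
#' @param seed Seed for the Poisson draws.
#' @return A [PosteriorEmbedding].
#' @export
posteriorSamples <- function(model, x, M = NULL, seed = 0) {
  if (is.null(M)) M <- model@config$posteriorSamples
  prep <- prepEncoderInput(model, x)
  pts <- encForward(model@params, log1p(prep$xhat))$l
  rownames(pts) <- prep$cells
  n <- nrow(prep$xhat)
  set.seed(seed)
  big <- prep$xhat[rep(seq_len(n), each = M), , drop = FALSE]
  xt <- matrix(rpois(length(big), big), nrow(big))
  emb <- encForward(model@params, log1p(xt))$l
  D <- ncol(emb)
  samples <- array(0, c(n, M, D))
  for (d in seq_len(D))
    samples[, , d] <- matrix(emb[, d], n, M, byrow = TRUE)
  methods::new("PosteriorEmbedding", points = pts, samples = samples)
}

#' Empirical 1-D Wasserstein-1 distance
#'
#' For equal sample counts this is the order-statistic solution of 1-D
#' optimal transport: the mean absolute difference of sorted samples. Unequal
#' counts are handled through the quantile-function formulation.
#'
#' @param u,v Numeric sample vectors (nonempty).
#' @return Nonnegative scalar.
#' @export
wasserstein1Empirical <- function(u, v) {
  if (!length(u) || !length(v)) stop("empty sample vector")
  if (length(u) == length(v))
    return(mean(abs(sort(u) - sort(v))))
  # general case: integrate |F_u^{-1}(t) - F_v^{-1}(t)| dt
  us <- sort(u); vs <- sort(v)
  tu <- seq_along(us) / length(us)
  tv <- seq_along(vs) / length(vs)
  ts <- sort(unique(c(tu, tv)))
  qu <- us[pmax(1, ceiling(ts * length(us) - 1e-12))]
  qv <- vs[pmax(1, ceiling(ts * length(vs) - 1e-12))]
  widths <- diff(c(0, ts))
  sum(widths * abs(qu - qv))
}

# core NPD between two cells given point estimates and sample matrices
.npdCore <- function(p1, s1, p2, s2) {
  d <- p2 - p1
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(0)  # coincident point estimates: maximally similar
  u <- d / nd
  prj1 <- as.numeric(s1 %*% u)
  prj2 <- as.numeric(s2 %*% u)
  sd1 <- sd(prj1); sd2 <- sd(prj2)
  if (sd1 == 0 || sd2 == 0)
    stop("zero projected posterior variance; increase the number of ",
         "posterior samples M")
  z1p <- (prj1 - mean(prj1)) / sd1
  z1q <- (prj2 - mean(prj1)) / sd1
  z2p <- (prj1 - mean(prj2)) / sd2
  z2q <- (prj2 - mean(prj2)) / sd2
  0.5 * (wasserstein1Empirical(z1p, z1q) + wasserstein1Empirical(z2p, z2q))
}

#' Normalized projection distance (NPD) between two cells
#'
#' Projects both cells' posterior samples onto the line through their point
#' estimates, z-normalizes the projections twice (by the first cell's
#' projected mean/sd and by the second's), and averages the two 1-D
#' Wasserstein-1 distances. Symmetric; zero for identical posteriors and for
#' coincident point estimates (where the projection direction is undefined).
#'
#' @param p,q Either single-cell entries of a [PosteriorEmbedding] (use
#'   `cell` / `cell2` indices) or lists with elements `point` (length-D
#'   vector) and `samples` (M x D matrix).
#' @param cell,cell2 When `p`/`q` are `PosteriorEmbedding` objects: the cell
#'   index or id to use from each.
#' @return Nonnegative scalar.
#' @export
npd <- function(p, q, cell = 1, cell2 = 1) {
  pe <- .asCellPosterior(p, cell)
  qe <- .asCellPosterior(q, cell2)
  if (length(pe$point) != length(qe$point))
    stop("latent dimensions differ")
  .npdCore(pe$point, pe$samples, qe$point, qe$samples)
}

.asCellPosterior <- function(x, cell) {
  if (methods::is(x, "PosteriorEmbedding")) {
    if (is.character(cell)) cell <- match(cell, rownames(x@points))
    list(point = x@points[cell, ],
         samples = matrix(x@samples[cell, , ], dim(x@samples)[2]))
  } else x
}

#' Euclidean k-nearest-neighbor candidates
#'
#' Exhaustive Euclidean search on point estimates; ties broken by reference
#' index for determinism.
#'
#' @param reference N x D matrix of reference point estimates.
#' @param queryPoint Length-D query point (or matrix of query rows).
#' @param k Number of neighbors (k <= N).
#' @return For a single query: list with `index`, `id` (rownames, if any) and
#'   `distance`, each length k in increasing-distance order. For a matrix
#'   query: list of such lists.
#' @export
knnCandidates <- function(reference, queryPoint, k) {
  if (!nrow(reference)) stop("empty reference")
  if (k > nrow(reference)) stop("k exceeds reference size")
  one <- function(qp) {
    d2 <- rowSums(sweep(reference, 2, qp)^2)
    ord <- order(d2, seq_along(d2))[seq_len(k)]
    list(index = ord, id = rownames(reference)[ord],
         distance = sqrt(d2[ord]))
  }
  if (is.matrix(queryPoint) && nrow(queryPoint) > 1)
    lapply(seq_len(nrow(queryPoint)), function(i) one(queryPoint[i, ]))
  else one(as.numeric(queryPoint))
}

#' Empirical NPD null distribution over reference pairs
#'
#' NPD values for randomly selected pairs of distinct reference cells, used
#' to convert query-hit NPDs into empirical p-values.
#'
#' @param ref A [PosteriorEmbedding] of the reference (>= 2 cells).
#' @param nPairs Number of random pairs (default 10000).
#' @param seed RNG seed.
#' @return A list of class `NullDistribution` with sorted `values`, `nPairs`
#'   and `seed`.
#' @export
buildEmpiricalNull <- function(ref, nPairs = 10000, seed = 0) {
  n <- nrow(ref@points)
  if (n < 2) stop("need at least 2 reference cells")
  set.seed(seed)
  i <- sample.int(n, nPairs, replace = TRUE)
  j <- sample.int(n - 1, nPairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1, j)  # uniform over distinct pairs
  vals <- vapply(seq_len(nPairs), function(t) {
    .npdCore(ref@points[i[t], ], matrix(ref@samples[i[t], , ],
                                        dim(ref@samples)[2]),
             ref@points[j[t], ], matrix(ref@samples[j[t], , ],
                                        dim(ref@samples)[2]))
  }, numeric(1))
  structure(list(values = sort(vals), nPairs = nPairs, seed = seed),
            class = "NullDistribution")
}

#' Empirical p-value of a query-hit NPD
#'
#' Add-one estimator `p = (1 + #\{null <= npd\}) / (1 + nPairs)`: small NPD
#' (similar cells) gives small p, and p is never exactly zero.
#'
#' @param npdValue Numeric NPD value(s).
#' @param null A `NullDistribution` from [buildEmpiricalNull()].
#' @return p-value(s) in (0, 1].
#' @export
hitPvalue <- function(npdValue, null) {
  v <- null$values
  (1 + findInterval(npdValue, v)) / (1 + length(v))
}

#' Consensus querying across an ensemble of models
#'
#' For each query cell, candidate reference cells are the union of each
#' model's k Euclidean nearest neighbors. Every candidate receives an NPD and
#' an empirical p-value under every model; a hit is significant only if its
#' p-value passes the cutoff in every model (strict consensus), and the
#' reported p-value is the maximum across models.
#'
#' @param models A [CellScoutModel] or list of them (sharing the reference's
#'   gene contract).
#' @param query,reference [CellScoutSet] objects (or count matrices).
#' @param k Euclidean prefilter size per model (default 50).
#' @param cutoff Per-model p-value cutoff (default 0.05).
#' @param nPairs Null-distribution size when a model has no cached null.
#' @param M Posterior samples per cell (default: each model's config).
#' @param seed Base seed; model m uses seed + m for its stochastic draws.
#' @param requireAll If `FALSE`, significance in a majority of models
#'   suffices and the median p-value is reported.
#' @return data.frame with columns query, ref, euclidean (mean across
#'   models), npd (mean), pvalue (max or median), significant.
#' @export
consensusQuery <- function(models, query, reference, k = 50, cutoff = 0.05,
                           nPairs = 10000, M = NULL, seed = 0,
                           requireAll = TRUE) {
  if (methods::is(models, "CellScoutModel")) models <- list(models)
  if (!length(models)) stop("need at least one model")
  nm <- length(models)
  embQ <- list(); embR <- list(); nulls <- list()
  for (m in seq_len(nm)) {
    # one shared sampling seed: ensembles differ through their weights, and
    # duplicating a model then exactly reproduces the single-model calls
    model <- models[[m]]
    embR[[m]] <- posteriorSamples(model, reference, M = M, seed = seed)
    embQ[[m]] <- posteriorSamples(model, query, M = M, seed = seed + 1000L)
    nulls[[m]] <- if (!is.null(model@null)) model@null
                  else buildEmpiricalNull(embR[[m]], nPairs = nPairs,
                                          seed = seed)
  }
  nq <- nrow(embQ[[1]]@points)
  refIds <- rownames(embR[[1]]@points)
  out <- vector("list", nq)
  for (qi in seq_len(nq)) {
    cand <- sort(unique(unlist(lapply(seq_len(nm), function(m)
      knnCandidates(embR[[m]]@points, embQ[[m]]@points[qi, ], k)$index))))
    pv <- matrix(0, length(cand), nm)
    np <- matrix(0, length(cand), nm)
    eu <- matrix(0, length(cand), nm)
    for (m in seq_len(nm)) {
      qp <- embQ[[m]]@points[qi, ]
      qs <- matrix(embQ[[m]]@samples[qi, , ], dim(embQ[[m]]@samples)[2])
      for (ci in seq_along(cand)) {
        r <- cand[ci]
        np[ci, m] <- .npdCore(
          qp, qs, embR[[m]]@points[r, ],
          matrix(embR[[m]]@samples[r, , ], dim(embR[[m]]@samples)[2]))
        eu[ci, m] <- sqrt(sum((qp - embR[[m]]@points[r, ])^2))
      }
      pv[, m] <- hitPvalue(np[, m], nulls[[m]])
    }
    sig <- if (requireAll) rowSums(pv <= cutoff) == nm
           else rowSums(pv <= cutoff) > nm / 2
    pRep <- if (requireAll) apply(pv, 1, max) else apply(pv, 1, stats::median)
    out[[qi]] <- data.frame(
      query = rownames(embQ[[1]]@points)[qi] %||% as.character(qi),
      ref = refIds[cand] %||% as.character(cand),
      euclidean = rowMeans(eu), npd = rowMeans(np), pvalue = pRep,
      significant = sig, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete annotation transfer from significant hits
#'
#' Majority voting among significant hits: fewer than `minHits` significant
#' hits rejects the query cell; a winning label must take a vote fraction
#' strictly greater than `majorityThreshold`, otherwise the call is
#' ambiguous.
#'
#' @param hits data.frame from [consensusQuery()].
#' @param referenceLabels Named vector mapping reference cell ids to labels.
#' @param majorityThreshold Strict vote-fraction threshold (default 0.5).
#' @param minHits Minimum number of significant hits (default 2).
#' @return data.frame with query, status (predicted/ambiguous/rejected),
#'   label, nHits.
#' @export
predictDiscrete <- function(hits, referenceLabels, majorityThreshold = 0.5,
                            minHits = 2) {
  qs <- unique(hits$query)
  res <- lapply(qs, function(q) {
    h <- hits[hits$query == q & hits$significant, , drop = FALSE]
    if (nrow(h) < minHits)
      return(data.frame(query = q, status = "rejected", label = NA,
                        nHits = nrow(h), stringsAsFactors = FALSE))
    labs <- referenceLabels[h$ref]
    tab <- sort(table(labs), decreasing = TRUE)
    frac <- tab[1] / sum(tab)
    if (frac > majorityThreshold)
      data.frame(query = q, status = "predicted", label = names(tab)[1],
                 nHits = nrow(h), stringsAsFactors = FALSE)
    else
      data.frame(query = q, status = "ambiguous", label = NA,
                 nHits = nrow(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Continuous annotation transfer from significant hits
#'
#' Unweighted arithmetic mean of the significant hits' annotation vectors
#' (e.g. lineage fate probabilities); inputs on the probability simplex stay
#' on it. Queries with fewer than `minHits` significant hits are rejected.
#'
#' @param hits data.frame from [consensusQuery()].
#' @param referenceVectors Numeric matrix, rownames = reference cell ids.
#' @param minHits Minimum number of significant hits (default 2).
#' @return List with `predictions` (query x dims matrix, NA rows for
#'   rejected) and `status` (named character).
#' @export
predictContinuous <- function(hits, referenceVectors, minHits = 2) {
  qs <- unique(hits$query)
  pred <- matrix(NA_real_, length(qs), ncol(referenceVectors),
                 dimnames = list(qs, colnames(referenceVectors)))
  status <- setNames(rep("rejected", length(qs)), qs)
  for (q in qs) {
    h <- hits[hits$query == q & hits$significant, , drop = FALSE]
    if (nrow(h) >= minHits) {
      pred[q, ] <- colMeans(referenceVectors[h$ref, , drop = FALSE])
      status[q] <- "predicted"
    }
  }
  list(predictions = pred, status = status)
}
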