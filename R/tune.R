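#' Mutual nearest neighbors between two embedding sets
#'
#' (a, b) is a pair iff b is among a's k nearest neighbors in B and a is
#' among b's k nearest in A (Euclidean distance on point estimates; ties
#' broken by index).
#'
#' @param a,b Point matrices (rows = cells, same dimensionality).
#' @param k Neighborhood size on both sides (default 5).
#' @return data.frame with integer columns `a` and `b` (possibly 0 rows).
#' @export
mutualNearestNeighbors <- function(a, b, k = 5) {
  if (!nrow(a) || !nrow(b)) stop("both embedding sets must be nonempty")
  stopifnot(k >= 1)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  ka <- min(k, ncol(d2)); kb <- min(k, nrow(d2))
  nnAB <- matrix(vapply(seq_len(nrow(d2)), function(i)
    order(d2[i, ], seq_len(ncol(d2)))[seq_len(ka)], integer(ka)),
    ncol = ka, byrow = TRUE)
  nnBA <- matrix(vapply(seq_len(ncol(d2)), function(j)
    order(d2[, j], seq_len(nrow(d2)))[seq_len(kb)], integer(kb)),
    ncol = kb, byrow = TRUE)
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in nnAB[i, ]) {
      if (i %in% nnBA[j, ]) pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (!length(pairs)) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, pairs)
  data.frame(a = m[, 1], b = m[, 2])
}

#' Online-tuning configuration
#'
#' @param lambdaQueryBatch Adversarial strength for the reference-vs-query
#'   discriminator (default 10, on the same scale as lambdaBatch).
#' @param deviationPenalty Weight of the squared-deviation anchor tying tuned
#'   weights to the pretrained ones (default 0.001); new parameters
#'   (indicator rows, the new discriminator) are unpenalized.
#' @param kMnn Mutual-nearest-neighbor size (default 5); the adversarial loss
#'   only acts on cells participating in an MNN pair, recomputed once per
#'   epoch.
#' @param epochs Tuning epochs (default 50).
#' @param batchSize Minibatch size (default 128).
#' @param seed RNG seed.
#' @return A list of class `TuneConfig`.
#' @export
tuneConfig <- function(lambdaQueryBatch = 10, deviationPenalty = 0.001,
                       kMnn = 5, epochs = 50, batchSize = 128, seed = 0) {
  stopifnot(lambdaQueryBatch >= 0, deviationPenalty >= 0, kMnn >= 1)
  structure(list(lambdaQueryBatch = lambdaQueryBatch,
                 deviationPenalty = deviationPenalty, kMnn = kMnn,
                 epochs = epochs, batchSize = batchSize,
                 seed = as.integer(seed)),
            class = "TuneConfig")
}

# training tensors for the combined reference + query stream; query cells get
# all-zero indicators on the reference batch levels
.tuneData <- function(model, reference, query) {
  genes <- model@genes
  levels <- names(model@batchInfo)
  levels <- setdiff(levels, "origin")
  tdR <- .trainingData(reference, genes, levels)
  ctsQ <- if (methods::is(query, "CellScoutSet"))
    SummarizedExperiment::assay(query, "counts") else query
  prepQ <- prepEncoderInput(model, ctsQ)
  if (any(prepQ$sizeFactors == 0))
    stop("query cell(s) with zero counts over the model genes")
  nR <- nrow(tdR$x); nQ <- nrow(prepQ$xhat)
  oh <- lapply(tdR$oh, function(m)
    rbind(m, matrix(0, nQ, ncol(m))))
  list(x = rbind(tdR$x, prepQ$counts),
       xhat = rbind(tdR$xhat, prepQ$xhat),
       s = c(tdR$s, prepQ$sizeFactors),
       oh = oh, nR = nR, nQ = nQ,
       rqOnehot = rbind(cbind(rep(1, nR), 0), cbind(0, rep(1, nQ))))
}

#' Online tuning against a batch-shifted query set
#'
#' Fine-tunes pretrained models on the combined reference + query stream:
#' the decoder is expanded with a reference/query one-hot indicator
#' (zero-initialized, so the forward pass is unchanged at step 0), a new
#' discriminator dedicated to the reference-vs-query batch effect is added,
#' its adversarial loss is restricted to cells participating in a mutual-
#' nearest-neighbor pair (recomputed each epoch on current point estimates),
#' and a squared-deviation penalty anchors all pre-existing weights to their
#' pretrained values. All original components keep training as before.
#'
#' @param models A [CellScoutModel] or list of them.
#' @param reference [CellScoutSet] the models were trained on (gene contract
#'   and batch levels must match).
#' @param query [CellScoutSet] or counts matrix with the model genes.
#' @param config A [tuneConfig()].
#' @param verbose Print epoch losses every `verbose` epochs (0 = silent).
#' @return Tuned model(s), same shape as `models`; each gains an `origin`
#'   batch level (`reference` / `query`) consumed by [decodeCells()].
#' @export
onlineTune <- function(models, reference, query, config = tuneConfig(),
                       verbose = 0) {
  single <- methods::is(models, "CellScoutModel")
  if (single) models <- list(models)
  tuned <- lapply(seq_along(models), function(m)
    .tuneOne(models[[m]], reference, query, config,
             seed = config$seed + m - 1L, verbose = verbose))
  if (single) tuned[[1]] else tuned
}

.tuneOne <- function(model, reference, query, config, seed, verbose = 0) {
  cfg <- model@config
  set.seed(seed)
  td <- .tuneData(model, reference, query)
  levels <- setdiff(names(model@batchInfo), "origin")
  params <- model@params
  anchor <- list(enc = params$enc, dec = params$dec, H = params$H)
  # expand decoder input by the two indicator columns (zero-init)
  params$dec$trunk[[1]]$W <- rbind(params$dec$trunk[[1]]$W,
                                   matrix(0, 2, ncol(params$dec$trunk[[1]]$W)))
  hid <- rep(cfg$hiddenUnits, cfg$depth)
  params$rq <- netInit(c(cfg$latentDim, hid, 2))
  gstate <- rmspropInit(list(enc = params$enc, dec = params$dec, H = params$H))
  dstate <- rmspropInit(list(dz = params$dz, dc = params$dc, db = params$db,
                             rq = params$rq))
  n <- td$nR + td$nQ
  bs <- min(config$batchSize, n)
  log <- list()
  for (ep in seq_len(config$epochs)) {
    pts <- encForward(params, log1p(td$xhat))$l
    mnn <- mutualNearestNeighbors(pts[seq_len(td$nR), , drop = FALSE],
                                  pts[td$nR + seq_len(td$nQ), , drop = FALSE],
                                  config$kMnn)
    inPair <- rep(FALSE, n)
    inPair[unique(mnn$a)] <- TRUE
    inPair[td$nR + unique(mnn$b)] <- TRUE
    if (!any(inPair) && ep == 1)
      warning("no mutual nearest neighbors found; alignment inactive")
    ord <- sample.int(n)
    nb <- max(1, floor(n / bs))
    acc <- NULL
    for (i in seq_len(nb)) {
      idx <- ord[((i - 1) * bs + 1):(i * bs)]
      mb <- .mbSlice(td, idx)
      extra <- list(mask = inPair[idx],
                    rqOnehot = td$rqOnehot[idx, , drop = FALSE],
                    lambdaRq = config$lambdaQueryBatch,
                    deviationPenalty = config$deviationPenalty,
                    anchor = anchor)
      it <- .trainIteration(params, gstate, dstate, mb, cfg, levels,
                            extra = extra)
      params <- it$params; gstate <- it$gstate; dstate <- it$dstate
      if (!all(is.finite(it$losses)))
        stop("non-finite loss during tuning at epoch ", ep)
      acc <- if (is.null(acc)) it$losses else acc + it$losses
    }
    log[[ep]] <- acc / nb
    if (verbose > 0 && ep %% verbose == 0)
      message("tune epoch ", ep, ": nll=", signif(log[[ep]]["nll"], 5))
  }
  # fold the reference/query discriminator in as a regular batch level
  binfo <- model@batchInfo
  binfo$origin <- c("reference", "query")
  db <- params$db
  db$origin <- params$rq
  params$db <- db
  params$rq <- NULL
  methods::new("CellScoutModel", params = params, genes = model@genes,
               batchInfo = binfo, config = cfg,
               trainingLog = cbind(epoch = seq_along(log),
                                   as.data.frame(do.call(rbind, log))),
               null = NULL)
}
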