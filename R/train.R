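# Two-step adversarial training. Each SGD iteration first updates all
# discriminators (prior discriminators on z and c, one batch discriminator
# per batch level) on the current encoder outputs, then updates the encoder,
# decoder and mixture matrix H against the reconstruction NLL plus the
# adversarial terms. RMSProp without momentum throughout.

CLIP <- 1e-7
clipProb <- function(p) pmin(pmax(p, CLIP), 1 - CLIP)

# assemble per-minibatch tensors from precomputed training data
.mbSlice <- function(td, idx) {
  list(x = td$x[idx, , drop = FALSE],
       xhat = td$xhat[idx, , drop = FALSE],
       s = td$s[idx],
       oh = lapply(td$oh, function(m) m[idx, , drop = FALSE]))
}

.priorSamples <- function(n, D, K) {
  zp <- matrix(rnorm(n * D), n, D)
  cp <- NULL
  if (K > 0) {
    cp <- matrix(0, n, K)
    cp[cbind(seq_len(n), sample.int(K, n, replace = TRUE))] <- 1
  }
  list(z = zp, c = cp)
}

# One full iteration. params/states are environments-free lists; returns
# updated params, states and the named losses. extra: optional tuning hooks
# (rq discriminator, MNN mask, deviation anchor), see tune.R.
.trainIteration <- function(params, gstate, dstate, mb, cfg, levels,
                            extra = NULL) {
  n <- nrow(mb$xhat)
  D <- cfg$latentDim; K <- cfg$nComponents
  xt <- matrix(rpois(length(mb$xhat), mb$xhat), n)
  Xenc <- log1p(xt)
  ec <- encForward(params, Xenc)
  pr <- .priorSamples(n, D, K)
  losses <- c()

  # ---- step 1: discriminators --------------------------------------------
  dgrads <- list(dz = NULL, dc = NULL, db = NULL, rq = NULL)
  bin <- function(net, real, fake, lambda) {
    Xd <- rbind(real, fake)
    y <- c(rep(1, nrow(real)), rep(0, nrow(fake)))
    fw <- netForward(net, Xd)
    p <- clipProb(sigmoid(fw$out[, 1]))
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dA <- matrix(lambda * (p - y) / length(y), ncol = 1)
    list(loss = loss, grads = netBackward(net, fw, dA)$grads)
  }
  rz <- bin(params$dz, pr$z, ec$z, cfg$lambdaZ)
  dgrads$dz <- rz$grads; losses["discZ"] <- rz$loss
  if (K > 0) {
    rc <- bin(params$dc, pr$c, ec$c, cfg$lambdaC)
    dgrads$dc <- rc$grads; losses["discC"] <- rc$loss
  }
  if (length(levels)) {
    dgrads$db <- list()
    for (lv in levels) {
      lam <- lambdaForLevel(cfg, lv)
      fw <- netForward(params$db[[lv]], ec$l)
      p <- clipProb(softmaxRows(fw$out))
      ce <- -mean(rowSums(mb$oh[[lv]] * log(p)))
      dA <- lam * (p - mb$oh[[lv]]) / n
      dgrads$db[[lv]] <- netBackward(params$db[[lv]], fw, dA)$grads
      losses[paste0("discB.", lv)] <- ce
    }
  }
  if (!is.null(extra)) {
    # reference/query discriminator: trained on the whole minibatch (its
    # generator-side alignment loss is what the MNN restriction applies to)
    fw <- netForward(params$rq, ec$l)
    p <- clipProb(softmaxRows(fw$out))
    ce <- -mean(rowSums(extra$rqOnehot * log(p)))
    dA <- extra$lambdaRq * (p - extra$rqOnehot) / n
    dgrads$rq <- netBackward(params$rq, fw, dA)$grads
    losses["discRq"] <- ce
  }
  dparams <- list(dz = params$dz, dc = params$dc, db = params$db,
                  rq = params$rq)
  st <- rmspropStep(dparams, dgrads, dstate, cfg$learningRate)
  params$dz <- st$params$dz
  if (!is.null(params$dc)) params$dc <- st$params$dc
  params$db <- st$params$db
  if (!is.null(params$rq)) params$rq <- st$params$rq
  dstate <- st$state

  # ---- step 2: encoder + decoder + H -------------------------------------
  L <- cbind(ec$l, do.call(cbind, c(mb$oh, list(matrix(0, n, 0)))))
  if (!is.null(extra)) L <- cbind(L, extra$rqOnehot)
  dcache <- decForward(params, L, mb$s, cfg$thetaMode)
  nb <- nbNllGrad(mb$x, dcache$mu, dcache$theta)
  losses["nll"] <- nb$nll
  dbk <- decBackward(params, dcache, nb$dMu, nb$dTheta, cfg$thetaMode,
                     inputGrad = TRUE)
  dl <- dbk$dX[, seq_len(D), drop = FALSE]

  genThrough <- function(net, X, dA) netBackward(net, netForward(net, X),
                                                 dA, inputGrad = TRUE)$dX
  # non-saturating prior terms: maximize log D(fake)
  fwz <- netForward(params$dz, ec$z)
  pz <- clipProb(sigmoid(fwz$out[, 1]))
  losses["genZ"] <- -mean(log(pz))
  dzExtra <- netBackward(params$dz, fwz,
                         matrix(-cfg$lambdaZ * (1 - pz) / n, ncol = 1),
                         inputGrad = TRUE)$dX
  dcExtra <- NULL
  if (K > 0) {
    fwc <- netForward(params$dc, ec$c)
    pc <- clipProb(sigmoid(fwc$out[, 1]))
    losses["genC"] <- -mean(log(pc))
    dcExtra <- netBackward(params$dc, fwc,
                           matrix(-cfg$lambdaC * (1 - pc) / n, ncol = 1),
                           inputGrad = TRUE)$dX
  }
  if (length(levels)) {
    for (lv in levels) {
      lam <- lambdaForLevel(cfg, lv)
      fw <- netForward(params$db[[lv]], ec$l)
      p <- clipProb(softmaxRows(fw$out))
      ce <- -mean(rowSums(mb$oh[[lv]] * log(p)))
      losses[paste0("genB.", lv)] <- -ce
      # ascend the discriminator's cross-entropy
      dl <- dl + genThrough(params$db[[lv]], ec$l, -lam * (p - mb$oh[[lv]]) / n)
    }
  }
  if (!is.null(extra) && sum(extra$mask) >= 2) {
    mask <- extra$mask
    fw <- netForward(params$rq, ec$l[mask, , drop = FALSE])
    p <- clipProb(softmaxRows(fw$out))
    tgt <- extra$rqOnehot[mask, , drop = FALSE]
    dIn <- netBackward(params$rq, fw,
                       -extra$lambdaRq * (p - tgt) / sum(mask),
                       inputGrad = TRUE)$dX
    add <- matrix(0, n, D); add[mask, ] <- dIn
    dl <- dl + add
  }
  ebk <- encBackward(params, ec, dl, dzExtra = dzExtra, dcExtra = dcExtra)
  ggrads <- list(enc = ebk$grads, dec = dbk$grads, H = ebk$dH)
  gparams <- list(enc = params$enc, dec = params$dec, H = params$H)
  if (!is.null(extra) && extra$deviationPenalty > 0) {
    # L2 anchor on the pre-tuning parameters (new parameters unpenalized)
    pen <- zipMap(function(p0, p1) 2 * extra$deviationPenalty * (p1 - p0),
                  list(enc = extra$anchor$enc, dec = .anchorDec(extra, params)),
                  list(enc = params$enc, dec = params$dec))
    ggrads$enc <- sumParams(ggrads$enc, pen$enc)
    ggrads$dec <- sumParams(ggrads$dec, pen$dec)
    if (!is.null(params$H))
      ggrads$H <- ggrads$H + 2 * extra$deviationPenalty * (params$H - extra$anchor$H)
  }
  st <- rmspropStep(gparams, ggrads, gstate, cfg$learningRate)
  params$enc <- st$params$enc
  params$dec <- st$params$dec
  if (!is.null(params$H)) params$H <- st$params$H
  gstate <- st$state
  losses["total"] <- losses["nll"] +
    cfg$lambdaZ * losses["genZ"] +
    (if (K > 0) cfg$lambdaC * losses["genC"] else 0) +
    sum(vapply(levels, function(lv)
      lambdaForLevel(cfg, lv) * losses[paste0("genB.", lv)], numeric(1)))
  list(params = params, gstate = gstate, dstate = dstate, losses = losses)
}

# tuning anchors cover only the pre-existing decoder parameters; the
# expanded first-layer rows (reference/query indicator) are new and free
.anchorDec <- function(extra, params) {
  a <- extra$anchor$dec
  cur <- params$dec
  a$trunk[[1]]$W <- rbind(a$trunk[[1]]$W,
                          cur$trunk[[1]]$W[
                            seq(nrow(a$trunk[[1]]$W) + 1,
                                nrow(cur$trunk[[1]]$W)), , drop = FALSE])
  a
}

# precompute dense training tensors from a CellScoutSet
.trainingData <- function(x, genes, levels) {
  cts <- SummarizedExperiment::assay(x, "counts")
  tot <- Matrix::colSums(cts)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(head(colnames(x)[tot == 0], 5), collapse = ", "))
  xs <- t(as.matrix(cts[genes, , drop = FALSE]))
  s <- rowSums(xs)
  if (any(s == 0))
    stop(sum(s == 0), " cell(s) have zero counts over the selected genes; ",
         "select a broader gene set")
  oh <- list(); info <- list()
  for (lv in levels) {
    bo <- batchOneHot(x, lv)
    oh[[lv]] <- bo$onehot
    info[[lv]] <- bo$levels
  }
  list(x = xs, xhat = xs * (1e4 / tot), s = s, oh = oh, info = info)
}

#' Fit the generative embedding model
#'
#' Trains the adversarial autoencoder on raw counts restricted to the
#' selected genes: the encoder maps Poisson-perturbed, normalized,
#' log1p-transformed profiles to embeddings l = z + Hc; the decoder
#' reconstructs counts through a batch-conditioned negative binomial whose
#' mean is a softmax over genes scaled by the size factor. Each iteration
#' first updates all discriminators, then the encoder/decoder/H. Training is
#' reproducible under `config$seed`.
#'
#' @param x A [CellScoutSet] with `selectedGenes` set (if empty, variable
#'   genes are selected with default parameters first).
#' @param config A [modelConfig()].
#' @param batchLevels Batch levels to align adversarially (default: all
#'   levels registered on `x`).
#' @param verbose Print epoch losses every `verbose` epochs (0 = silent).
#' @return A [CellScoutModel] with the per-epoch loss trajectory in
#'   `@trainingLog`.
#' @export
fitModel <- function(x, config = modelConfig(), batchLevels = NULL,
                     verbose = 0) {
  if (ncol(x) < 50) stop("need at least 50 cells to train")
  if (ncol(x) < 1000)
    warning("fewer than 1000 cells may suffer from under-training")
  if (is.null(batchLevels)) batchLevels <- batchLevels(x)
  genes <- selectedGenes(x)
  if (!length(genes)) {
    message("no selected genes; running selectVariableGenes() with defaults")
    genes <- selectVariableGenes(x)
    if (!length(genes)) stop("gene selection returned no genes")
  }
  set.seed(config$seed)
  td <- .trainingData(x, genes, batchLevels)
  params <- newModelParams(length(genes), td$info, config)
  params$rq <- NULL
  gstate <- rmspropInit(list(enc = params$enc, dec = params$dec, H = params$H))
  dstate <- rmspropInit(list(dz = params$dz, dc = params$dc, db = params$db,
                             rq = NULL))
  n <- nrow(td$x)
  bs <- min(config$batchSize, n)
  log <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- floor(n / bs)
    acc <- NULL
    for (i in seq_len(nb)) {
      idx <- ord[((i - 1) * bs + 1):(i * bs)]
      it <- .trainIteration(params, gstate, dstate, .mbSlice(td, idx),
                            config, batchLevels)
      params <- it$params; gstate <- it$gstate; dstate <- it$dstate
      if (!all(is.finite(it$losses)))
        stop("non-finite loss at epoch ", ep, ": ",
             paste(names(it$losses), signif(it$losses, 4),
                   sep = "=", collapse = " "))
      acc <- if (is.null(acc)) it$losses else acc + it$losses
    }
    log[[ep]] <- acc / nb
    if (verbose > 0 && ep %% verbose == 0)
      message("epoch ", ep, ": ",
              paste(names(log[[ep]]), signif(log[[ep]], 4),
                    sep = "=", collapse = " "))
  }
  methods::new("CellScoutModel", params = params, genes = genes,
               batchInfo = td$info, config = config,
               trainingLog = cbind(epoch = seq_along(log),
                                   as.data.frame(do.call(rbind, log))),
               null = NULL)
}

#' Diagnostic loss evaluation on a set of cells
#'
#' Computes the named training losses (reconstruction NLL, generator-side
#' adversarial terms, discriminator losses and the total generator objective)
#' at the current parameters, without updating anything. Deterministic: uses
#' the point path (no Poisson perturbation) and a fixed seed for prior draws.
#'
#' @param model A [CellScoutModel].
#' @param x A [CellScoutSet] carrying the model's batch levels.
#' @param seed Seed for the prior samples (default 0).
#' @return Named numeric vector of losses. Discriminator entries are the
#'   minimized negative log-likelihoods (log 2 for an uninformative binary
#'   discriminator); `total` is the generator objective, which reduces to
#'   `nll` when all lambdas are zero.
#' @export
trainingLosses <- function(model, x, seed = 0) {
  cfg <- model@config
  set.seed(seed)
  levels <- names(model@batchInfo)
  td <- .trainingData(x, model@genes, levels)
  n <- nrow(td$x)
  params <- model@params
  ec <- encForward(params, log1p(td$xhat))
  pr <- .priorSamples(n, cfg$latentDim, cfg$nComponents)
  losses <- c()
  evalBin <- function(net, real, fake) {
    p <- clipProb(sigmoid(netForward(net, rbind(real, fake))$out[, 1]))
    y <- c(rep(1, nrow(real)), rep(0, nrow(fake)))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  losses["discZ"] <- evalBin(params$dz, pr$z, ec$z)
  pz <- clipProb(sigmoid(netForward(params$dz, ec$z)$out[, 1]))
  losses["genZ"] <- -mean(log(pz))
  if (cfg$nComponents > 0) {
    losses["discC"] <- evalBin(params$dc, pr$c, ec$c)
    pc <- clipProb(sigmoid(netForward(params$dc, ec$c)$out[, 1]))
    losses["genC"] <- -mean(log(pc))
  }
  for (lv in levels) {
    p <- clipProb(softmaxRows(netForward(params$db[[lv]], ec$l)$out))
    ce <- -mean(rowSums(td$oh[[lv]] * log(p)))
    losses[paste0("discB.", lv)] <- ce
    losses[paste0("genB.", lv)] <- -ce
  }
  L <- cbind(ec$l, do.call(cbind, c(td$oh, list(matrix(0, n, 0)))))
  dcache <- decForward(params, L, td$s, cfg$thetaMode)
  losses["nll"] <- nbNllGrad(td$x, dcache$mu, dcache$theta)$nll
  losses["total"] <- losses["nll"] + cfg$lambdaZ * losses["genZ"] +
    (if (cfg$nComponents > 0) cfg$lambdaC * losses["genC"] else 0) +
    sum(vapply(levels, function(lv)
      lambdaForLevel(cfg, lv) * losses[paste0("genB.", lv)], numeric(1)))
  losses
}
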