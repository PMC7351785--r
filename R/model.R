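#' Configuration for the generative embedding model
#'
#' Defaults follow the model's recommended hyperparameters: a 10-dimensional
#' embedding, a 20-component Gaussian-mixture latent prior, one hidden layer
#' of 128 units, prior-matching strength 1e-3, and a negative binomial count
#' likelihood. `nComponents = 0` disables the categorical latent variable
#' (then l = z directly, standard-normal prior).
#'
#' @param latentDim Embedding dimensionality D (default 10).
#' @param nComponents Mixture components K (default 20; 0 disables c).
#' @param hiddenUnits Hidden layer width (default 128).
#' @param depth Number of hidden layers in encoder/decoder/discriminators
#'   (default 1).
#' @param lambdaPrior Prior-matching strength, shared by the z and c
#'   discriminators (default 0.001). `lambdaZ`/`lambdaC` override it.
#' @param lambdaZ,lambdaC Optional overrides of `lambdaPrior`.
#' @param lambdaBatch Batch-alignment strength; a single number applied to
#'   every batch level or a named vector `c(level = lambda)` (default 10; the
#'   reconstruction term is a sum over genes, so useful values are of order
#'   the selected-gene count divided by ten).
#' @param thetaMode `"gene-cell"`: the NB dispersion is a decoder output
#'   (depends on the embedding); `"gene"`: one free dispersion per gene.
#' @param posteriorSamples Number of posterior samples M per cell (default 50).
#' @param learningRate RMSProp learning rate (default 1e-3, no momentum).
#' @param batchSize Minibatch size (default 128).
#' @param epochs Training epochs (default 500).
#' @param seed Integer seed controlling initialization and stochastic training.
#' @return A list of class `ModelConfig`.
#' @export
modelConfig <- function(latentDim = 10, nComponents = 20, hiddenUnits = 128,
                        depth = 1, lambdaPrior = 0.001, lambdaZ = NULL,
                        lambdaC = NULL, lambdaBatch = 10,
                        thetaMode = c("gene-cell", "gene"),
                        posteriorSamples = 50, learningRate = 1e-3,
                        batchSize = 128, epochs = 500, seed = 0) {
  thetaMode <- match.arg(thetaMode)
  stopifnot(latentDim >= 1, nComponents >= 0, posteriorSamples >= 1,
            lambdaPrior >= 0, all(lambdaBatch >= 0), depth >= 1)
  structure(list(
    latentDim = latentDim, nComponents = nComponents,
    hiddenUnits = hiddenUnits, depth = depth,
    lambdaZ = if (is.null(lambdaZ)) lambdaPrior else lambdaZ,
    lambdaC = if (is.null(lambdaC)) lambdaPrior else lambdaC,
    lambdaBatch = lambdaBatch, thetaMode = thetaMode,
    posteriorSamples = posteriorSamples, learningRate = learningRate,
    batchSize = batchSize, epochs = epochs, seed = as.integer(seed)),
    class = c("ModelConfig", "list"))
}

#' CellScoutModel: the trained generative model
#'
#' Holds the encoder, decoder and discriminator parameters, the mixture
#' component matrix H (D x K), the ordered selected-gene contract, the batch
#' design the decoder conditions on, the configuration, and the training log.
#' Created by [fitModel()]; persisted with [saveModel()] / [loadModel()].
#'
#' @slot params Nested list of network parameters (enc, dec, H, dz, dc, db).
#' @slot genes Character vector: the model's ordered input genes (G*).
#' @slot batchInfo Named list: factor levels per batch level.
#' @slot config A `ModelConfig` list.
#' @slot trainingLog data.frame of per-epoch losses.
#' @slot null Cached empirical NPD null (numeric, sorted) or NULL.
#' @export
setClass("CellScoutModel", representation(
  params = "list", genes = "character", batchInfo = "list",
  config = "ANY", trainingLog = "data.frame", null = "ANY"))

setMethod("show", "CellScoutModel", function(object) {
  cfg <- object@config
  cat("CellScoutModel: D =", cfg$latentDim, ", K =", cfg$nComponents,
      ",", length(object@genes), "genes\n")
  cat("batch levels:",
      if (length(object@batchInfo))
        paste(names(object@batchInfo), vapply(object@batchInfo, length, 1L),
              sep = ":", collapse = " ")
      else "(none)", "\n")
  if (nrow(object@trainingLog))
    cat("trained", nrow(object@trainingLog), "epochs; final NLL",
        signif(utils::tail(object@trainingLog$nll, 1), 5), "\n")
})

#' @rdname accessors
#' @export
setMethod("selectedGenes", "CellScoutModel", function(x) x@genes)

# ---- likelihood primitives ------------------------------------------------

#' Negative binomial log-probability mass
#'
#' Sum over genes of the NB log-pmf with mean/dispersion parameterization
#' (mean mu, dispersion theta; variance mu + mu^2/theta), evaluated with
#' log-gamma arithmetic so counts up to 1e6 pose no overflow problem. For
#' mu = 0 the distribution degenerates to a point mass at x = 0.
#'
#' @param x Nonnegative integer counts (vector or matrix, cells x genes).
#' @param mu NB means, same shape (>= 0).
#' @param theta NB dispersions, same shape or recyclable (> 0).
#' @return Per-cell log-probability: scalar for vectors, numeric per row for
#'   matrices.
#' @export
nbLogPmf <- function(x, mu, theta) {
  if (any(x < 0)) stop("counts must be nonnegative")
  if (any(theta <= 0)) stop("theta must be positive")
  ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    ifelse(x == 0, 0, x * log(mu)) -
    (x + theta) * log(theta + mu) + theta * log(theta)
  # mu = 0: mass concentrated at zero
  ll[mu == 0 & x > 0] <- -Inf
  if (is.matrix(ll)) rowSums(ll) else sum(ll)
}

#' Log-density of the Gaussian-mixture latent prior
#'
#' The prior over embeddings l is an equally weighted mixture of K unit-
#' variance Gaussians with means in the columns of H; computed with
#' log-sum-exp. With K = 0 (categorical variable disabled) the prior is
#' standard normal.
#'
#' @param l Numeric vector (length D) or matrix (cells x D).
#' @param H D x K matrix of component means, or NULL / 0-column for K = 0.
#' @return Log-density (scalar or per-row vector).
#' @export
mixturePriorLogDensity <- function(l, H) {
  if (!is.matrix(l)) l <- matrix(l, nrow = 1)
  D <- ncol(l)
  if (is.null(H) || NCOL(H) == 0) {
    out <- -0.5 * rowSums(l^2) - 0.5 * D * log(2 * pi)
    return(if (length(out) == 1) out[[1]] else out)
  }
  stopifnot(nrow(H) == D)
  K <- ncol(H)
  # log N(l; H_k, I) per component
  comp <- vapply(seq_len(K), function(k)
    -0.5 * rowSums(sweep(l, 2, H[, k])^2) - 0.5 * D * log(2 * pi),
    numeric(nrow(l)))
  comp <- matrix(comp, nrow = nrow(l))
  out <- logSumExpRows(comp) - log(K)
  if (length(out) == 1) out[[1]] else out
}

# ---- model construction ---------------------------------------------------

# batchInfo: named list level -> character vector of factor levels
newModelParams <- function(nGenes, batchInfo, cfg) {
  D <- cfg$latentDim; K <- cfg$nComponents
  hid <- rep(cfg$hiddenUnits, cfg$depth)
  nB <- sum(vapply(batchInfo, length, numeric(1)))
  enc <- list(trunk = netInit(c(nGenes, hid)),
              z = denseInit(hid[length(hid)], D),
              c = if (K > 0) denseInit(hid[length(hid)], K) else NULL)
  decIn <- D + nB
  dec <- list(trunk = netInit(c(decIn, hid)),
              mu = denseInit(hid[length(hid)], nGenes),
              theta = if (cfg$thetaMode == "gene-cell")
                denseInit(hid[length(hid)], nGenes)
              else list(raw = numeric(nGenes)))
  dz <- netInit(c(D, hid, 1))
  dc <- if (K > 0) netInit(c(K, hid, 1)) else NULL
  db <- lapply(batchInfo, function(lv) netInit(c(D, hid, length(lv))))
  H <- if (K > 0) matrix(rnorm(D * K, sd = 0.1), D, K) else NULL
  list(enc = enc, dec = dec, H = H, dz = dz, dc = dc, db = db)
}

lambdaForLevel <- function(cfg, level) {
  lb <- cfg$lambdaBatch
  if (!is.null(names(lb)) && level %in% names(lb)) lb[[level]]
  else lb[[1]]
}

# ---- encoding -------------------------------------------------------------

# X: cells x |G*| matrix of log1p-transformed (perturbed) normalized counts.
encForward <- function(params, X) {
  tr <- netForward(params$enc$trunk, X)
  hTop <- lrelu(tr$out)  # trunk's last layer output activated
  z <- sweep(hTop %*% params$enc$z$W, 2, params$enc$z$b, "+")
  if (!is.null(params$enc$c)) {
    cLogit <- sweep(hTop %*% params$enc$c$W, 2, params$enc$c$b, "+")
    cSoft <- softmaxRows(cLogit)
    l <- z + cSoft %*% t(params$H)
  } else {
    cLogit <- NULL; cSoft <- NULL; l <- z
  }
  list(trunk = tr, hTop = hTop, z = z, cLogit = cLogit, c = cSoft, l = l)
}

# dl: gradient wrt l; dzExtra / dcExtra: additional gradients on z and the
# softmax c (e.g. from prior discriminators). Returns encoder+H grads and,
# optionally, the gradient wrt the input X.
encBackward <- function(params, cache, dl, dzExtra = NULL, dcExtra = NULL,
                        inputGrad = FALSE) {
  dz <- dl
  if (!is.null(dzExtra)) dz <- dz + dzExtra
  dH <- NULL
  dhTop <- dz %*% t(params$enc$z$W)
  gz <- list(W = crossprod(cache$hTop, dz), b = colSums(dz))
  gc <- NULL
  if (!is.null(params$enc$c)) {
    dc <- dl %*% params$H
    if (!is.null(dcExtra)) dc <- dc + dcExtra
    dH <- crossprod(dl, cache$c)  # D x K
    dcLogit <- softmaxRowsBackward(cache$c, dc)
    gc <- list(W = crossprod(cache$hTop, dcLogit), b = colSums(dcLogit))
    dhTop <- dhTop + dcLogit %*% t(params$enc$c$W)
  }
  # through the activation applied on top of the trunk's linear output
  dTrunkOut <- dhTop * lreluGrad(cache$trunk$out)
  bk <- netBackward(params$enc$trunk, cache$trunk, dTrunkOut,
                    inputGrad = inputGrad)
  list(grads = list(trunk = bk$grads, z = gz, c = gc), dH = dH, dX = bk$dX)
}

# ---- decoding -------------------------------------------------------------

# L: cells x (D + nB) matrix (embedding + batch one-hots); s: size factors.
decForward <- function(params, L, s, thetaMode) {
  tr <- netForward(params$dec$trunk, L)
  hTop <- lrelu(tr$out)
  muLogit <- sweep(hTop %*% params$dec$mu$W, 2, params$dec$mu$b, "+")
  p <- softmaxRows(muLogit)
  mu <- p * s  # rows scaled by size factor; rowSums(mu) == s
  if (thetaMode == "gene-cell") {
    thPre <- sweep(hTop %*% params$dec$theta$W, 2, params$dec$theta$b, "+")
    theta <- softplus(thPre) + 1e-4
  } else {
    thPre <- NULL
    theta <- matrix(softplus(params$dec$theta$raw) + 1e-4,
                    nrow(L), length(params$dec$theta$raw), byrow = TRUE)
  }
  list(trunk = tr, hTop = hTop, p = p, mu = mu, thPre = thPre, theta = theta,
       s = s)
}

decBackward <- function(params, cache, dMu, dTheta, thetaMode,
                        inputGrad = FALSE) {
  # mu = s * softmax(a): dL/da = s * p * (g - sum(p * g)) with g = dL/dmu
  g <- dMu * cache$s
  dMuLogit <- softmaxRowsBackward(cache$p, g)
  gmu <- list(W = crossprod(cache$hTop, dMuLogit), b = colSums(dMuLogit))
  dhTop <- dMuLogit %*% t(params$dec$mu$W)
  if (thetaMode == "gene-cell") {
    dThPre <- dTheta * sigmoid(cache$thPre)
    gth <- list(W = crossprod(cache$hTop, dThPre), b = colSums(dThPre))
    dhTop <- dhTop + dThPre %*% t(params$dec$theta$W)
  } else {
    gth <- list(raw = colSums(dTheta) * sigmoid(params$dec$theta$raw))
  }
  dTrunkOut <- dhTop * lreluGrad(cache$trunk$out)
  bk <- netBackward(params$dec$trunk, cache$trunk, dTrunkOut,
                    inputGrad = inputGrad)
  list(grads = list(trunk = bk$grads, mu = gmu, theta = gth), dX = bk$dX)
}

# NB negative log-likelihood (mean over cells) and gradients wrt mu/theta.
nbNllGrad <- function(x, mu, theta) {
  n <- nrow(x)
  ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    x * log(mu) - (x + theta) * log(theta + mu) + theta * log(theta)
  nll <- -sum(ll) / n
  dMu <- -(x / mu - (x + theta) / (theta + mu)) / n
  dTheta <- -(digamma(x + theta) - digamma(theta) - log(theta + mu) -
                (x + theta) / (theta + mu) + log(theta) + 1) / n
  list(nll = nll, dMu = dMu, dTheta = dTheta)
}

# ---- user-facing encode / decode -----------------------------------------

#' Encode cells into the embedding space
#'
#' Runs the stochastic encoder pipeline: library-size normalization to 1e4
#' over all supplied genes, optional Poisson perturbation (the source of
#' posterior stochasticity), log1p, the encoder network, and l = z + Hc.
#' In `"point"` mode the Poisson step is skipped (deterministic point
#' estimates).
#'
#' @param model A [CellScoutModel].
#' @param x A [CellScoutSet] or genes x cells matrix containing at least the
#'   model's genes (normalization uses all genes present in `x`).
#' @param mode `"point"` or `"stochastic"`.
#' @param seed Optional seed for the Poisson perturbation.
#' @return Cells x D matrix of embeddings.
#' @export
encodeCells <- function(model, x, mode = c("point", "stochastic"),
                        seed = NULL) {
  mode <- match.arg(mode)
  prep <- prepEncoderInput(model, x)
  if (mode == "stochastic") {
    if (!is.null(seed)) set.seed(seed)
    xt <- matrix(rpois(length(prep$xhat), prep$xhat), nrow(prep$xhat))
  } else xt <- prep$xhat
  emb <- encForward(model@params, log1p(xt))$l
  rownames(emb) <- prep$cells
  emb
}

# returns xhat (cells x |G*|) restricted to the model's genes, normalized
# over all genes in x
prepEncoderInput <- function(model, x) {
  if (methods::is(x, "CellScoutSet"))
    x <- SummarizedExperiment::assay(x, "counts")
  missing <- setdiff(model@genes, rownames(x))
  if (length(missing))
    stop("input lacks model genes: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) paste0(" (+", length(missing) - 5, " more)"))
  tot <- Matrix::colSums(x)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(head(colnamesOrIdx(x, which(tot == 0)), 5), collapse = ", "))
  xs <- t(as.matrix(x[model@genes, , drop = FALSE]))
  xhat <- xs * (1e4 / tot)
  list(xhat = xhat, cells = rownames(xhat),
       sizeFactors = rowSums(xs), counts = xs)
}

#' Decode embeddings into NB parameters
#'
#' Maps embeddings (plus batch one-hot indicators) to the negative binomial
#' mean and dispersion over the model's genes. The mean is a softmax over
#' genes scaled by the size factor, so each cell's means sum to its size
#' factor exactly.
#'
#' @param model A [CellScoutModel].
#' @param l Cells x D embedding matrix (or length-D vector).
#' @param batch Named list mapping each of the model's batch levels to a
#'   per-cell factor/character vector; or NULL when the model has no batch
#'   levels.
#' @param s Positive size factor(s), one per cell (recycled if scalar).
#' @return List with matrices `mu` and `theta` (cells x genes).
#' @export
decodeCells <- function(model, l, batch = NULL, s) {
  if (!is.matrix(l)) l <- matrix(l, nrow = 1)
  if (any(s <= 0)) stop("size factor s must be positive")
  s <- rep_len(s, nrow(l))
  oh <- batchDesignMatrix(model, batch, nrow(l))
  out <- decForward(model@params, cbind(l, oh), s, model@config$thetaMode)
  list(mu = unname(out$mu), theta = unname(out$theta))
}

batchDesignMatrix <- function(model, batch, n) {
  if (!length(model@batchInfo)) return(matrix(0, n, 0))
  cols <- lapply(names(model@batchInfo), function(lv) {
    lvs <- model@batchInfo[[lv]]
    if (is.null(batch) || is.null(batch[[lv]]))
      stop("batch assignment for level '", lv, "' required")
    f <- factor(rep_len(as.character(batch[[lv]]), n), levels = lvs)
    if (anyNA(f)) stop("unknown batch value in level '", lv, "'")
    oh <- matrix(0, n, length(lvs))
    oh[cbind(seq_len(n), as.integer(f))] <- 1
    oh
  })
  do.call(cbind, cols)
}

# ---- persistence ----------------------------------------------------------

#' Save / load a model directory
#'
#' A model is persisted as a directory holding `weights.rds` (the parameter
#' list), `config.json`, `genes.txt` (ordered gene contract), `batch.json`
#' and `training_log.csv`. Round-tripping reproduces point-estimate
#' embeddings bit-identically.
#'
#' @param model A [CellScoutModel].
#' @param dir Directory path.
#' @return `saveModel`: `dir` invisibly; `loadModel`: a [CellScoutModel].
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model@params, file.path(dir, "weights.rds"))
  jsonlite::write_json(model@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model@genes, file.path(dir, "genes.txt"))
  jsonlite::write_json(model@batchInfo, file.path(dir, "batch.json"))
  write.csv(model@trainingLog, file.path(dir, "training_log.csv"),
            row.names = FALSE)
  if (!is.null(model@null))
    saveRDS(model@null, file.path(dir, "null.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  class(cfg) <- c("ModelConfig", "list")
  lg <- file.path(dir, "training_log.csv")
  nl <- file.path(dir, "null.rds")
  methods::new("CellScoutModel",
               params = readRDS(file.path(dir, "weights.rds")),
               genes = readLines(file.path(dir, "genes.txt")),
               batchInfo = lapply(jsonlite::read_json(
                 file.path(dir, "batch.json"), simplifyVector = TRUE),
                 as.character),
               config = cfg,
               trainingLog = if (file.exists(lg)) read.csv(lg)
                             else data.frame(),
               null = if (file.exists(nl)) readRDS(nl) else NULL)
}
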