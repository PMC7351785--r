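# Internal dense-network machinery: initialization, forward/backward passes
# with hand-derived gradients, and an RMSProp optimizer. Kept deliberately
# small: every network in the model (encoder trunk + heads, decoder,
# discriminators) is a stack of dense layers with leaky-ReLU hidden
# activations, so one set of primitives serves them all.

LRELU_SLOPE <- 0.1

lrelu <- function(x) ifelse(x > 0, x, LRELU_SLOPE * x)
lreluGrad <- function(x) ifelse(x > 0, 1, LRELU_SLOPE)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

softmaxRows <- function(a) {
  m <- a - apply(a, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# d(loss)/d(logits) for p = softmaxRows(a) given upstream d(loss)/dp
softmaxRowsBackward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

logSumExpRows <- function(a) {
  m <- apply(a, 1, max)
  m + log(rowSums(exp(a - m)))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

denseInit <- function(nin, nout) list(W = glorot(nin, nout),
                                      b = numeric(nout))

# A net is a list of dense layers; hidden layers get leaky-ReLU, the last
# layer is linear (heads apply their own link functions).
netInit <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i)
    denseInit(sizes[i], sizes[i + 1]))
}

netForward <- function(net, X) {
  nl <- length(net)
  pres <- vector("list", nl)
  posts <- vector("list", nl + 1)
  posts[[1]] <- X
  for (i in seq_len(nl)) {
    pre <- posts[[i]] %*% net[[i]]$W
    pre <- sweep(pre, 2, net[[i]]$b, "+")
    pres[[i]] <- pre
    posts[[i + 1]] <- if (i < nl) lrelu(pre) else pre
  }
  list(out = posts[[nl + 1]], pres = pres, posts = posts)
}

netBackward <- function(net, cache, dOut, inputGrad = FALSE) {
  nl <- length(net)
  grads <- vector("list", nl)
  d <- dOut
  for (i in rev(seq_len(nl))) {
    if (i < nl) d <- d * lreluGrad(cache$pres[[i]])
    grads[[i]] <- list(W = crossprod(cache$posts[[i]], d),
                       b = colSums(d))
    if (i > 1 || inputGrad) d <- d %*% t(net[[i]]$W)
  }
  list(grads = grads, dX = if (inputGrad) d else NULL)
}

# ---- nested parameter-list arithmetic (for RMSProp over whole models) ----

zipMap <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      v <- if (is.null(a[[i]]) || is.null(b[[i]])) a[[i]]
           else zipMap(f, a[[i]], b[[i]])
      out[i] <- list(v)  # keeps NULL slots instead of deleting them
    }
    out
  } else f(a, b)
}

zerosLike <- function(a) {
  if (is.null(a)) NULL
  else if (is.list(a)) lapply(a, zerosLike)
  else a * 0
}

rmspropInit <- function(params) zerosLike(params)

# returns list(params, state); rho = 0.9, eps = 1e-8
rmspropStep <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  state <- zipMap(function(s, g) rho * s + (1 - rho) * g * g, state, grads)
  upd <- zipMap(function(g, s) lr * g / (sqrt(s) + eps), grads, state)
  params <- zipMap(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}

sumParams <- function(a, b) zipMap(`+`, a, b)

# squared L2 distance between two nested parameter lists (tuning penalty)
paramSqDist <- function(a, b) {
  if (is.list(a)) {
    s <- 0
    for (i in seq_along(a))
      if (!is.null(a[[i]]) && !is.null(b[[i]]))
        s <- s + paramSqDist(a[[i]], b[[i]])
    s
  } else sum((a - b)^2)
}
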