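# Closed-form analytics for adversarial batch alignment: the optimal batch
# discriminator and the generalized Jensen-Shannon divergence it implies.
# Used as oracles for the training code path and exported for analysis.

#' Batch mixture specification
#'
#' Bundles per-batch embedding densities with the batch proportions w. Each
#' density is either a function (evaluating the density at points given as a
#' matrix or vector) or, for discrete problems, a numeric probability vector
#' over a common support.
#'
#' @param densities List of length B: density functions or probability
#'   vectors (all of the same kind).
#' @param weights Numeric length B, nonnegative, summing to 1 (default:
#'   uniform).
#' @return A list of class `BatchMixture`.
#' @export
batchMixture <- function(densities, weights = NULL) {
  B <- length(densities)
  if (B < 1) stop("need at least one component density")
  if (is.null(weights)) weights <- rep(1 / B, B)
  if (length(weights) != B) stop("weights/density length mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  discrete <- is.numeric(densities[[1]])
  if (discrete) {
    len <- unique(vapply(densities, length, numeric(1)))
    if (length(len) != 1) stop("discrete components must share a support")
  }
  structure(list(densities = densities, weights = weights,
                 discrete = discrete), class = "BatchMixture")
}

.evalDensities <- function(mixture, l) {
  if (mixture$discrete) {
    # l indexes the common support
    vapply(mixture$densities, function(d) d[l], numeric(length(l)))
  } else {
    vapply(mixture$densities, function(f) as.numeric(f(l)), numeric(NROW(l)))
  }
}

#' Optimal batch discriminator output
#'
#' The batch discriminator that maximizes the adversarial objective outputs,
#' at every embedding point, the weighted relative density of each batch:
#' `w_i q(l | b = i) / sum_k w_k q(l | b = k)`.
#'
#' @param mixture A [batchMixture()].
#' @param l Evaluation point(s): a vector/matrix for functional densities, or
#'   support indices for discrete ones.
#' @return A simplex vector of length B (or a matrix, rows = points).
#' @export
optimalDiscriminator <- function(mixture, l) {
  q <- .evalDensities(mixture, l)
  q <- matrix(q, ncol = length(mixture$weights))
  num <- sweep(q, 2, mixture$weights, "*")
  tot <- rowSums(num)
  if (any(tot == 0))
    stop("all component densities are zero at the evaluation point")
  out <- num / tot
  if (nrow(out) == 1) out[1, ] else out
}

#' Generalized Jensen-Shannon divergence of a batch mixture
#'
#' `sum_i w_i KL(q_i || sum_k w_k q_k)`, the quantity adversarial batch
#' alignment minimizes: nonnegative, zero iff all per-batch embedding
#' distributions coincide, and bounded above by `-sum_i w_i log w_i`
#' (disjoint supports). The adversarial objective at the optimal
#' discriminator equals this value plus `sum_i w_i log w_i`.
#'
#' For functional densities the KL terms are estimated by sample averages
#' over draws supplied in `support` (a list of per-component sample
#' matrices); discrete distributions are evaluated exactly.
#'
#' @param mixture A [batchMixture()].
#' @param support For discrete mixtures: ignored. For functional ones: a
#'   list of length B of sample matrices, one per component, drawn from that
#'   component.
#' @return Nonnegative scalar.
#' @export
generalizedJSD <- function(mixture, support = NULL) {
  w <- mixture$weights
  if (mixture$discrete) {
    Q <- do.call(cbind, mixture$densities)  # support x B
    mix <- as.numeric(Q %*% w)
    kl <- vapply(seq_along(w), function(i) {
      qi <- Q[, i]
      pos <- qi > 0
      sum(qi[pos] * log(qi[pos] / mix[pos]))
    }, numeric(1))
    return(max(0, sum(w * kl)))
  }
  if (is.null(support) || length(support) != length(w))
    stop("functional mixtures need one sample set per component")
  kl <- vapply(seq_along(w), function(i) {
    s <- support[[i]]
    qi <- as.numeric(mixture$densities[[i]](s))
    qall <- .evalDensities(mixture, s)
    mix <- as.numeric(matrix(qall, ncol = length(w)) %*% w)
    mean(log(qi / mix))
  }, numeric(1))
  max(0, sum(w * kl))
}
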