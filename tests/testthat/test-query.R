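test_that("wasserstein1Empirical solves 1-D transport", {
  u <- rnorm(10)
  expect_equal(wasserstein1Empirical(u, u), 0)
  expect_equal(wasserstein1Empirical(u, u + 3.5), 3.5)
  expect_equal(wasserstein1Empirical(u, u - 2), 2)
  # exact assignment oracle on 100 random equal-size instances
  set.seed(13)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    a <- rnorm(n); b <- rnorm(n, 1)
    expect_equal(wasserstein1Empirical(a, b), oracleW1(a, b),
                 tolerance = 1e-8)
  }
  # unequal sizes via the quantile formulation
  expect_equal(wasserstein1Empirical(0, c(1, 3)), 2)
  expect_error(wasserstein1Empirical(numeric(0), 1), "empty")
})

test_that("npd matches the frozen step-by-step evaluation", {
  # 2-D anisotropic clouds with point estimates 2 apart along x; the frozen
  # value was computed by independent spreadsheet-style arithmetic
  # (projection, per-cell z-normalization, sorted-sample W1, average)
  p <- list(point = c(0, 0),
            samples = rbind(c(-0.5, 1.0), c(0.3, -0.2), c(0.1, 0.4),
                            c(-0.2, -0.8), c(0.4, 0.1)))
  q <- list(point = c(2, 0),
            samples = rbind(c(1.5, 0.3), c(2.5, -0.4), c(2.2, 0.9),
                            c(1.8, -0.2), c(2.1, 0.2)))
  expect_equal(npd(p, q), 5.3099187896, tolerance = 1e-9)
  expect_equal(npd(p, q), npd(q, p))
})

test_that("npd is symmetric, zero at identity and zero at coincidence", {
  set.seed(17)
  mk <- function(center) list(point = center,
                              samples = matrix(rnorm(40, sd = 0.5), 20, 2) +
                                rep(center, each = 20))
  p <- mk(c(0, 0))
  expect_equal(npd(p, p), 0)
  for (i in 1:10) {
    a <- mk(rnorm(2)); b <- mk(rnorm(2))
    expect_equal(npd(a, b), npd(b, a))
    expect_gte(npd(a, b), 0)
  }
  # coincident point estimates define NPD = 0
  a <- mk(c(1, 1)); b <- mk(c(1, 1))
  expect_equal(npd(a, b), 0)
  # degenerate projected spread is reported
  flat <- list(point = c(0, 0), samples = matrix(0, 5, 2))
  tgt <- mk(c(2, 0))
  expect_error(npd(flat, tgt), "posterior samples")
})

test_that("npd is monotone in Euclidean distance for isotropic posteriors", {
  set.seed(19)
  n <- 60; D <- 3; M <- 400
  pts <- matrix(rnorm(n * D, sd = 3), n, D)
  samples <- array(0, c(n, M, D))
  for (i in seq_len(n))
    samples[i, , ] <- matrix(rnorm(M * D, sd = 0.4), M, D) +
      rep(pts[i, ], each = M)
  pe <- new("PosteriorEmbedding", points = pts, samples = samples)
  ref <- .asCell <- function(i) list(point = pts[i, ], samples = samples[i, , ])
  npds <- c(); eucs <- c()
  for (i in 2:n) {
    npds <- c(npds, npd(pe, pe, cell = 1, cell2 = i))
    eucs <- c(eucs, sqrt(sum((pts[1, ] - pts[i, ])^2)))
  }
  expect_gt(cor(npds, eucs, method = "spearman"), 0.99)
})

test_that("knnCandidates agrees with exhaustive search", {
  set.seed(23)
  ref <- matrix(rnorm(200), 100, 2,
                dimnames = list(paste0("r", 1:100), NULL))
  q <- rnorm(2)
  got <- knnCandidates(ref, q, 7)
  expect_equal(got$index, oracleKnn(ref, q, 7))
  expect_equal(got$id, paste0("r", got$index))
  # a query equal to a reference point ranks it first
  expect_equal(knnCandidates(ref, ref[42, ], 3)$index[1], 42)
  # k = reference size returns everything
  expect_setequal(knnCandidates(ref, q, 100)$index, 1:100)
  expect_error(knnCandidates(ref, q, 101), "exceeds")
  expect_error(knnCandidates(ref[0, , drop = FALSE], q, 1), "empty")
})

test_that("the empirical null is seeded, sorted and nonnegative", {
  set.seed(29)
  n <- 80; D <- 2; M <- 30
  pts <- matrix(rnorm(n * D), n, D)
  samples <- array(rnorm(n * M * D, sd = 0.5), c(n, M, D)) +
    aperm(array(rep(t(pts), M), c(D, n, M)), c(2, 3, 1))
  pe <- new("PosteriorEmbedding", points = pts, samples = samples)
  n1 <- buildEmpiricalNull(pe, nPairs = 500, seed = 3)
  n2 <- buildEmpiricalNull(pe, nPairs = 500, seed = 3)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))
  expect_false(is.unsorted(n1$values))
  # single-cluster isotropic fixture: the null median is stable across seeds
  m1 <- median(buildEmpiricalNull(pe, nPairs = 2000, seed = 1)$values)
  m2 <- median(buildEmpiricalNull(pe, nPairs = 2000, seed = 2)$values)
  expect_lt(abs(m1 - m2) / m1, 0.2)
})

test_that("hitPvalue follows add-one rank arithmetic", {
  null <- structure(list(values = sort(runif(999)), nPairs = 999, seed = 0),
                    class = "NullDistribution")
  expect_equal(hitPvalue(-1, null), 1 / 1000)
  expect_equal(hitPvalue(2, null), 1)
  med <- median(null$values)
  expect_equal(hitPvalue(med, null), 0.5, tolerance = 3 / 999)
  # monotone in the NPD value
  v <- hitPvalue(c(0.1, 0.5, 0.9), null)
  expect_true(all(diff(v) > 0))
})

test_that("consensus with duplicated copies of one model is unchanged", {
  fx <- fxSmallModel()
  cs <- fx$cs
  qry <- cs[, 1:15]
  ref <- cs[, 16:300]
  h1 <- consensusQuery(fx$model, qry, ref, k = 10, nPairs = 300, seed = 2)
  h2 <- consensusQuery(list(fx$model, fx$model), qry, ref, k = 10,
                       nPairs = 300, seed = 2)
  expect_equal(h1, h2)
})

test_that("predictDiscrete applies min-hits and strict majority rules", {
  mkHits <- function(labels, sig = TRUE, p = 0.01) {
    data.frame(query = "q1", ref = paste0("r", seq_along(labels)),
               euclidean = 1, npd = 1, pvalue = p,
               significant = rep_len(sig, length(labels)))
  }
  labs <- function(labels) setNames(labels, paste0("r", seq_along(labels)))
  # 0 or 1 significant hits: rejected
  expect_equal(predictDiscrete(mkHits("a", sig = FALSE), labs("a"))$status,
               "rejected")
  expect_equal(predictDiscrete(mkHits("a"), labs("a"))$status, "rejected")
  # 5 hits, 4 shared: predicted at 0.8 > 0.5
  r <- predictDiscrete(mkHits(c("a", "a", "a", "a", "b")),
                       labs(c("a", "a", "a", "a", "b")))
  expect_equal(r$status, "predicted")
  expect_equal(r$label, "a")
  # 2/2 split: 0.5 is not > 0.5
  r2 <- predictDiscrete(mkHits(c("a", "a", "b", "b")),
                        labs(c("a", "a", "b", "b")))
  expect_equal(r2$status, "ambiguous")
})

test_that("predictContinuous averages significant hits on the simplex", {
  hits <- data.frame(query = "q1", ref = c("r1", "r2"), euclidean = 1,
                     npd = 1, pvalue = 0.01, significant = TRUE)
  vec <- rbind(r1 = c(1, 0), r2 = c(0, 1))
  out <- predictContinuous(hits, vec)
  expect_equal(unname(out$predictions["q1", ]), c(0.5, 0.5))
  expect_equal(unname(out$status["q1"]), "predicted")
  # identical vectors return that vector
  vec2 <- rbind(r1 = c(0.3, 0.7), r2 = c(0.3, 0.7))
  expect_equal(unname(predictContinuous(hits, vec2)$predictions["q1", ]),
               c(0.3, 0.7))
  # simplex closure on random simplex inputs
  set.seed(31)
  v <- matrix(rgamma(10 * 4, 1), 10, 4)
  v <- v / rowSums(v)
  rownames(v) <- paste0("r", 1:10)
  h <- data.frame(query = "q1", ref = rownames(v), euclidean = 1, npd = 1,
                  pvalue = 0.01, significant = TRUE)
  p <- predictContinuous(h, v)$predictions["q1", ]
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # below min-hits: rejected with NA prediction
  h2 <- h[1, , drop = FALSE]
  out2 <- predictContinuous(h2, v)
  expect_equal(unname(out2$status["q1"]), "rejected")
  expect_true(all(is.na(out2$predictions)))
})
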