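test_that("averagePrecision matches the running-precision formula", {
  expect_equal(averagePrecision("a", c("a", "a", "a")), 1)
  expect_equal(averagePrecision("a", c("b", "b")), 0)
  # (match, miss, match): (1 + 2/3) / 2
  expect_equal(averagePrecision("a", c("a", "b", "a")), 5 / 6)
  set.seed(59)
  for (i in 1:1000) {
    y <- sample(c("a", "b"), 1)
    yk <- sample(c("a", "b"), sample(1:8, 1), replace = TRUE)
    expect_equal(averagePrecision(y, yk), oracleAP(y, yk))
  }
})

test_that("mapScore reduces to nearest-neighbor accuracy at K = 1", {
  set.seed(61)
  for (i in 1:20) {
    n <- 40
    emb <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(c("x", "y", "z"), n, replace = TRUE)
    nnAcc <- mean(vapply(seq_len(n), function(j) {
      d <- colSums((t(emb) - emb[j, ])^2)
      d[j] <- Inf
      lab[order(d, seq_along(d))[1]] == lab[j]
    }, logical(1)))
    expect_equal(mapScore(emb, lab, k = 1), nnAcc)
  }
})

test_that("mapScore is 1 on separated clusters and ~0.5 on random labels", {
  set.seed(67)
  emb <- rbind(matrix(rnorm(200), 100, 2),
               matrix(rnorm(200, 50), 100, 2))
  lab <- rep(c("a", "b"), each = 100)
  expect_equal(mapScore(emb, lab, k = 20), 1)
  # random balanced labels: matches the permutation baseline computed with
  # the brute-force average-precision oracle (AP of a random K-neighborhood
  # exceeds the 0.5 base rate because early matches weigh more)
  n <- 2000
  emb2 <- matrix(rnorm(n * 2), n, 2)
  lab2 <- rep(c("a", "b"), n / 2)
  K <- max(1, round(0.01 * n))
  baseline <- mean(vapply(1:4000, function(i)
    oracleAP("a", sample(c("a", "b"), K, replace = TRUE)), numeric(1)))
  expect_equal(mapScore(emb2, lab2), baseline, tolerance = 0.05)
  # rigid rotation leaves the score unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(mapScore(emb %*% R, lab, k = 20), mapScore(emb, lab, k = 20))
})

test_that("the alignment score formula hits its analytic bounds", {
  # total separation: every neighbor from one's own batch
  expect_equal(alignmentScoreValue(xbar = 10, k = 10, nBatches = 2), 0)
  # perfect mixing: same-batch neighbors at the chance rate k/N
  expect_equal(alignmentScoreValue(xbar = 5, k = 10, nBatches = 2), 1)
  expect_equal(alignmentScoreValue(xbar = 10 / 3, k = 10, nBatches = 3), 1)
  # clipped to [0, 1]
  expect_equal(alignmentScoreValue(xbar = 2, k = 10, nBatches = 2), 1)
})

test_that("seuratAlignmentScore sees mixing and separation", {
  set.seed(71)
  emb <- matrix(rnorm(400), 200, 2)
  interleaved <- rep(c("b1", "b2"), 100)
  expect_gt(seuratAlignmentScore(emb, interleaved, k = 10, seed = 1), 0.9)
  separated <- rbind(matrix(rnorm(200), 100, 2),
                     matrix(rnorm(200, 100), 100, 2))
  expect_lt(seuratAlignmentScore(separated, rep(c("b1", "b2"), each = 100),
                                 k = 10, seed = 1), 0.05)
  # rotation invariance
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(seuratAlignmentScore(emb %*% R, interleaved, k = 10, seed = 1),
               seuratAlignmentScore(emb, interleaved, k = 10, seed = 1))
  expect_error(seuratAlignmentScore(emb, interleaved, k = 150, seed = 1),
               "smaller k")
  expect_error(seuratAlignmentScore(emb, rep("b1", 200)), "2 batches")
})

test_that("mba averages per-type accuracies against the expectation matrix", {
  M <- matrix(0, 4, 4,
              dimnames = list(c("t1", "t2", "neg1", "neg2"),
                              c("t1", "t2", "other", "rejected")))
  M["t1", "t1"] <- 1; M["t2", "t2"] <- 1
  M["neg1", "rejected"] <- 1; M["neg2", "rejected"] <- 1
  actual <- c(rep("t1", 2), rep("t2", 4), rep("neg1", 5))
  predicted <- c("t1", "t1", "t2", "t2", "other", "other", rep("rejected", 4),
                 "t1")
  out <- mba(actual, predicted, M, positiveTypes = c("t1", "t2"),
             negativeTypes = c("neg1", "neg2"))
  expect_equal(out$mbaPositive, mean(c(1, 0.5)))
  expect_equal(out$mbaNegative, 0.8)
  expect_equal(out$overall, (0.75 + 0.8) / 2)
  # ambiguous counts as rejection
  out2 <- mba("neg1", "ambiguous", M, c("t1", "t2"), c("neg1", "neg2"))
  expect_equal(out2$mbaNegative, 1)
  expect_error(mba("unknown", "t1", M, "t1", "neg1"), "indexable")
})

test_that("jsd is a bounded symmetric divergence", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2))
  set.seed(73)
  for (i in 1:20) {
    a <- rgamma(4, 1); a <- a / sum(a)
    b <- rgamma(4, 1); b <- b / sum(b)
    expect_equal(jsd(a, b), jsd(b, a))
    expect_gte(jsd(a, b), 0)
    expect_lte(jsd(a, b), log(2) + 1e-12)
  }
  # sqrt(jsd) satisfies the triangle inequality on random triples
  for (i in 1:20) {
    a <- rgamma(3, 1); a <- a / sum(a)
    b <- rgamma(3, 1); b <- b / sum(b)
    cc <- rgamma(3, 1); cc <- cc / sum(cc)
    expect_lte(sqrt(jsd(a, cc)),
               sqrt(jsd(a, b)) + sqrt(jsd(b, cc)) + 1e-12)
  }
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(jsd(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
})

test_that("enrichmentRatio implements the printed ratio and its reciprocal", {
  # class at the same rate overall and among rejections
  expect_equal(enrichmentRatio(10, 100, 5, 50), 1)
  # worked case: (19/1000) / (14/134)
  expect_equal(enrichmentRatio(19, 1000, 14, 134), 0.1818571,
               tolerance = 1e-6)
  # scaling all counts leaves the ratio unchanged
  expect_equal(enrichmentRatio(190, 10000, 140, 1340),
               enrichmentRatio(19, 1000, 14, 134))
  expect_equal(rejectionEnrichment(19, 1000, 14, 134),
               1 / enrichmentRatio(19, 1000, 14, 134))
  expect_error(enrichmentRatio(0, 10, 1, 5), "positive")
})
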