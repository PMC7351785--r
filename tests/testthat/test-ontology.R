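test_that("readOBO builds the DAG, dropping obsolete terms", {
  chain <- writeOboFixture(c(
    "[Term]", "id: A", "name: leaf", "is_a: B ! middle", "",
    "[Term]", "id: B", "name: middle", "is_a: C ! root", "",
    "[Term]", "id: C", "name: root"))
  g <- readOBO(chain)
  expect_equal(length(g@terms), 3)
  expect_equal(igraph::ecount(g@graph), 2)
  expect_setequal(descendants(g, "C"), c("A", "B", "C"))
  expect_setequal(ancestors(g, "A"), c("A", "B", "C"))
  # diamond: two paths, ancestor counted once
  diamond <- writeOboFixture(c(
    "[Term]", "id: D", "is_a: P1", "is_a: P2", "",
    "[Term]", "id: P1", "is_a: R", "",
    "[Term]", "id: P2", "is_a: R", "",
    "[Term]", "id: R"))
  gd <- readOBO(diamond)
  expect_setequal(descendants(gd, "R"), c("D", "P1", "P2", "R"))
  expect_equal(length(ancestors(gd, "D")), 4)
  # obsolete terms and their edges disappear
  obs <- writeOboFixture(c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "",
    "[Term]", "id: X", "is_a: B", "is_obsolete: true"))
  go <- readOBO(obs)
  expect_false("X" %in% go@terms)
  # a cycle is an error naming an edge
  cyc <- writeOboFixture(c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A"))
  expect_error(readOBO(cyc), "cycle")
})

test_that("the bundled toy ontology has the advertised structure", {
  g <- toyOntology()
  expect_true(igraph::is_dag(g@graph))
  expect_setequal(descendants(g, "T:root"), g@terms)
  # diamond: both paths from T:lymphB reach T:immune; counted once
  expect_equal(sum(ancestors(g, "T:lymphB") == "T:immune"), 1)
  expect_setequal(ancestors(g, "T:lymphB"),
                  c("T:lymphB", "T:lymphoid", "T:immuneB", "T:immune",
                    "T:root"))
  expect_equal(termDepth(g, "T:root"), 0)
  expect_equal(termDepth(g, "T:lymphT4"), 4)
  expect_equal(termDepth(g, "T:lymphBmem"), 4)
})

test_that("base confidence scores are similarity-normalized", {
  g <- toyOntology()
  one <- data.frame(pvalue = 0, term = "T:lymphT4")
  expect_equal(blast2coBaseScores(one, g),
               c("T:lymphT4" = 1))
  two <- data.frame(pvalue = c(0.2, 0.2), term = c("T:lymphT4", "T:mono"))
  sc <- blast2coBaseScores(two, g)
  expect_equal(unname(sc[c("T:lymphT4", "T:mono")]), c(0.5, 0.5))
  set.seed(37)
  hits <- data.frame(pvalue = runif(12),
                     term = sample(g@terms, 12, replace = TRUE))
  expect_equal(sum(blast2coBaseScores(hits, g)), 1)
  allRejected <- data.frame(pvalue = c(1, 1), term = c("T:mono", "T:dc"))
  expect_identical(blast2coBaseScores(allRejected, g), "rejected")
})

test_that("propagation sums descendant scores once and is monotone", {
  g <- toyOntology()
  sc <- c("T:lymphT4" = 0.3, "T:lymphT8" = 0.1, "T:lymphB" = 0.6)
  pr <- propagateScores(sc, g)
  expect_equal(unname(pr["T:root"]), 1)
  expect_equal(unname(pr["T:lymphT"]), 0.4)
  # diamond: T:lymphB's 0.6 reaches T:immune once, not twice
  expect_equal(unname(pr["T:immune"]), 1)
  expect_equal(unname(pr["T:immuneB"]), 0.6)
  # leaves keep their base scores
  expect_equal(unname(pr["T:lymphT4"]), 0.3)
  # monotone along every is_a edge
  ed <- igraph::as_edgelist(g@graph)
  for (i in seq_len(nrow(ed))) {
    child <- pr[ed[i, 1]]; parent <- pr[ed[i, 2]]
    if (!is.na(child) && !is.na(parent))
      expect_gte(unname(parent), unname(child))
  }
})

test_that("blast2coPredict picks the deepest confident subgraph leaf", {
  g <- toyOntology()
  # all hits share one deep term
  pr <- propagateScores(c("T:lymphT4" = 1), g)
  expect_equal(blast2coPredict(pr, g, minDepth = 3), "T:lymphT4")
  # sibling leaves tied above threshold: ambiguous
  pr2 <- propagateScores(c("T:lymphT4" = 0.5, "T:lymphT8" = 0.5), g)
  expect_equal(blast2coPredict(pr2, g, threshold = 0.4, minDepth = 3),
               "ambiguous")
  # nothing over the threshold: rejected
  pr3 <- propagateScores(c("T:lymphT4" = 0.3, "T:mono" = 0.3,
                           "T:fibro" = 0.4), g)
  expect_equal(blast2coPredict(pr3, g, threshold = 0.9, minDepth = 5),
               "rejected")
  # with threshold 0 and minDepth 0 hits always yield a term or a tie
  set.seed(41)
  for (i in 1:10) {
    hits <- data.frame(pvalue = runif(6, 0, 0.9),
                       term = sample(g@terms, 6, replace = TRUE))
    pr4 <- propagateScores(blast2coBaseScores(hits, g), g)
    expect_false(identical(blast2coPredict(pr4, g, threshold = 0,
                                           minDepth = 0), "rejected"))
  }
  # the depth requirement suppresses coarse calls: scores concentrated on a
  # shallow term are rejected at minDepth 3
  pr5 <- propagateScores(c("T:stromal" = 1), g)
  expect_equal(blast2coPredict(pr5, g, minDepth = 3), "rejected")
  expect_equal(blast2coPredict(pr5, g, minDepth = 1), "T:stromal")
})

test_that("clAccuracy gives full, partial and zero credit per the rules", {
  g <- toyOntology()
  ref <- c("T:lymphT4", "T:mono")
  # exact match and descendant predictions score 1
  expect_equal(clAccuracy("T:lymphT4", "T:lymphT4", g, ref), 1)
  expect_equal(clAccuracy("T:lymphT", "T:lymphT4", g, ref), 1)
  # unrelated sibling branch scores 0
  expect_equal(clAccuracy("T:lymphT4", "T:fibro", g, ref), 0)
  # ancestor prediction: actual T:lymphT4 (|desc| = 1) predicted as
  # T:lymphT (|desc| = 3); intermediates {T:lymphT4, T:lymphT} are both
  # reference-inferable via T:lymphT4, so the credit is mean(1/3, 3/3) = 2/3
  expect_equal(clAccuracy("T:lymphT4", "T:lymphT", g, ref), 2 / 3)
  # negative actual term: rejection is the correct call
  expect_equal(clAccuracy("T:fibro", "rejected", g, ref), 1)
  expect_equal(clAccuracy("T:fibro", "T:fibro", g, ref), 0)
  expect_error(clAccuracy("nope", "T:mono", g, ref), "not in ontology")
})

test_that("clMBA balances over distinct actual terms", {
  g <- toyOntology()
  ref <- c("T:lymphT4", "T:mono")
  perfect <- data.frame(actual = c("T:lymphT4", "T:mono"),
                        predicted = c("T:lymphT4", "T:mono"))
  expect_equal(clMBA(perfect, g, ref), 1)
  # one term right, one wrong: 0.5 regardless of cell counts
  mixed <- data.frame(actual = c("T:lymphT4", "T:mono"),
                      predicted = c("T:lymphT4", "T:fibro"))
  expect_equal(clMBA(mixed, g, ref), 0.5)
  imbalanced <- data.frame(
    actual = c(rep("T:lymphT4", 10), "T:mono"),
    predicted = c(rep("T:lymphT4", 10), "T:fibro"))
  expect_equal(clMBA(imbalanced, g, ref), 0.5)
})
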