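test_that("normalizeInput rescales cells to 1e4 over all genes", {
  expect_equal(normalizeInput(c(0, 5, 0)), c(0, 1e4, 0))
  expect_equal(normalizeInput(c(1, 1, 2)), c(2500, 2500, 5000))
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(50, 3) + c(1, numeric(49))
    expect_equal(sum(normalizeInput(x)), 1e4)
  }
  # idempotent up to scale: normalizing twice equals once
  x <- rpois(30, 5) + 1
  expect_equal(normalizeInput(normalizeInput(x)), normalizeInput(x))
  # matrix form, column cells
  m <- matrix(c(1, 1, 2, 0, 5, 0), 3, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(colSums(normalizeInput(m))), c(1e4, 1e4))
  expect_error(normalizeInput(c(0, 0)), "all-zero")
  m[, 2] <- 0
  expect_error(normalizeInput(m), "b")
})

test_that("sizeFactor sums raw counts over the selected genes", {
  expect_equal(sizeFactor(c(a = 0, b = 0, c = 0), c("a", "b")), 0)
  expect_equal(sizeFactor(c(a = 1, b = 3, c = 4), c("b", "c")), 7)
  set.seed(2)
  x <- setNames(rpois(20, 4), paste0("g", 1:20))
  expect_lte(sizeFactor(x, paste0("g", 1:7)), sum(x))
  expect_error(sizeFactor(x, character(0)), "empty")
  m <- matrix(1:6, 3, dimnames = list(c("a", "b", "c"), c("x", "y")))
  expect_equal(sizeFactor(m, c("a", "c")), c(4, 10))
})

test_that("CellScoutSet enforces its invariants", {
  m <- matrix(rpois(40, 2), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  cs <- CellScoutSet(m, colData = data.frame(donor = rep(c("a", "b"), 5)),
                     batchLevels = "donor")
  expect_s4_class(cs, "CellScoutSet")
  expect_identical(batchLevels(cs), "donor")
  bo <- batchOneHot(cs, "donor")
  expect_equal(rowSums(bo$onehot), setNames(rep(1, 10), colnames(m)))
  expect_equal(sum(bo$weights), 1)
  selectedGenes(cs) <- c("g1", "g3")
  expect_identical(selectedGenes(cs), c("g1", "g3"))
  expect_error(selectedGenes(cs) <- "nope", "not present")
  bad <- m; bad[1, 1] <- -1
  expect_error(CellScoutSet(bad), "nonnegative")
  dup <- m; rownames(dup) <- rep("g1", 4)
  expect_error(CellScoutSet(dup), "unique")
  expect_error(CellScoutSet(m, batchLevels = "missing"), "missing")
  # sparse input is preserved
  sp <- CellScoutSet(Matrix::Matrix(m, sparse = TRUE))
  expect_s4_class(SummarizedExperiment::assay(sp, "counts"), "sparseMatrix")
})

test_that("selectVariableGenes recovers planted high-dispersion genes", {
  set.seed(7)
  G <- 200; n <- 500
  mu <- exp(rnorm(G, 1, 1))
  theta <- rep(100, G)
  hi <- sample(G, 20)
  theta[hi] <- 0.3
  cts <- matrix(rnbinom(G * n, mu = mu, size = theta), G, n,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("c%03d", 1:n)))
  sel <- selectVariableGenes(cts)
  expect_gte(sum(rownames(cts)[hi] %in% sel), 18)
  # constant gene is never selected
  cts2 <- rbind(cts, constant = rep(5, n))
  expect_false("constant" %in% selectVariableGenes(cts2))
  # invariance to cell and gene permutation (as sets)
  perm <- cts[sample(G), sample(n)]
  expect_setequal(selectVariableGenes(perm), sel)
})

test_that("one variance-inflated gene is picked out of its bin", {
  # 50-gene toy with near-identical means; brute-force z-score oracle
  set.seed(11)
  n <- 200
  cts <- matrix(rpois(50 * n, 20), 50, n,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:n)))
  cts[17, ] <- rnbinom(n, mu = 20, size = 0.2)  # variance inflated ~100x
  sel <- selectVariableGenes(cts, geneSelectionParams(nBins = 5))
  expect_true("g17" %in% sel)
  # oracle: recompute dispersions on the same transform, z-score globally
  ln <- log1p(1e4 * sweep(cts, 2, colSums(cts), "/"))
  disp <- apply(ln, 1, var) / rowMeans(ln)
  expect_equal(unname(which.max(disp)), 17)
})

test_that("poolGenesAcrossBatches applies the inclusive fraction rule", {
  expect_true("g" %in% poolGenesAcrossBatches(list(c("g"), c("x")), 0.5))
  expect_false("g" %in% poolGenesAcrossBatches(list("g", "x", "y"), 0.5))
  sets <- list(c("a", "b"), c("b", "c"), c("b", "d"))
  expect_setequal(poolGenesAcrossBatches(sets, 0), c("a", "b", "c", "d"))
  expect_identical(poolGenesAcrossBatches(sets, 1), "b")
  expect_identical(poolGenesAcrossBatches(list(character(0), character(0))),
                   character(0))
  expect_error(poolGenesAcrossBatches(list()), "no per-batch")
})

test_that("mergeDatasets unions selections and intersects detected genes", {
  mk <- function(genes, cells, sel) {
    m <- matrix(rpois(length(genes) * cells, 3), length(genes),
                dimnames = list(genes, paste0(cells, "_", seq_len(cells))))
    colnames(m) <- paste0("c", seq_len(cells), "x", cells)
    CellScoutSet(m, selectedGenes = sel)
  }
  d1 <- mk(c("A", "B", "C"), 5, c("A", "B"))
  d2 <- mk(c("B", "C"), 6, c("B", "C"))
  merged <- mergeDatasets(list(x = d1, y = d2))
  expect_setequal(selectedGenes(merged), c("B", "C"))
  expect_setequal(rownames(merged), c("B", "C"))
  expect_true("dataset" %in% batchLevels(merged))
  expect_equal(ncol(merged), 11)
  # identical datasets: merged selection equals either
  m2 <- mergeDatasets(list(a = d1, b = d1))
  expect_setequal(selectedGenes(m2), selectedGenes(d1))
  # gene map collapsing two names into one group
  d3 <- mk(c("A1", "B"), 5, "A1")
  d4 <- mk(c("A2", "B"), 5, "A2")
  map <- c(A1 = "A", A2 = "A", B = "B")
  m3 <- mergeDatasets(list(p = d3, q = d4), geneMap = map)
  expect_setequal(rownames(m3), c("A", "B"))
  expect_identical(selectedGenes(m3), "A")
  # disjoint gene sets cannot merge
  d5 <- mk(c("X", "Y"), 5, "X")
  expect_error(mergeDatasets(list(d1, d5)), "no genes detected")
})

test_that("MTX and dense readers round-trip a dataset", {
  sim <- simulateDataset(simulationDesign(nCells = 30, nGenes = 15, seed = 4))
  dir <- tempfile()
  writeMTXSet(sim$data, dir)
  back <- readMTXSet(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sim$data, "counts")))
  # dense CSV with cells as rows
  csv <- tempfile(fileext = ".csv")
  write.csv(t(as.matrix(SummarizedExperiment::assay(sim$data, "counts"))),
            csv)
  dense <- readDenseSet(csv)
  expect_equal(rownames(dense), rownames(sim$data))
  # gene map reader
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tG1", "geneB\tG1"), tsv)
  gm <- readGeneMap(tsv)
  expect_identical(gm, c(geneA = "G1", geneB = "G1"))
})
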