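#' Design of a synthetic negative-binomial scRNA-seq dataset
#'
#' Specifies the planted structure of a simulated UMI count matrix: discrete
#' clusters with their own expression programs and marker genes, one or more
#' multiplicative per-gene batch effects, log-normal library sizes and a
#' shared NB dispersion. Defaults describe a small, clearly clustered tissue:
#' 2000 cells, 200 genes, 3 equally sized clusters whose programs differ in a
#' tenth of the genes, 5 planted 8-fold markers per cluster, two batches with
#' moderate (sigma 0.5) per-gene log-normal effects, median library ~2000
#' counts and NB dispersion theta = 10.
#'
#' @param nCells,nGenes,nClusters Dataset dimensions.
#' @param clusterProportions Cluster proportions (default equal; must sum
#'   to 1).
#' @param deGenesFraction Fraction of genes whose log-mean differs between
#'   clusters (default 0.1).
#' @param deLogSd Standard deviation of the cluster-specific log-mean shifts
#'   (default 1).
#' @param markersPerCluster,markerFoldChange Planted marker genes per cluster
#'   and their fold change (default 5 markers at 8x).
#' @param batchLevels Named list: level name -> number of batches (default
#'   `list(batch = 2)`); batches are assigned uniformly at random.
#' @param batchLogSd Per-gene log-normal batch-effect scale sigma_b
#'   (default 0.5; 0 disables batch effects).
#' @param libMeanLog,libSdLog Log-normal library-size parameters (defaults
#'   log(2000) and 0.3).
#' @param theta NB dispersion (default 10; variance mu + mu^2/theta).
#' @param cellNoiseSd Per-cell log-mean noise (default 0.1).
#' @param nLineages If > 0, per-cell Dirichlet fate vectors are attached
#'   (default 0).
#' @param seed RNG seed.
#' @return A list of class `SimulationDesign`.
#' @export
simulationDesign <- function(nCells = 2000, nGenes = 200, nClusters = 3,
                             clusterProportions = NULL,
                             deGenesFraction = 0.1, deLogSd = 1,
                             markersPerCluster = 5, markerFoldChange = 8,
                             batchLevels = list(batch = 2), batchLogSd = 0.5,
                             libMeanLog = log(2000), libSdLog = 0.3,
                             theta = 10, cellNoiseSd = 0.1, nLineages = 0,
                             seed = 0) {
  if (is.null(clusterProportions))
    clusterProportions <- rep(1 / nClusters, nClusters)
  stopifnot(nCells > 0, nGenes > 0, nClusters > 0,
            abs(sum(clusterProportions) - 1) < 1e-8, theta > 0,
            markerFoldChange > 1)
  structure(list(nCells = nCells, nGenes = nGenes, nClusters = nClusters,
                 clusterProportions = clusterProportions,
                 deGenesFraction = deGenesFraction, deLogSd = deLogSd,
                 markersPerCluster = markersPerCluster,
                 markerFoldChange = markerFoldChange,
                 batchLevels = batchLevels, batchLogSd = batchLogSd,
                 libMeanLog = libMeanLog, libSdLog = libSdLog, theta = theta,
                 cellNoiseSd = cellNoiseSd, nLineages = nLineages,
                 seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate a dataset with planted structure
#'
#' Counts are drawn from a negative binomial whose mean is the cell's library
#' size times a softmax over genes of (cluster log-profile + per-gene batch
#' effect + per-cell noise), with fixed dispersion theta. The returned ground
#' truth records cluster and batch memberships and the planted marker genes.
#' Deterministic under the design seed.
#'
#' @param design A [simulationDesign()].
#' @return List with `data` (a [CellScoutSet] whose colData has `cell_type`,
#'   the batch levels, and fate-vector columns when requested) and `truth`
#'   (markers per cluster, cluster log-profiles, library sizes).
#' @export
simulateDataset <- function(design) {
  d <- design
  if (d$nCells <= 0 || d$nGenes <= 0) stop("degenerate design")
  set.seed(d$seed)
  genes <- sprintf("gene%03d", seq_len(d$nGenes))
  cells <- sprintf("cell%04d", seq_len(d$nCells))
  base <- rnorm(d$nGenes, 0, 1)
  nDE <- max(1, round(d$deGenesFraction * d$nGenes))
  profiles <- matrix(rep(base, d$nClusters), d$nGenes, d$nClusters)
  markers <- vector("list", d$nClusters)
  for (kk in seq_len(d$nClusters)) {
    de <- sample.int(d$nGenes, nDE)
    profiles[de, kk] <- profiles[de, kk] + rnorm(nDE, 0, d$deLogSd)
    # markers go on decently expressed genes so the fold change is visible
    eligible <- setdiff(which(base >= stats::median(base)), de)
    mk <- sample(eligible, d$markersPerCluster)
    profiles[mk, kk] <- profiles[mk, kk] + log(d$markerFoldChange)
    markers[[kk]] <- genes[mk]
  }
  names(markers) <- paste0("type", seq_len(d$nClusters))
  cluster <- sample(seq_len(d$nClusters), d$nCells, replace = TRUE,
                    prob = d$clusterProportions)
  batchAssign <- list(); batchEffects <- list()
  for (lv in names(d$batchLevels)) {
    B <- d$batchLevels[[lv]]
    batchAssign[[lv]] <- sample(seq_len(B), d$nCells, replace = TRUE)
    batchEffects[[lv]] <- matrix(rnorm(d$nGenes * B, 0, d$batchLogSd),
                                 d$nGenes, B)
  }
  lib <- stats::rlnorm(d$nCells, d$libMeanLog, d$libSdLog)
  logm <- profiles[, cluster, drop = FALSE]
  for (lv in names(d$batchLevels))
    logm <- logm + batchEffects[[lv]][, batchAssign[[lv]], drop = FALSE]
  logm <- logm + matrix(rnorm(d$nCells * d$nGenes, 0, d$cellNoiseSd),
                        d$nGenes, d$nCells)
  p <- exp(logm)
  p <- sweep(p, 2, colSums(p), "/")
  mu <- sweep(p, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = d$theta),
                   d$nGenes, d$nCells, dimnames = list(genes, cells))
  cd <- data.frame(cell_type = paste0("type", cluster),
                   row.names = cells, stringsAsFactors = FALSE)
  for (lv in names(d$batchLevels))
    cd[[lv]] <- paste0(lv, batchAssign[[lv]])
  if (d$nLineages > 0) {
    fate <- simulateFateVectors(d$nCells, d$nLineages, concentration = 0.5)
    colnames(fate) <- paste0("fate", seq_len(d$nLineages))
    cd <- cbind(cd, fate)
  }
  data <- CellScoutSet(counts, colData = cd,
                       batchLevels = names(d$batchLevels))
  list(data = data,
       truth = list(cluster = paste0("type", cluster), markers = markers,
                    profiles = profiles, library = lib,
                    batch = lapply(batchAssign, function(a)
                      paste0("b", a))))
}

#' Dirichlet cell-fate probability vectors
#'
#' Symmetric Dirichlet draws over lineages: small concentrations yield mostly
#' committed (near one-hot, low entropy) cells, large concentrations mostly
#' undifferentiated (uniform, high entropy) ones; intermediate values mix
#' both regimes.
#'
#' @param nCells Number of cells.
#' @param nLineages Number of terminal lineages (>= 2).
#' @param concentration Symmetric Dirichlet parameter (default 0.5).
#' @return nCells x nLineages matrix, rows on the probability simplex.
#' @export
simulateFateVectors <- function(nCells, nLineages, concentration = 0.5) {
  if (nLineages < 2) stop("need at least 2 lineages")
  g <- matrix(rgamma(nCells * nLineages, shape = concentration, rate = 1),
              nCells, nLineages)
  # guard against all-zero rows at tiny concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) {
    g[zero, ] <- 0
    g[cbind(which(zero), sample.int(nLineages, sum(zero), replace = TRUE))] <- 1
  }
  g / rowSums(g)
}

#' A small fixed ontology for tests and examples
#'
#' 15 terms, three-plus depth levels, containing a diamond (two is_a paths
#' from `T:lymphB` through `T:lymphoid` and `T:immuneB` to `T:immune`) so
#' closure logic is exercised.
#'
#' @return An [OntologyGraph].
#' @export
toyOntology <- function() {
  ids <- c("T:root", "T:immune", "T:stromal", "T:lymphoid", "T:myeloid",
           "T:immuneB", "T:lymphB", "T:lymphT", "T:lymphT4", "T:lymphT8",
           "T:mono", "T:dc", "T:fibro", "T:peri", "T:lymphBmem")
  labels <- c("cell", "immune cell", "stromal cell", "lymphoid cell",
              "myeloid cell", "B-lineage cell", "B cell", "T cell",
              "CD4 T cell", "CD8 T cell", "monocyte", "dendritic cell",
              "fibroblast", "pericyte", "memory B cell")
  edges <- data.frame(
    from = c("T:immune", "T:stromal", "T:lymphoid", "T:myeloid", "T:immuneB",
             "T:lymphB", "T:lymphB", "T:lymphT", "T:lymphT4", "T:lymphT8",
             "T:mono", "T:dc", "T:fibro", "T:peri", "T:lymphBmem"),
    to = c("T:root", "T:root", "T:immune", "T:immune", "T:immune",
           "T:lymphoid", "T:immuneB", "T:lymphoid", "T:lymphT", "T:lymphT",
           "T:myeloid", "T:myeloid", "T:stromal", "T:stromal", "T:lymphB"),
    stringsAsFactors = FALSE)
  .newOntology(ids, labels, edges)
}
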