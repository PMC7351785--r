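# Memoized expensive fixtures (trained models) shared across test files.
# Problem sizes are desk scale: hidden layer 32 units, 100-150 epochs.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# 2000 cells, 200 genes, 3 clusters, 2 batches (generator defaults)
fxClusterSet <- function() fixture("clusterSet", function() {
  sim <- simulateDataset(simulationDesign(seed = 101))
  cs <- sim$data
  selectedGenes(cs) <- selectVariableGenes(cs, perBatch = "batch")
  list(cs = cs, sim = sim,
       ct = as.character(SummarizedExperiment::colData(cs)$cell_type),
       bt = as.character(SummarizedExperiment::colData(cs)$batch))
})

fxAlignedModel <- function() fixture("alignedModel", function() {
  fx <- fxClusterSet()
  fitModel(fx$cs, modelConfig(hiddenUnits = 32, epochs = 150, seed = 11))
})

fxUnalignedModel <- function() fixture("unalignedModel", function() {
  fx <- fxClusterSet()
  fitModel(fx$cs, modelConfig(hiddenUnits = 32, epochs = 150, seed = 11,
                              lambdaBatch = 0))
})

# 4-model ensemble on a 5-type reference with one type withheld, plus the
# held-out query split (seen type1 cells are excluded from the reference).
# Five types keep the empirical null dominated by cross-type pairs, the
# regime reference atlases live in.
fxQuerySplit <- function() fixture("querySplit", function() {
  sim <- simulateDataset(simulationDesign(nClusters = 5, seed = 101))
  cs <- sim$data
  selectedGenes(cs) <- selectVariableGenes(cs, perBatch = "batch")
  ct <- as.character(SummarizedExperiment::colData(cs)$cell_type)
  qSeen <- which(ct == "type1")[1:100]
  qNovel <- which(ct == "type5")[1:100]
  refIdx <- setdiff(which(ct != "type5"), qSeen)
  ref <- cs[, refIdx]
  qry <- cs[, c(qSeen, qNovel)]
  models <- lapply(1:4, function(m)
    fitModel(ref, modelConfig(hiddenUnits = 32, epochs = 120, seed = 20 + m)))
  list(ref = ref, qry = qry, models = models,
       seen = colnames(cs)[qSeen], novel = colnames(cs)[qNovel],
       refLabels = setNames(ct[refIdx], colnames(ref)))
})

fxQueryHits <- function() fixture("queryHits", function() {
  q <- fxQuerySplit()
  consensusQuery(q$models, q$qry, q$ref, k = 50, cutoff = 0.05,
                 nPairs = 5000, seed = 7)
})

# reference / batch-shifted query pair for online tuning
fxTuneSetup <- function() fixture("tuneSetup", function() {
  sim <- simulateDataset(simulationDesign(
    nCells = 1200, nGenes = 200, nClusters = 3,
    batchLevels = list(run = 2), batchLogSd = 0.8, seed = 5))
  cs <- sim$data
  run <- as.character(SummarizedExperiment::colData(cs)$run)
  ref <- cs[, run == "run1"]
  # the reference is treated as single-batch; the run shift is the
  # query-vs-reference batch effect online tuning must absorb
  refS <- CellScoutSet(SummarizedExperiment::assay(ref, "counts"),
                       colData = as.data.frame(
                         SummarizedExperiment::colData(ref)))
  selectedGenes(refS) <- selectVariableGenes(refS)
  qry <- cs[, run == "run2"]
  model <- suppressWarnings(
    fitModel(refS, modelConfig(hiddenUnits = 32, epochs = 60, seed = 7)))
  list(ref = refS, qry = qry, model = model,
       refType = as.character(SummarizedExperiment::colData(refS)$cell_type))
})

# marker-dominant fixture for interpretability: one 8x marker per cluster on
# a decently expressed gene; cluster DE shifts kept below the marker's
fxMarkerSetup <- function() fixture("markerSetup", function() {
  sim <- simulateDataset(simulationDesign(
    nCells = 1200, nGenes = 200, nClusters = 3, markersPerCluster = 1,
    markerFoldChange = 8, deLogSd = 0.5, batchLevels = list(), seed = 21))
  cs <- sim$data
  selectedGenes(cs) <- rownames(cs)
  models <- lapply(1:2, function(m)
    suppressWarnings(fitModel(cs, modelConfig(
      hiddenUnits = 32, epochs = 80, lambdaBatch = numeric(0), seed = m))))
  list(cs = cs, models = models, marker = sim$truth$markers$type2)
})

# a small trained model for cheap unit checks
fxSmallModel <- function() fixture("smallModel", function() {
  sim <- simulateDataset(simulationDesign(nCells = 300, nGenes = 120,
                                          nClusters = 2, seed = 33))
  cs <- sim$data
  selectedGenes(cs) <- selectVariableGenes(cs)
  model <- suppressWarnings(
    fitModel(cs, modelConfig(hiddenUnits = 16, epochs = 30, seed = 3,
                             posteriorSamples = 25)))
  list(cs = cs, model = model)
})
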