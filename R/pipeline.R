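#' End-to-end train / query / annotate workflow
#'
#' Trains an ensemble of models with different starting points (default 4) on
#' the reference, builds each model's empirical NPD null, runs consensus
#' querying, transfers the discrete annotation, and writes everything (model
#' directories, `hits.csv`, `pred.csv` and a JSON run manifest capturing the
#' configuration, seeds and package version) into `outDir`. Reruns with the
#' same inputs and seed reproduce the outputs.
#'
#' @param reference A [CellScoutSet] with selected genes and a label column.
#' @param query A [CellScoutSet] (or counts matrix).
#' @param outDir Output directory.
#' @param labelColumn colData column to transfer (default `"cell_type"`).
#' @param nModels Ensemble size (default 4).
#' @param config Base [modelConfig()]; model m trains with seed
#'   `config$seed + m - 1`.
#' @param k,cutoff,nPairs Passed to [consensusQuery()].
#' @return Invisibly, a list with `hits`, `predictions` and the manifest.
#' @export
runPipeline <- function(reference, query, outDir,
                        labelColumn = "cell_type", nModels = 4,
                        config = modelConfig(), k = 50, cutoff = 0.05,
                        nPairs = 10000) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  models <- lapply(seq_len(nModels), function(m) {
    cfg <- config
    cfg$seed <- config$seed + m - 1L
    model <- fitModel(reference, cfg)
    saveModel(model, file.path(outDir, sprintf("model%02d", m)))
    model
  })
  hits <- consensusQuery(models, query, reference, k = k, cutoff = cutoff,
                         nPairs = nPairs, seed = config$seed)
  labels <- setNames(
    as.character(SummarizedExperiment::colData(reference)[[labelColumn]]),
    colnames(reference))
  pred <- predictDiscrete(hits, labels)
  write.csv(hits, file.path(outDir, "hits.csv"), row.names = FALSE)
  write.csv(pred, file.path(outDir, "pred.csv"), row.names = FALSE)
  manifest <- list(
    command = "runPipeline",
    package = as.character(utils::packageVersion("CellScout")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, nModels = nModels, k = k, cutoff = cutoff,
    nPairs = nPairs, labelColumn = labelColumn,
    config = unclass(config),
    nReferenceCells = ncol(reference),
    nQueryCells = if (methods::is(query, "CellScoutSet")) ncol(query)
                  else ncol(query))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(hits = hits, predictions = pred, manifest = manifest,
                 models = models))
}
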