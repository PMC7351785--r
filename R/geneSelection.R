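#' Parameters for informative-gene selection
#'
#' Dispersion-based selection in the style of mean-variance-relationship
#' methods: genes are binned by mean expression, dispersions are z-scored
#' within each bin, and genes above a z cutoff are kept.
#'
#' @param binningMethod `"equal_frequency"` (default) or `"equal_width"`
#'   binning of gene means.
#' @param nBins Number of mean-expression bins (default 20).
#' @param dispersionZCutoff Within-bin dispersion z-score cutoff (default 0.5).
#' @param minBatchFraction When pooling per-batch selections, the fraction of
#'   batches a gene must be selected in to be retained (default 0.5,
#'   inclusive).
#' @return A list of class `GeneSelectionParams`.
#' @export
geneSelectionParams <- function(binningMethod = c("equal_frequency", "equal_width"),
                                nBins = 20, dispersionZCutoff = 0.5,
                                minBatchFraction = 0.5) {
  binningMethod <- match.arg(binningMethod)
  stopifnot(nBins >= 1, minBatchFraction >= 0, minBatchFraction <= 1)
  structure(list(binningMethod = binningMethod, nBins = nBins,
                 dispersionZCutoff = dispersionZCutoff,
                 minBatchFraction = minBatchFraction),
            class = "GeneSelectionParams")
}

#' Select highly variable (informative) genes
#'
#' Computes, per gene, the mean and the dispersion (variance/mean) of
#' log1p-transformed library-size-normalized expression, bins genes by mean
#' (equal-frequency by default), z-scores dispersions within each bin, and
#' returns the genes whose z-score exceeds the cutoff. All-zero genes are
#' dropped before binning; bins with fewer than two genes are merged into the
#' adjacent lower-mean bin so z-scores are defined. If `perBatch` is a
#' registered batch level, selection is run independently per batch and the
#' per-batch sets are pooled with [poolGenesAcrossBatches()].
#'
#' The result is deterministic and invariant to cell/gene ordering; genes are
#' returned in decreasing dispersion z-score order.
#'
#' @param x A [CellScoutSet] or genes x cells matrix.
#' @param params A [geneSelectionParams()] list.
#' @param perBatch Optional batch level name (CellScoutSet input only).
#' @return Character vector of selected gene names.
#' @export
selectVariableGenes <- function(x, params = geneSelectionParams(),
                                perBatch = NULL) {
  if (methods::is(x, "CellScoutSet")) {
    cts <- SummarizedExperiment::assay(x, "counts")
    if (!is.null(perBatch)) {
      f <- factor(SummarizedExperiment::colData(x)[[perBatch]])
      sets <- lapply(levels(f), function(lv)
        .selectVariableGenesMatrix(cts[, f == lv, drop = FALSE], params))
      return(poolGenesAcrossBatches(sets, params$minBatchFraction))
    }
    return(.selectVariableGenesMatrix(cts, params))
  }
  .selectVariableGenesMatrix(x, params)
}

.selectVariableGenesMatrix <- function(cts, params) {
  if (ncol(cts) < 2) stop("need at least 2 cells for dispersion estimation")
  cts <- as.matrix(cts)
  # log1p of library-size-normalized expression
  ln <- log1p(normalizeInput(cts))
  mu <- rowMeans(ln)
  v <- apply(ln, 1, var)
  keep <- mu > 0
  mu <- mu[keep]; v <- v[keep]
  genes <- rownames(cts)[keep]
  disp <- v / mu
  if (length(genes) == 0) return(character(0))
  bins <- .assignBins(mu, params$nBins, params$binningMethod)
  bins <- .mergeSmallBins(bins, mu)
  z <- rep(NA_real_, length(disp))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    if (is.na(s) || s == 0) z[idx] <- 0
    else z[idx] <- (disp[idx] - mean(disp[idx])) / s
  }
  sel <- z > params$dispersionZCutoff
  out <- genes[sel][order(z[sel], decreasing = TRUE)]
  out
}

.assignBins <- function(mu, nBins, method) {
  nBins <- min(nBins, length(mu))
  if (method == "equal_width") {
    br <- seq(min(mu), max(mu), length.out = nBins + 1)
    br[1] <- br[1] - 1e-9
    as.integer(cut(mu, breaks = br))
  } else {
    qs <- unique(quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
    qs[1] <- qs[1] - 1e-9
    as.integer(cut(mu, breaks = qs))
  }
}

# merge bins with < 2 members into the adjacent lower-mean bin
.mergeSmallBins <- function(bins, mu) {
  repeat {
    tab <- table(bins)
    small <- as.integer(names(tab)[tab < 2])
    if (!length(small) || length(tab) == 1) break
    b <- small[1]
    ord <- sort(unique(bins))
    pos <- match(b, ord)
    target <- if (pos > 1) ord[pos - 1] else ord[pos + 1]
    bins[bins == b] <- target
  }
  bins
}

#' Pool per-batch gene selections
#'
#' A gene is retained if it was selected in at least `minBatchFraction` of
#' the batches (inclusive; the default 0.5 keeps a gene selected in 1 of 2
#' batches). Fraction 0 yields the union, fraction 1 the intersection.
#'
#' @param sets List of character vectors (per-batch selections).
#' @param minBatchFraction Fraction in \[0, 1\].
#' @return Character vector of pooled genes (stable order: by decreasing
#'   selection count, then first appearance).
#' @export
poolGenesAcrossBatches <- function(sets, minBatchFraction = 0.5) {
  if (length(sets) == 0) stop("no per-batch selections supplied")
  all <- unique(unlist(sets))
  if (!length(all)) return(character(0))
  cnt <- vapply(all, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), numeric(1))
  keep <- cnt / length(sets) >= minBatchFraction
  all[keep][order(cnt[keep], decreasing = TRUE)]
}

#' Read a gene / ortholog mapping table
#'
#' Two-column TSV without header: source gene name, shared group id. Used to
#' harmonize gene names across datasets (e.g. cross-species orthologs).
#'
#' @param path Path to the TSV file.
#' @return A named character vector mapping source names to group ids.
#' @export
readGeneMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("source", "group"), quote = "")
  setNames(as.character(df$group), df$source)
}

#' Merge multiple datasets into one
#'
#' Gene names are harmonized (optionally through a `geneMap` collapsing
#' source names into shared group ids; counts of names mapping to the same
#' group are summed). The merged matrix keeps the genes detected in every
#' dataset; the merged selected-gene set is the union of per-dataset
#' selections intersected with that common detected set. Dataset of origin is
#' recorded as a new batch level (`"dataset"` by default); existing batch
#' levels present in all datasets are retained.
#'
#' @param datasets Named list of [CellScoutSet] objects (>= 2).
#' @param geneMap Optional named character vector from [readGeneMap()].
#' @param datasetLevel Name of the new batch level recording origin.
#' @return A merged [CellScoutSet].
#' @export
mergeDatasets <- function(datasets, geneMap = NULL, datasetLevel = "dataset") {
  if (length(datasets) < 2) stop("need at least 2 datasets to merge")
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  mapped <- lapply(datasets, function(d) {
    cts <- SummarizedExperiment::assay(d, "counts")
    sel <- selectedGenes(d)
    if (!is.null(geneMap)) {
      hit <- rownames(cts) %in% names(geneMap)
      cts <- cts[hit, , drop = FALSE]
      grp <- geneMap[rownames(cts)]
      cts <- rowsumByGroup(cts, grp)
      sel <- unique(geneMap[intersect(sel, names(geneMap))])
    }
    list(counts = cts, selected = sel, cd = SummarizedExperiment::colData(d))
  })
  detected <- Reduce(intersect, lapply(mapped, function(m) rownames(m$counts)))
  if (!length(detected))
    stop("no genes detected in all datasets (per-dataset gene counts: ",
         paste(vapply(mapped, function(m) nrow(m$counts), numeric(1)),
               collapse = ", "), ")")
  selUnion <- unique(unlist(lapply(mapped, function(m) m$selected)))
  selMerged <- intersect(selUnion, detected)
  counts <- do.call(cbind, lapply(mapped, function(m)
    m$counts[detected, , drop = FALSE]))
  origin <- rep(names(datasets),
                vapply(mapped, function(m) ncol(m$counts), numeric(1)))
  colnames(counts) <- make.unique(unlist(lapply(seq_along(mapped), function(i)
    paste(names(datasets)[i], colnames(mapped[[i]]$counts), sep = "."))))
  commonLevels <- Reduce(intersect, lapply(datasets, batchLevels))
  cdCols <- Reduce(intersect, lapply(mapped, function(m) colnames(m$cd)))
  cd <- data.frame(row.names = colnames(counts))
  for (col in cdCols)
    cd[[col]] <- unlist(lapply(mapped, function(m) m$cd[[col]]))
  cd[[datasetLevel]] <- origin
  CellScoutSet(counts, colData = cd,
               batchLevels = c(commonLevels, datasetLevel),
               selectedGenes = selMerged)
}

rowsumByGroup <- function(cts, grp) {
  dense <- as.matrix(cts)
  out <- rowsum(dense, group = grp)
  out[order(rownames(out)), , drop = FALSE]
}
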