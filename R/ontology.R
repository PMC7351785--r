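#' OntologyGraph: is_a DAG of ontology terms
#'
#' Directed acyclic graph of ontology terms with child-to-parent `is_a`
#' edges, as parsed from an OBO 1.2 file by [readOBO()] or built by
#' [toyOntology()]. Descendant/ancestor queries are inclusive (a term is its
#' own descendant), matching the partial order used by the ontology-aware
#' accuracy metric.
#'
#' @slot graph An igraph with vertex attribute `name` (term id) and `label`.
#' @slot terms Character vector of term ids (deterministic order).
#' @export
setClass("OntologyGraph", representation(graph = "ANY", terms = "character"))

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph:", length(object@terms), "terms,",
      igraph::ecount(object@graph), "is_a edges,",
      sum(igraph::degree(object@graph, mode = "out") == 0), "root(s)\n")
})

.newOntology <- function(ids, labels, edges) {
  ord <- order(ids)
  ids <- ids[ord]; labels <- labels[ord]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, label = labels,
                          stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    e <- igraph::ends(g, cyc[1])
    stop("ontology contains a cycle (e.g. edge ", e[1], " -> ", e[2], ")")
  }
  methods::new("OntologyGraph", graph = g, terms = ids)
}

#' Read an OBO 1.2 ontology file
#'
#' Consumes `[Term]` stanzas only: `id`, `name`, `is_a` and `is_obsolete`
#' lines. Obsolete terms (and edges touching them) are dropped. Cycles are an
#' error.
#'
#' @param path Path to the OBO file.
#' @return An [OntologyGraph].
#' @export
readOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); labels <- character(0); obsolete <- character(0)
  edges <- list()
  cur <- NULL; inTerm <- FALSE
  flush <- function() {}
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # strip OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") { inTerm <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { inTerm <- FALSE; next }
    if (!inTerm || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      ids <- c(ids, cur); labels <- c(labels, "")
    } else if (!is.null(cur) && grepl("^name:", ln)) {
      labels[length(labels)] <- trimws(sub("^name:", "", ln))
    } else if (!is.null(cur) && grepl("^is_a:", ln)) {
      parent <- trimws(sub("^is_a:", "", ln))
      edges[[length(edges) + 1]] <- c(cur, parent)
    } else if (!is.null(cur) && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- c(obsolete, cur)
    }
  }
  keep <- !ids %in% obsolete
  ids <- ids[keep]; labels <- labels[keep]
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), 0, 2)
  em <- em[em[, 1] %in% ids & em[, 2] %in% ids, , drop = FALSE]
  .newOntology(ids, labels,
               data.frame(from = em[, 1], to = em[, 2],
                          stringsAsFactors = FALSE))
}

#' Descendant and ancestor sets (inclusive)
#'
#' `descendants(g, term)` returns all terms t with t is_a* term, including
#' the term itself; `ancestors` the converse. Multiple paths (diamonds) count
#' each term once.
#'
#' @param g An [OntologyGraph].
#' @param term A term id.
#' @return Character vector of term ids.
#' @export
descendants <- function(g, term) {
  .checkTerms(g, term)
  sort(names(igraph::subcomponent(g@graph, term, mode = "in")))
}

#' @rdname descendants
#' @export
ancestors <- function(g, term) {
  .checkTerms(g, term)
  sort(names(igraph::subcomponent(g@graph, term, mode = "out")))
}

.checkTerms <- function(g, terms) {
  bad <- setdiff(terms, g@terms)
  if (length(bad))
    stop("term(s) not in ontology: ", paste(head(bad, 5), collapse = ", "))
}

# is a <= b (a is_a* b, inclusive)?
isDescendant <- function(g, a, b) a %in% descendants(g, b)

#' Longest path length from a term to a root
#'
#' @param g An [OntologyGraph].
#' @param term Term id.
#' @return Integer edge count of the longest is_a path to any root.
#' @export
termDepth <- function(g, term) {
  .checkTerms(g, term)
  anc <- ancestors(g, term)
  sub <- igraph::induced_subgraph(g@graph, anc)
  # longest path in a DAG by topological order
  topo <- igraph::topo_sort(sub, mode = "out")
  depth <- setNames(rep(0L, length(topo)), names(topo))
  for (v in names(topo)) {
    for (p in names(igraph::neighbors(sub, v, mode = "out")))
      depth[p] <- max(depth[p], depth[v] + 1L)
  }
  max(depth)
}

#' Hit-based base confidence scores
#'
#' For every ontology term among the hits, the confidence is the sum of hit
#' similarities (1 - p-value) of hits carrying that term, normalized by the
#' total over all hits, so base scores sum to 1.
#'
#' @param hits data.frame with columns `pvalue` and `term`.
#' @param g An [OntologyGraph] containing all hit terms.
#' @return Named numeric vector of base confidences, or the string
#'   `"rejected"` sentinel when every hit has p-value 1 (zero similarity).
#' @export
blast2coBaseScores <- function(hits, g) {
  if (!nrow(hits)) stop("no hits supplied")
  .checkTerms(g, unique(hits$term))
  sim <- 1 - hits$pvalue
  tot <- sum(sim)
  if (tot == 0) return("rejected")
  sc <- tapply(sim, hits$term, sum) / tot
  setNames(as.numeric(sc), names(sc))
}

#' Propagate confidence scores to ancestors
#'
#' A term's propagated confidence is the sum of base scores of all annotated
#' terms in its inclusive descendant set; multiple is_a paths count a
#' descendant once, and confidences are monotone nondecreasing from child to
#' parent (the root collects everything, score 1).
#'
#' @param scores Named base-score vector from [blast2coBaseScores()].
#' @param g An [OntologyGraph].
#' @return Named numeric vector over all terms with nonzero confidence.
#' @export
propagateScores <- function(scores, g) {
  .checkTerms(g, names(scores))
  out <- numeric(0)
  touched <- unique(unlist(lapply(names(scores), function(t) ancestors(g, t))))
  for (t in touched) {
    dset <- descendants(g, t)
    out[t] <- sum(scores[intersect(names(scores), dset)])
  }
  out
}

#' Ontology-aware cell-type call from propagated confidences
#'
#' Retains terms whose propagated confidence exceeds `threshold`, forming an
#' induced subgraph; its leaves (terms none of whose is_a children are in the
#' subgraph) deeper than `minDepth` (longest path to root) are candidates.
#' The unique maximal-confidence candidate is the prediction; tied maxima
#' give `"ambiguous"`, no candidate gives `"rejected"`.
#'
#' @param propagated Named confidence vector from [propagateScores()].
#' @param g An [OntologyGraph].
#' @param threshold Confidence threshold (strict >, default 0.5).
#' @param minDepth Minimal longest-path-to-root depth (default 3).
#' @param tol Tie tolerance on confidences (default 1e-12).
#' @return A term id, `"ambiguous"`, or `"rejected"`.
#' @export
blast2coPredict <- function(propagated, g, threshold = 0.5, minDepth = 3,
                            tol = 1e-12) {
  if (identical(propagated, "rejected")) return("rejected")
  sub <- names(propagated)[propagated > threshold]
  if (!length(sub)) return("rejected")
  isLeaf <- vapply(sub, function(t) {
    kids <- names(igraph::neighbors(g@graph, t, mode = "in"))
    !any(kids %in% sub)
  }, logical(1))
  cand <- sub[isLeaf]
  cand <- cand[vapply(cand, function(t) termDepth(g, t) >= minDepth,
                      logical(1))]
  if (!length(cand)) return("rejected")
  mx <- max(propagated[cand])
  top <- cand[propagated[cand] >= mx - tol]
  if (length(top) > 1) "ambiguous" else top
}

#' Ontology-aware accuracy of one prediction
#'
#' For a positive query term (related to the reference terms by is_a in
#' either direction): a prediction that is the term itself or one of its
#' descendants scores 1; a strict ancestor prediction receives partial credit
#' equal to the mean, over the reference-inferable intermediate terms c_k
#' (actual <= c_k <= predicted with some reference term <= c_k), of the
#' descendant-set size ratio |desc(c_k)| / |desc(predicted)|; anything else
#' scores 0. For a negative query term, rejection scores 1, any prediction 0.
#'
#' @param actual Query term id.
#' @param predicted Term id or `"rejected"` / `"ambiguous"`.
#' @param g An [OntologyGraph].
#' @param referenceTerms Character vector of terms present in the reference.
#' @return Accuracy in `[0, 1]`.
#' @export
clAccuracy <- function(actual, predicted, g, referenceTerms) {
  .checkTerms(g, c(actual, referenceTerms))
  positive <- any(vapply(referenceTerms, function(r)
    isDescendant(g, actual, r) || isDescendant(g, r, actual), logical(1)))
  rejected <- predicted %in% c("rejected", "ambiguous")
  if (!positive) return(if (rejected) 1 else 0)
  if (rejected) return(0)
  .checkTerms(g, predicted)
  if (isDescendant(g, predicted, actual)) return(1)
  if (isDescendant(g, actual, predicted) && actual != predicted) {
    between <- intersect(ancestors(g, actual), descendants(g, predicted))
    ci <- between[vapply(between, function(ck)
      any(vapply(referenceTerms, function(r) isDescendant(g, r, ck),
                 logical(1))), logical(1))]
    if (!length(ci)) return(0)
    nPred <- length(descendants(g, predicted))
    return(mean(vapply(ci, function(ck)
      length(descendants(g, ck)) / nPred, numeric(1))))
  }
  0
}

#' Term-balanced mean ontology-aware accuracy
#'
#' Mean over distinct actual terms of each term's mean per-cell accuracy, so
#' abundant types do not dominate.
#'
#' @param results data.frame with columns `actual` and `predicted` (one row
#'   per cell).
#' @param g An [OntologyGraph].
#' @param referenceTerms Terms present in the reference.
#' @return Scalar in `[0, 1]`.
#' @export
clMBA <- function(results, g, referenceTerms) {
  accs <- mapply(function(a, p) clAccuracy(a, p, g, referenceTerms),
                 results$actual, results$predicted)
  mean(tapply(accs, results$actual, mean))
}
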