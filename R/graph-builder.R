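#' Sparsify a similarity matrix to each node's top-k neighbours
#'
#' For every node the `k` most similar other nodes are selected (ties
#' broken by ascending identifier; zero-similarity candidates dropped,
#' since similarity edges must carry strictly positive weight). The edge
#' list is the union over all per-node selections — an edge is kept if
#' either endpoint selected the other — which preserves every node's
#' stated neighbourhood and bounds the edge count by `k * n`.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param k neighbours per node, `1 <= k <= n - 1`.
#' @return A data.frame of class `SimilarityEdgeList` with columns
#'   `from`, `to`, `weight` (unordered pairs listed once, `from < to`);
#'   the node universe is kept in `attr(, "ids")`.
#' @examples
#' s <- SimilarityMatrix(matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' knnFilter(s, k = 1)
#' @export
knnFilter <- function(sim, k) {
  ids <- nodeIds(sim)
  s <- similarityValues(sim)
  n <- length(ids)
  if (k < 1 || k > n - 1)
    stop(sprintf("k must satisfy 1 <= k <= %d (got %s)", n - 1, format(k)))
  idOrder <- order(ids)   # rank of each id in ascending lexicographic order
  idRank <- match(seq_len(n), idOrder)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # highest similarity first; among equal similarities, ascending id
    ord <- cand[order(-s[i, cand], idRank[cand])]
    sel <- ord[seq_len(k)]
    sel <- sel[s[i, sel] > 0]
    keep[i, sel] <- TRUE
  }
  keep <- keep | t(keep)   # union symmetrisation
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  el <- data.frame(
    from = pmin(a, b), to = pmax(a, b),
    weight = s[idx], stringsAsFactors = FALSE)
  el <- el[order(el$from, el$to), , drop = FALSE]
  rownames(el) <- NULL
  attr(el, "ids") <- ids
  class(el) <- c("SimilarityEdgeList", "data.frame")
  el
}

#' Assemble the weighted heterogeneous drug/target graph
#'
#' Combines the training interaction edges (weight exactly 1) with the
#' two KNN similarity subgraphs. Only training pairs are passed in, so
#' test-fold interaction edges are absent by construction. Nodes with no
#' edge remain in the graph as isolated vertices.
#'
#' @param trainPairs data.frame with character columns `drug`, `target`:
#'   the known interactions available for training. May have zero rows
#'   (e.g. similarity-only graphs).
#' @param ddEdges,ttEdges `SimilarityEdgeList`s from [knnFilter()] for the
#'   drug and target families.
#' @param drugIds,targetIds full node universes; default to the edge
#'   lists' universes.
#' @return A [HeterogeneousGraph-class].
#' @export
buildHeterogeneousGraph <- function(trainPairs, ddEdges, ttEdges,
                                    drugIds = attr(ddEdges, "ids"),
                                    targetIds = attr(ttEdges, "ids")) {
  if (is.null(drugIds) || is.null(targetIds))
    stop("drug and target node universes are required")
  trainPairs <- as.data.frame(trainPairs)
  if (nrow(trainPairs)) {
    if (!all(trainPairs$drug %in% drugIds))
      stop("training pair references unknown drug id")
    if (!all(trainPairs$target %in% targetIds))
      stop("training pair references unknown target id")
    key <- paste(trainPairs$drug, trainPairs$target, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate training interaction pairs removed")
      trainPairs <- trainPairs[!duplicated(key), , drop = FALSE]
    }
  }
  edges <- rbind(
    if (nrow(trainPairs)) data.frame(
      from = trainPairs$drug, to = trainPairs$target,
      weight = 1, kind = "dti", stringsAsFactors = FALSE),
    if (nrow(ddEdges)) data.frame(
      from = ddEdges$from, to = ddEdges$to,
      weight = ddEdges$weight, kind = "dd", stringsAsFactors = FALSE),
    if (nrow(ttEdges)) data.frame(
      from = ttEdges$from, to = ttEdges$to,
      weight = ttEdges$weight, kind = "tt", stringsAsFactors = FALSE))
  vertices <- data.frame(
    name = c(drugIds, targetIds),
    type = rep(c("drug", "target"), c(length(drugIds), length(targetIds))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(vertices$name))
    stop("drug and target identifier universes overlap")
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character(),
      weight = numeric(), kind = character()) else edges,
    directed = FALSE, vertices = vertices)
  new("HeterogeneousGraph", graph = g)
}

#' Choose the KNN sparsification level by cross-validated AUPR
#'
#' Runs the full pipeline cross-validation on the training data for each
#' candidate `k` and returns the candidate with the highest mean AUPR
#' (ties broken by the smaller k, preferring the sparser graph).
#'
#' @param dataset list with `network`, `drugSim`, `targetSim` (as returned
#'   by [generateBlockDataset()]).
#' @param candidateKs integer vector of candidate neighbour counts.
#' @param config a [pipelineConfig()]; its `k_drug`/`k_target` are
#'   overridden by each candidate.
#' @param folds number of CV folds per candidate.
#' @param seed master seed.
#' @return A list with `k` (the winner), and a data.frame `sweep` of
#'   candidate vs mean AUPR.
#' @export
selectK <- function(dataset, candidateKs, config = pipelineConfig(),
                    folds = 10L, seed = 1L) {
  if (!length(candidateKs)) stop("at least one candidate k is required")
  candidateKs <- sort(unique(as.integer(candidateKs)))
  aupr <- vapply(candidateKs, function(k) {
    cfg <- config
    cfg$k_drug <- k
    cfg$k_target <- k
    plan <- makeRandomPairFolds(dataset$network, n_folds = folds, seed = seed)
    rep <- runCV(dataset, cfg, plan)
    rep$mean$aupr
  }, numeric(1))
  best <- candidateKs[which.max(aupr)]  # which.max takes the first (smallest) tie
  list(k = best, sweep = data.frame(k = candidateKs, mean_aupr = aupr))
}
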