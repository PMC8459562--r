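#' @rdname DrugTargetNetwork-class
#' @param object,x a package object
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname DrugTargetNetwork-class
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname DrugTargetNetwork-class
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' @rdname EdgeFeatureSet-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname EdgeFeatureSet-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname EdgeFeatureSet-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

setMethod("drugIds", "DrugTargetNetwork", function(x) x@drugIds)
setMethod("targetIds", "DrugTargetNetwork", function(x) x@targetIds)
setMethod("interactionMatrix", "DrugTargetNetwork", function(x) x@interactions)
setMethod("nodeIds", "SimilarityMatrix", function(x) x@ids)
setMethod("similarityValues", "SimilarityMatrix", function(x) x@sim)
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))
setMethod("embeddingVectors", "EmbeddingTable", function(x) x@vectors)
setMethod("featureMatrix", "EdgeFeatureSet", function(x) x@features)
setMethod("pairLabels", "EdgeFeatureSet", function(x) x@labels)
setMethod("pairTable", "EdgeFeatureSet", function(x) x@pairs)

#' @describeIn DrugTargetNetwork-class number of drugs and targets
#' @export
setMethod("dim", "DrugTargetNetwork", function(x) dim(x@interactions))

setMethod("show", "DrugTargetNetwork", function(object) {
  y <- object@interactions
  cat(sprintf(
    "DrugTargetNetwork: %d drugs x %d targets, %d known interactions (%.1f%%)\n",
    nrow(y), ncol(y), sum(y), 100 * mean(y)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  s <- object@sim
  off <- s[upper.tri(s)]
  cat(sprintf("SimilarityMatrix: %d nodes, off-diagonal range [%.3f, %.3f]\n",
    length(object@ids), if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
})

setMethod("show", "HeterogeneousGraph", function(object) {
  g <- object@graph
  kind <- igraph::E(g)$kind
  cat(sprintf(
    "HeterogeneousGraph: %d nodes (%d drugs, %d targets), %d edges (dti %d, drug-sim %d, target-sim %d)\n",
    igraph::vcount(g), sum(igraph::V(g)$type == "drug"),
    sum(igraph::V(g)$type == "target"), igraph::ecount(g),
    sum(kind == "dti"), sum(kind == "dd"), sum(kind == "tt")))
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d nodes embedded in R^%d\n",
    nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "EdgeFeatureSet", function(object) {
  cat(sprintf("EdgeFeatureSet: %d pairs x %d features (%d positive, %d negative)\n",
    nrow(object@features), ncol(object@features),
    sum(object@labels == 1), sum(object@labels == 0)))
})
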