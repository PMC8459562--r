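#' @useDynLib DTIembed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' DrugTargetNetwork: a binary drug-target interaction matrix
#'
#' Container for a set of drugs, a set of targets, and the binary
#' interaction label matrix Y (drugs in rows, targets in columns).
#' An entry of 1 marks a known interaction; 0 marks an unknown pair,
#' which the prediction task treats as a negative sample.
#'
#' @slot drugIds character vector of unique drug identifiers (rows of Y).
#' @slot targetIds character vector of unique target identifiers (columns).
#' @slot interactions integer/numeric matrix with entries in \{0, 1\}.
#'
#' @seealso [readInteractionMatrix()], [summarizeDataset()]
#' @exportClass DrugTargetNetwork
setClass("DrugTargetNetwork",
  representation(
    drugIds = "character",
    targetIds = "character",
    interactions = "matrix"
  )
)

setValidity("DrugTargetNetwork", function(object) {
  msg <- character()
  m <- length(object@drugIds)
  n <- length(object@targetIds)
  if (m < 1L) msg <- c(msg, "at least one drug is required")
  if (n < 1L) msg <- c(msg, "at least one target is required")
  if (anyDuplicated(object@drugIds))
    msg <- c(msg, "drug identifiers must be unique")
  if (anyDuplicated(object@targetIds))
    msg <- c(msg, "target identifiers must be unique")
  if (!identical(dim(object@interactions), c(m, n)))
    msg <- c(msg, sprintf("interaction matrix must be %d x %d", m, n))
  y <- object@interactions
  if (length(y) && !all(y == 0 | y == 1))
    msg <- c(msg, "interaction entries must be exactly 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugTargetNetwork
#'
#' @param interactions binary matrix, drugs in rows and targets in columns.
#'   Row and column names are used as identifiers when `drugIds`/`targetIds`
#'   are missing.
#' @param drugIds,targetIds identifier character vectors.
#' @return A [DrugTargetNetwork-class] object.
#' @examples
#' y <- matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("d1", "d2"), c("t1", "t2")))
#' DrugTargetNetwork(y)
#' @export
DrugTargetNetwork <- function(interactions,
                              drugIds = rownames(interactions),
                              targetIds = colnames(interactions)) {
  if (is.null(drugIds) || is.null(targetIds))
    stop("drug and target identifiers are required (dimnames or arguments)")
  interactions <- as.matrix(interactions)
  storage.mode(interactions) <- "double"
  dimnames(interactions) <- list(drugIds, targetIds)
  new("DrugTargetNetwork",
    drugIds = as.character(drugIds),
    targetIds = as.character(targetIds),
    interactions = interactions)
}

#' SimilarityMatrix: square symmetric similarities for one node family
#'
#' Holds pairwise similarity scores in \[0, 1\] for either drugs (e.g.
#' chemical-structure similarity) or targets (e.g. normalised sequence
#' alignment scores). The matrix must be symmetric with a unit diagonal;
#' scores are consumed as given, never computed here.
#'
#' @slot ids character vector of unique node identifiers.
#' @slot sim square numeric matrix of similarities.
#'
#' @seealso [readSimilarityMatrix()], [knnFilter()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(ids = "character", sim = "matrix")
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "identifiers must be unique")
  if (!identical(dim(object@sim), c(n, n)))
    msg <- c(msg, "similarity matrix must be square and match ids")
  s <- object@sim
  if (length(s)) {
    if (any(s < 0 | s > 1)) msg <- c(msg, "similarities must lie in [0, 1]")
    if (max(abs(s - t(s))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(s) - 1) > 1e-9)) msg <- c(msg, "diagonal must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' Small asymmetries (up to `1e-6`, as left by rounding in distributed
#' files) are repaired by averaging the matrix with its transpose.
#'
#' @param sim square numeric matrix with values in \[0, 1\].
#' @param ids node identifiers; defaults to `rownames(sim)`.
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(sim, ids = rownames(sim)) {
  sim <- as.matrix(sim)
  if (is.null(ids)) stop("node identifiers are required")
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  asym <- max(abs(sim - t(sim)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance 1e-6", asym))
  if (asym > 0) sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  dimnames(sim) <- list(ids, ids)
  new("SimilarityMatrix", ids = as.character(ids), sim = sim)
}

#' HeterogeneousGraph: the weighted drug/target graph
#'
#' A typed, weighted, undirected graph combining training drug-target
#' interaction edges (weight exactly 1) with KNN-sparsified drug-drug and
#' target-target similarity edges (weights in (0, 1\]). Backed by an
#' igraph object carrying `type` ("drug"/"target") vertex attributes and
#' `kind` ("dti"/"dd"/"tt") edge attributes.
#'
#' @slot graph the underlying `igraph` object.
#'
#' @seealso [buildHeterogeneousGraph()], [embedGraph()]
#' @exportClass HeterogeneousGraph
setClass("HeterogeneousGraph", representation(graph = "ANY"))

setValidity("HeterogeneousGraph", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph slot must hold an igraph object")
  msg <- character()
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "duplicate edges are not allowed")
  w <- igraph::E(g)$weight
  kind <- igraph::E(g)$kind
  vtype <- igraph::V(g)$type
  if (igraph::ecount(g)) {
    if (is.null(w) || any(w <= 0) || any(w > 1))
      msg <- c(msg, "edge weights must lie in (0, 1]")
    if (!is.null(w) && !is.null(kind) && any(w[kind == "dti"] != 1))
      msg <- c(msg, "interaction edges must have weight exactly 1")
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    ta <- vtype[ends[, 1]]; tb <- vtype[ends[, 2]]
    if (!is.null(kind)) {
      if (any(kind == "dti" & ta == tb))
        msg <- c(msg, "interaction edges must join a drug and a target")
      if (any(kind != "dti" & ta != tb))
        msg <- c(msg, "similarity edges must stay within one node family")
    }
  }
  if (!all(vtype %in% c("drug", "target")))
    msg <- c(msg, "every node must be typed drug or target")
  if (length(msg)) msg else TRUE
})

#' EmbeddingTable: learned node feature vectors
#'
#' The mapping f: V -> R^d learned by skip-gram training on random-walk
#' sentences. Stored as a matrix with one row per node.
#'
#' @slot vectors numeric matrix; rownames are node identifiers.
#'
#' @seealso [embedGraph()], [buildFeatureSet()]
#' @exportClass EmbeddingTable
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  v <- object@vectors
  if (is.null(rownames(v))) return("embedding rows must be named by node id")
  if (anyDuplicated(rownames(v))) return("node ids must be unique")
  if (length(v) && !all(is.finite(v))) return("embedding values must be finite")
  TRUE
})

#' EdgeFeatureSet: fused per-pair feature vectors with labels
#'
#' One row per (drug, target) pair: the fused edge representation plus
#' its binary interaction label.
#'
#' @slot pairs data.frame with character columns `drug` and `target`.
#' @slot features numeric matrix, one row per pair.
#' @slot labels numeric vector of 0/1 labels.
#'
#' @seealso [buildFeatureSet()], [trainBooster()]
#' @exportClass EdgeFeatureSet
setClass("EdgeFeatureSet",
  representation(pairs = "data.frame", features = "matrix", labels = "numeric")
)

setValidity("EdgeFeatureSet", function(object) {
  msg <- character()
  n <- nrow(object@pairs)
  if (nrow(object@features) != n || length(object@labels) != n)
    msg <- c(msg, "pairs, features and labels must have matching row counts")
  if (!all(c("drug", "target") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have 'drug' and 'target' columns")
  if (length(object@features) && !all(is.finite(object@features)))
    msg <- c(msg, "all features must be finite")
  if (length(object@labels) && !all(object@labels %in% c(0, 1)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

EdgeFeatureSet <- function(pairs, features, labels) {
  new("EdgeFeatureSet",
    pairs = as.data.frame(pairs), features = features,
    labels = as.numeric(labels))
}
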