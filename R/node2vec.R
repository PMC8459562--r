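#' Configuration for biased random-walk embedding
#'
#' Second-order walks interpolate breadth-first and depth-first
#' exploration via the return parameter `p` (probability mass on stepping
#' back to the previous node) and the in-out parameter `q` (mass on
#' moving away from the previous node's neighbourhood). Walk sentences
#' feed a skip-gram model with negative sampling.
#'
#' @param p return parameter, > 0.
#' @param q in-out parameter, > 0.
#' @param d embedding dimension.
#' @param walk_length nodes per walk.
#' @param num_walks walks started from each non-isolated node.
#' @param window skip-gram context window.
#' @param epochs passes over the walk corpus.
#' @param negative negative samples per context pair.
#' @param alpha initial skip-gram learning rate.
#' @param workers reserved for API compatibility; training is
#'   single-threaded, which is what makes runs reproducible.
#' @param seed integer seed covering walk generation and training.
#' @return A list of class `Node2VecConfig`.
#' @export
node2vecConfig <- function(p = 1, q = 1, d = 64L, walk_length = 80L,
                           num_walks = 10L, window = 5L, epochs = 5L,
                           negative = 5L, alpha = 0.025, workers = 1L,
                           seed = 1L) {
  cfg <- list(p = p, q = q, d = as.integer(d),
    walk_length = as.integer(walk_length), num_walks = as.integer(num_walks),
    window = as.integer(window), epochs = as.integer(epochs),
    negative = as.integer(negative), alpha = alpha,
    workers = as.integer(workers), seed = as.integer(seed))
  if (cfg$p <= 0 || cfg$q <= 0) stop("p and q must be positive")
  stopifnot(cfg$d >= 1, cfg$walk_length >= 1, cfg$num_walks >= 1,
    cfg$window >= 1, cfg$epochs >= 1, cfg$negative >= 0, cfg$alpha > 0,
    cfg$workers >= 1)
  class(cfg) <- "Node2VecConfig"
  cfg
}

# ---- alias method ---------------------------------------------------------

# Build alias tables for a discrete distribution (Walker's method):
# O(1) sampling afterwards. probs must be non-negative, sum > 0.
aliasSetup <- function(probs) {
  n <- length(probs)
  probs <- probs / sum(probs)
  scaled <- probs * n
  alias <- integer(n)
  cutoff <- numeric(n)
  small <- which(scaled < 1)
  large <- which(scaled >= 1)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    cutoff[s] <- scaled[s]
    alias[s] <- l
    scaled[l] <- scaled[l] - (1 - scaled[s])
    if (scaled[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  cutoff[c(small, large)] <- 1
  alias[c(small, large)] <- c(small, large)
  list(cutoff = cutoff, alias = alias, probs = probs)
}

aliasDraw <- function(tab) {
  n <- length(tab$cutoff)
  i <- sample.int(n, 1L)
  if (stats::runif(1) < tab$cutoff[i]) i else tab$alias[i]
}

# ---- transition model -----------------------------------------------------

#' Build first- and second-order transition tables for biased walks
#'
#' The first step from a node is weight-proportional over its neighbours.
#' Subsequent steps from `v`, having arrived from `t`, weight each
#' neighbour `x` of `v` by `alpha(t, x) * w(v, x)` where `alpha` is `1/p`
#' for the return move `x == t`, `1` when `x` is adjacent to `t`, and
#' `1/q` otherwise. All distributions are stored as alias tables for
#' constant-time sampling.
#'
#' @param hgraph a [HeterogeneousGraph-class].
#' @param p,q bias parameters, > 0.
#' @return A list of class `TransitionModel`.
#' @export
buildTransitionModel <- function(hgraph, p, q) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  g <- hgraph@graph
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  wts <- igraph::E(g)$weight
  inc <- igraph::as_adj_edge_list(g, mode = "all")
  nbr <- vector("list", n)
  w <- vector("list", n)
  for (v in seq_len(n)) {
    ns <- as.integer(adj[[v]])
    ws <- wts[as.integer(inc[[v]])]
    o <- order(ns)
    nbr[[v]] <- ns[o]
    w[[v]] <- ws[o]
  }
  first <- vector("list", n)
  for (v in seq_len(n)) {
    if (length(nbr[[v]])) first[[v]] <- aliasSetup(w[[v]])
  }
  second <- new.env(parent = emptyenv(), size = 4L * igraph::ecount(g) + 1L)
  for (v in seq_len(n)) {
    xs <- nbr[[v]]
    if (!length(xs)) next
    for (t in xs) {
      adjT <- xs %in% nbr[[t]]
      a <- ifelse(xs == t, 1 / p, ifelse(adjT, 1, 1 / q))
      assign(sprintf("%d,%d", t, v), aliasSetup(a * w[[v]]), envir = second)
    }
  }
  model <- list(nodes = nodes, nbr = nbr, weights = w,
    first = first, second = second, p = p, q = q)
  class(model) <- "TransitionModel"
  model
}

#' Analytic transition probabilities of a TransitionModel
#'
#' For testing and inspection: the exact distribution over the neighbours
#' of `current`, either for a walk's first step (`previous = NULL`) or a
#' second-order step that arrived from `previous`.
#'
#' @param model a `TransitionModel`.
#' @param current node identifier the walk stands on.
#' @param previous node identifier of the preceding step, or `NULL`.
#' @return Named numeric vector of probabilities over neighbours.
#' @export
transitionProbability <- function(model, current, previous = NULL) {
  v <- match(current, model$nodes)
  if (is.na(v)) stop("unknown node: ", current)
  tab <- if (is.null(previous)) {
    model$first[[v]]
  } else {
    t <- match(previous, model$nodes)
    if (is.na(t)) stop("unknown node: ", previous)
    get0(sprintf("%d,%d", t, v), envir = model$second)
  }
  if (is.null(tab)) stop("no transition table for that state")
  stats::setNames(tab$probs, model$nodes[model$nbr[[v]]])
}

#' Simulate biased random walks
#'
#' Starts `num_walks` walks at every non-isolated node; each walk takes
#' its first step from the weight-proportional distribution and later
#' steps from the second-order tables, terminating early only at a
#' dead-end node. Fully reproducible from `cfg$seed`.
#'
#' @param model a `TransitionModel` from [buildTransitionModel()].
#' @param cfg a [node2vecConfig()].
#' @return A list of class `WalkCorpus` with `walks` (list of integer
#'   node-index vectors) and `nodes` (the identifier universe).
#' @export
simulateWalks <- function(model, cfg) {
  stopifnot(inherits(model, "TransitionModel"))
  set.seed(cfg$seed)
  sources <- which(lengths(model$nbr) > 0L)
  walks <- vector("list", cfg$num_walks * length(sources))
  wi <- 0L
  for (iter in seq_len(cfg$num_walks)) {
    for (s in sources) {
      walk <- integer(cfg$walk_length)
      walk[1L] <- s
      len <- 1L
      if (cfg$walk_length >= 2L) {
        cur <- model$nbr[[s]][aliasDraw(model$first[[s]])]
        len <- 2L
        walk[2L] <- cur
        prev <- s
        while (len < cfg$walk_length) {
          tab <- get0(sprintf("%d,%d", prev, cur), envir = model$second)
          if (is.null(tab)) break   # dead end
          nxt <- model$nbr[[cur]][aliasDraw(tab)]
          len <- len + 1L
          walk[len] <- nxt
          prev <- cur
          cur <- nxt
        }
      }
      wi <- wi + 1L
      walks[[wi]] <- walk[seq_len(len)]
    }
  }
  corpus <- list(walks = walks, nodes = model$nodes)
  class(corpus) <- "WalkCorpus"
  corpus
}

#' Export a walk corpus as whitespace-separated node-id lines
#'
#' @param corpus a `WalkCorpus`.
#' @param path output file, one walk per line.
#' @return The path, invisibly.
#' @export
writeWalkCorpus <- function(corpus, path) {
  lines <- vapply(corpus$walks,
    function(w) paste(corpus$nodes[w], collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Negative-sampling skip-gram, single-threaded so that a fixed seed
#' yields bit-identical embeddings. Nodes absent from the corpus receive
#' no vector.
#'
#' @param corpus a `WalkCorpus` from [simulateWalks()].
#' @param cfg a [node2vecConfig()].
#' @return An [EmbeddingTable-class].
#' @export
trainSkipgram <- function(corpus, cfg) {
  stopifnot(inherits(corpus, "WalkCorpus"))
  if (!length(corpus$walks)) stop("walk corpus is empty")
  if (cfg$d >= length(corpus$nodes))
    warning("embedding dimension d >= |V|; d < |V| is recommended")
  vec <- .skipgramTrain(corpus$walks, length(corpus$nodes), cfg$d,
    cfg$window, cfg$epochs, cfg$negative, cfg$alpha, cfg$alpha * 1e-4,
    cfg$seed)
  rownames(vec) <- corpus$nodes
  seen <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  new("EmbeddingTable", vectors = vec[seen, , drop = FALSE])
}

#' Embed a heterogeneous graph
#'
#' Composition of [buildTransitionModel()], [simulateWalks()] and
#' [trainSkipgram()]. Walks cross node types freely
#' (drug -> target -> drug ...), embedding the heterogeneous graph as one
#' network. Isolated nodes are absent from the result and reported via a
#' message.
#'
#' @param hgraph a [HeterogeneousGraph-class].
#' @param cfg a [node2vecConfig()].
#' @return An [EmbeddingTable-class].
#' @examples
#' ds <- generateBlockDataset(syntheticConfig(m = 15, n = 15, seed = 3))
#' g <- buildHeterogeneousGraph(
#'   interactionPairs(ds$network),
#'   knnFilter(ds$drugSim, 3), knnFilter(ds$targetSim, 3))
#' emb <- embedGraph(g, node2vecConfig(d = 8, num_walks = 2, walk_length = 10))
#' @export
embedGraph <- function(hgraph, cfg = node2vecConfig()) {
  model <- buildTransitionModel(hgraph, cfg$p, cfg$q)
  isolated <- model$nodes[lengths(model$nbr) == 0L]
  if (length(isolated))
    message(sprintf("%d isolated node(s) have no embedding: %s",
      length(isolated), paste(utils::head(isolated, 5), collapse = ", ")))
  corpus <- simulateWalks(model, cfg)
  trainSkipgram(corpus, cfg)
}

#' Write an embedding table in word2vec text format
#'
#' Header line "count dim", then one line per node: id followed by d
#' floating-point coordinates.
#'
#' @param emb an [EmbeddingTable-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  v <- embeddingVectors(emb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(rownames(v)[i],
      format(v[i, ], digits = 8, trim = TRUE, scientific = FALSE)),
      collapse = " "), con)
  }
  invisible(path)
}
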