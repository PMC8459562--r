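#' Fusion operators for drug-target edge representations
#'
#' Combine a drug vector `fd` and a target vector `ft` of common length d
#' into one edge feature vector:
#' \describe{
#'   \item{concatenate}{`c(fd, ft)`, drug first; length 2d.}
#'   \item{hadamard}{`fd * ft` elementwise.}
#'   \item{average}{`(fd + ft) / 2`.}
#'   \item{weighted_l1}{`abs(fd - ft)` elementwise.}
#'   \item{weighted_l2}{`(fd - ft)^2` elementwise.}
#' }
#' All but concatenation are symmetric in their arguments and keep
#' length d.
#'
#' @param fd,ft numeric vectors of equal length.
#' @param kind one of `"concatenate"`, `"hadamard"`, `"average"`,
#'   `"weighted_l1"`, `"weighted_l2"`.
#' @return The fused numeric vector.
#' @examples
#' fuseEmbeddings(c(1, 3), c(2, 1), "weighted_l1")  # 1 2
#' @export
fuseEmbeddings <- function(fd, ft, kind = fusionKinds()) {
  kind <- match.arg(kind)
  if (length(fd) != length(ft))
    stop("drug and target vectors must have equal length")
  switch(kind,
    concatenate = c(fd, ft),
    hadamard = fd * ft,
    average = (fd + ft) / 2,
    weighted_l1 = abs(fd - ft),
    weighted_l2 = (fd - ft)^2)
}

#' @rdname fuseEmbeddings
#' @export
fusionKinds <- function() {
  c("concatenate", "hadamard", "average", "weighted_l1", "weighted_l2")
}

#' Build an edge feature set from node embeddings
#'
#' Applies a fusion operator to every listed (drug, target) pair —
#' including unknown pairs, which carry label 0. Rows keep the input pair
#' order.
#'
#' @param emb an [EmbeddingTable-class].
#' @param pairs data.frame with columns `drug`, `target` (a `label`
#'   column is used when `labels` is missing).
#' @param labels 0/1 labels, one per pair.
#' @param kind fusion operator, see [fuseEmbeddings()].
#' @return An [EdgeFeatureSet-class].
#' @export
buildFeatureSet <- function(emb, pairs, labels = pairs$label,
                            kind = fusionKinds()) {
  kind <- match.arg(kind)
  pairs <- as.data.frame(pairs)
  if (is.null(labels)) stop("labels are required")
  v <- embeddingVectors(emb)
  di <- match(pairs$drug, rownames(v))
  ti <- match(pairs$target, rownames(v))
  if (anyNA(di))
    stop("no embedding for drug: ", pairs$drug[which(is.na(di))[1]])
  if (anyNA(ti))
    stop("no embedding for target: ", pairs$target[which(is.na(ti))[1]])
  fd <- v[di, , drop = FALSE]
  ft <- v[ti, , drop = FALSE]
  x <- switch(kind,
    concatenate = cbind(fd, ft),
    hadamard = fd * ft,
    average = (fd + ft) / 2,
    weighted_l1 = abs(fd - ft),
    weighted_l2 = (fd - ft)^2)
  dimnames(x) <- NULL
  EdgeFeatureSet(pairs[, c("drug", "target")], x, labels)
}

#' Min-max normalisation fitted on training rows only
#'
#' `fitMinMax()` learns per-feature minima and maxima from a training
#' set; `applyMinMax()` rescales any feature set with those parameters:
#' `(x - min) / (max - min)`. A constant training feature maps to 0
#' everywhere, and test values are deliberately not clipped, so they can
#' fall outside \[0, 1\] — out-of-range signal is information, and the
#' protocol transforms test data strictly with training parameters.
#'
#' @param train an [EdgeFeatureSet-class] of training rows.
#' @return For `fitMinMax()`, a list of class `NormalizationParams` with
#'   vectors `min` and `max`.
#' @export
fitMinMax <- function(train) {
  x <- featureMatrix(train)
  if (!nrow(x)) stop("training feature set is empty")
  params <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  class(params) <- "NormalizationParams"
  params
}

#' @rdname fitMinMax
#' @param x an [EdgeFeatureSet-class] to rescale.
#' @param params a `NormalizationParams` from `fitMinMax()`.
#' @export
applyMinMax <- function(x, params) {
  stopifnot(inherits(params, "NormalizationParams"))
  f <- featureMatrix(x)
  if (ncol(f) != length(params$min))
    stop("feature width does not match normalisation parameters")
  range <- params$max - params$min
  scaled <- sweep(f, 2, params$min, `-`)
  nonconst <- range > 0
  scaled[, nonconst] <- sweep(scaled[, nonconst, drop = FALSE], 2,
    range[nonconst], `/`)
  scaled[, !nonconst] <- 0
  EdgeFeatureSet(pairTable(x), scaled, pairLabels(x))
}

#' Random oversampling of the minority class
#'
#' Resamples minority-class rows with replacement until both classes have
#' the majority count. Applied to training data only; every synthesised
#' row is an exact copy of an original row. Reproducible from `seed`.
#'
#' @param train an [EdgeFeatureSet-class] containing both classes.
#' @param seed integer seed.
#' @return The balanced [EdgeFeatureSet-class] (original rows first, in
#'   their input order, then the resampled minority copies).
#' @export
oversampleMinority <- function(train, seed = 1L) {
  y <- pairLabels(train)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to oversample")
  if (n1 == n0) return(train)
  minority <- if (n1 < n0) which(y == 1) else which(y == 0)
  deficit <- abs(n0 - n1)
  set.seed(seed)
  extra <- minority[sample.int(length(minority), deficit, replace = TRUE)]
  idx <- c(seq_along(y), extra)
  EdgeFeatureSet(pairTable(train)[idx, , drop = FALSE],
    featureMatrix(train)[idx, , drop = FALSE], y[idx])
}
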