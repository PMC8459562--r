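#' Specification of a boosting classifier
#'
#' @param algorithm `"xgboost"` (gradient-boosted regression trees) or
#'   `"adaboost"` (adaptive boosting of depth-1 decision stumps).
#' @param n_trees number of boosting rounds.
#' @param max_depth tree depth (xgboost; AdaBoost always uses stumps of
#'   depth 1, the canonical weak learner).
#' @param learning_rate shrinkage (> 0).
#' @param lambda,alpha L2/L1 regularisation (xgboost only).
#' @param subsample row subsampling ratio in (0, 1] (xgboost only).
#' @param seed integer seed; training is single-threaded so the fit is
#'   deterministic given the seed.
#' @return A list of class `BoosterSpec`.
#' @export
boosterSpec <- function(algorithm = c("xgboost", "adaboost"),
                        n_trees = if (algorithm == "adaboost") 50L else 100L,
                        max_depth = 6L, learning_rate = NULL,
                        lambda = 1, alpha = 0, subsample = 1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(learning_rate))
    learning_rate <- if (algorithm == "adaboost") 1 else 0.3
  spec <- list(algorithm = algorithm, n_trees = as.integer(n_trees),
    max_depth = as.integer(max_depth), learning_rate = learning_rate,
    lambda = lambda, alpha = alpha, subsample = subsample,
    seed = as.integer(seed))
  if (spec$n_trees < 1) stop("n_trees must be positive")
  if (spec$learning_rate <= 0) stop("learning_rate must be positive")
  if (spec$subsample <= 0 || spec$subsample > 1)
    stop("subsample must lie in (0, 1]")
  class(spec) <- "BoosterSpec"
  spec
}

#' Train a boosting classifier on an edge feature set
#'
#' XGBoost fits gradient-boosted trees through the xgboost library
#' (single thread, seeded). AdaBoost is the classical reweighting
#' ensemble of depth-1 decision stumps (rpart weak learners): each round
#' fits a stump under the current case weights, earns a vote
#' `0.5 * log((1 - err) / err)` scaled by the learning rate, and
#' up-weights the rows it misclassified.
#'
#' @param train an [EdgeFeatureSet-class] with both classes present.
#' @param spec a [boosterSpec()].
#' @return A list of class `TrainedModel` (opaque fit + its spec).
#' @export
trainBooster <- function(train, spec = boosterSpec()) {
  stopifnot(inherits(spec, "BoosterSpec"))
  x <- featureMatrix(train)
  y <- pairLabels(train)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  fit <- if (spec$algorithm == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
        max_depth = spec$max_depth, eta = spec$learning_rate,
        lambda = spec$lambda, alpha = spec$alpha,
        subsample = spec$subsample, nthread = 1, seed = spec$seed),
      data = dtrain, nrounds = spec$n_trees, verbose = 0)
  } else {
    fitAdaBoostStumps(x, y, spec)
  }
  model <- list(algorithm = spec$algorithm, fit = fit, spec = spec,
    featureWidth = ncol(x))
  class(model) <- "TrainedModel"
  model
}

# AdaBoost.M1 with depth-1 rpart stumps and learning-rate shrinkage.
fitAdaBoostStumps <- function(x, y, spec) {
  n <- nrow(x)
  ysign <- ifelse(y == 1, 1, -1)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
    minbucket = 1, xval = 0, maxsurrogate = 0, usesurrogate = 0)
  stumps <- list()
  votes <- numeric()
  for (m in seq_len(spec$n_trees)) {
    df$.y <- factor(ysign, levels = c(-1, 1))
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
      control = ctrl)
    pred <- as.numeric(as.character(predict(stump, df, type = "class")))
    err <- sum(w[pred != ysign])
    if (err >= 0.5) break                  # weak learner no better than chance
    err <- max(err, 1e-12)
    vote <- spec$learning_rate * 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    votes <- c(votes, vote)
    w <- w * exp(-vote * ysign * pred)
    w <- w / sum(w)
    if (err <= 1e-12) break                # perfectly separated
  }
  if (!length(stumps)) stop("AdaBoost found no useful weak learner")
  list(stumps = stumps, votes = votes, nFeatures = ncol(x))
}

#' Predict interaction scores
#'
#' @param model a `TrainedModel` from [trainBooster()].
#' @param features numeric matrix or [EdgeFeatureSet-class] with the
#'   training feature width.
#' @return Numeric vector of scores in \[0, 1\], one per row. AdaBoost
#'   scores are the normalised signed vote margin mapped to \[0, 1\].
#' @export
predictScores <- function(model, features) {
  stopifnot(inherits(model, "TrainedModel"))
  x <- if (is(features, "EdgeFeatureSet")) featureMatrix(features) else features
  if (!is.matrix(x)) x <- matrix(x, ncol = model$featureWidth)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != model$featureWidth)
    stop(sprintf("feature width %d does not match training width %d",
      ncol(x), model$featureWidth))
  if (model$algorithm == "xgboost") {
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  } else {
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x)))
    margin <- rep(0, nrow(x))
    for (m in seq_along(model$fit$stumps)) {
      pred <- as.numeric(as.character(
        predict(model$fit$stumps[[m]], df, type = "class")))
      margin <- margin + model$fit$votes[m] * pred
    }
    (margin / sum(model$fit$votes) + 1) / 2
  }
}

# Stratified fold assignment: shuffle each class, deal round-robin.
# Per-fold positive counts differ from the ideal quota by at most 1.
stratifiedAssign <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Hyperparameter search by cross-validated AUPR
#'
#' Grid search enumerates the full Cartesian product of the candidate
#' lists; randomized search samples `budget` distinct combinations
#' uniformly. Each candidate is scored by mean AUPR over stratified folds
#' of the supplied training rows only, and the best candidate is returned
#' (ties broken by first encountered).
#'
#' @param train an [EdgeFeatureSet-class] of training rows.
#' @param space named list mapping [boosterSpec()] argument names to
#'   candidate value vectors.
#' @param algorithm classifier family, see [boosterSpec()].
#' @param strategy `"grid"` or `"randomized"`.
#' @param budget number of candidates for randomized search.
#' @param folds inner CV folds (the protocol default is 10; smaller
#'   values trade fidelity for speed).
#' @param seed integer seed.
#' @return A list with `spec` (best [boosterSpec()]), `mean_aupr`, and a
#'   data.frame `results` of every evaluated candidate.
#' @export
tuneHyperparameters <- function(train, space,
                                algorithm = c("xgboost", "adaboost"),
                                strategy = c("grid", "randomized"),
                                budget = 10L, folds = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  strategy <- match.arg(strategy)
  if (!length(space) || !all(nzchar(names(space))))
    stop("space must be a non-empty named list of candidate vectors")
  if (budget < 1) stop("budget must be at least 1")
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  if (strategy == "randomized" && nrow(grid) > budget) {
    set.seed(seed)
    grid <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
  }
  y <- pairLabels(train)
  x <- featureMatrix(train)
  fold <- stratifiedAssign(y, folds, seed = seed + 1L)
  auprs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- as.list(grid[i, , drop = FALSE])
    names(args) <- names(grid)
    spec <- do.call(boosterSpec,
      c(list(algorithm = algorithm, seed = seed), args))
    foldAupr <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      sub <- EdgeFeatureSet(pairTable(train)[tr, , drop = FALSE],
        x[tr, , drop = FALSE], y[tr])
      model <- trainBooster(sub, spec)
      computeMetrics(predictScores(model, x[!tr, , drop = FALSE]), y[!tr])$aupr
    }, numeric(1))
    auprs[i] <- mean(foldAupr, na.rm = TRUE)
  }
  best <- which.max(auprs)   # first index wins ties
  args <- as.list(grid[best, , drop = FALSE])
  names(args) <- names(grid)
  list(
    spec = do.call(boosterSpec, c(list(algorithm = algorithm, seed = seed), args)),
    mean_aupr = auprs[best],
    results = cbind(grid, mean_aupr = auprs))
}
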