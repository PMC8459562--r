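#' Pipeline configuration for the end-to-end predictor
#'
#' Bundles the knobs of every stage: KNN sparsification level for each
#' similarity network, the walk-embedding configuration, the fusion
#' operator, and the boosting classifier.
#'
#' @param k_drug,k_target neighbours kept per node when sparsifying the
#'   drug and target similarity networks (the two families may differ in
#'   size, hence separate values; they default to the same number).
#' @param embedding a [node2vecConfig()]; its seed is re-derived per fold.
#' @param fusion fusion operator, see [fuseEmbeddings()]. `"average"` is
#'   supported but known to underperform and is excluded from sweeps.
#' @param booster a [boosterSpec()]; its seed is re-derived per fold.
#' @param max_negatives optional cap on training negatives per fold
#'   (uniform subsample). `NULL` (default) keeps the full negative
#'   universe, the protocol's definition of the negative class.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(k_drug = 5L, k_target = k_drug,
                           embedding = node2vecConfig(),
                           fusion = "hadamard",
                           booster = boosterSpec("xgboost"),
                           max_negatives = NULL) {
  fusion <- match.arg(fusion, fusionKinds())
  cfg <- list(k_drug = as.integer(k_drug), k_target = as.integer(k_target),
    embedding = embedding, fusion = fusion, booster = booster,
    max_negatives = if (!is.null(max_negatives)) as.integer(max_negatives))
  class(cfg) <- "PipelineConfig"
  cfg
}

# ---- split plans ----------------------------------------------------------

#' Stratified random-pair cross-validation folds
#'
#' Partitions the full m x n pair universe into `n_folds` disjoint test
#' sets, stratified so each fold's positive count differs from the ideal
#' quota by at most one pair. Warns when some drug or target loses every
#' positive from a training fold (a violation of the random setting's
#' assumption that each node is seen interacting in training).
#'
#' @param net a [DrugTargetNetwork-class].
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed.
#' @return A list of class `SplitPlan` with `mode`, `folds` (list of
#'   integer index vectors into [pairUniverse()] row order) and `seed`.
#' @export
makeRandomPairFolds <- function(net, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  universe <- pairUniverse(net)
  if (sum(universe$label) < n_folds)
    stop("fewer positive pairs than folds")
  fold <- stratifiedAssign(universe$label, n_folds, seed)
  folds <- split(seq_len(nrow(universe)), fold)
  names(folds) <- NULL
  for (f in seq_len(n_folds)) {
    tr <- universe[-folds[[f]], ]
    pos <- tr[tr$label == 1, ]
    lost <- c(setdiff(drugIds(net), pos$drug), setdiff(targetIds(net), pos$target))
    if (length(lost))
      warning(sprintf(
        "fold %d training data has node(s) without positives: %s",
        f, paste(utils::head(lost, 5), collapse = ", ")))
  }
  plan <- list(mode = "random_pair_cv", folds = folds, seed = as.integer(seed))
  class(plan) <- "SplitPlan"
  plan
}

#' New-drug cross-validation rounds
#'
#' Shuffles the drugs and partitions them into `n_rounds` held-out
#' groups. A round's test set is every pair involving its held-out
#' drugs; those drugs keep their similarity edges in the graph (the only
#' way a drug with no known interactions can be embedded) but contribute
#' no interaction edges to training.
#'
#' @param net a [DrugTargetNetwork-class].
#' @param n_rounds number of rounds (<= number of drugs).
#' @param seed integer seed.
#' @return A `SplitPlan` with mode `"new_drug_cv"`; also carries the
#'   held-out drug groups as `heldOutDrugs`.
#' @export
makeNewDrugFolds <- function(net, n_rounds = 10L, seed = 1L) {
  n_rounds <- as.integer(n_rounds)
  m <- length(drugIds(net))
  if (n_rounds > m) stop("more rounds than drugs")
  set.seed(seed)
  shuffled <- drugIds(net)[sample.int(m)]
  groups <- split(shuffled, rep_len(seq_len(n_rounds), m))
  names(groups) <- NULL
  universe <- pairUniverse(net)
  folds <- lapply(groups, function(g) which(universe$drug %in% g))
  plan <- list(mode = "new_drug_cv", folds = folds,
    heldOutDrugs = groups, seed = as.integer(seed))
  class(plan) <- "SplitPlan"
  plan
}

#' Stratified train/validation/test hold-out split
#'
#' @param net a [DrugTargetNetwork-class].
#' @param fractions numeric of length 3 summing to 1
#'   (train, validation, test).
#' @param seed integer seed.
#' @return A `SplitPlan` with mode `"holdout"` and `folds` holding the
#'   `train`, `valid` and `test` index sets.
#' @export
makeHoldoutSplit <- function(net, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three values summing to 1")
  universe <- pairUniverse(net)
  set.seed(seed)
  group <- integer(nrow(universe))
  for (cls in c(1, 0)) {
    idx <- which(universe$label == cls)
    idx <- idx[sample.int(length(idx))]
    cuts <- round(cumsum(fractions) * length(idx))
    group[idx] <- rep(1:3, times = diff(c(0, cuts)))
  }
  plan <- list(mode = "holdout",
    folds = list(train = which(group == 1), valid = which(group == 2),
      test = which(group == 3)),
    seed = as.integer(seed))
  class(plan) <- "SplitPlan"
  plan
}

# ---- metrics --------------------------------------------------------------

#' Ranking metrics for scored drug-target pairs
#'
#' AUC is the trapezoidal area under the ROC curve built from the
#' distinct score thresholds; AUPR follows the average-precision
#' convention (precision summed at each newly recalled positive, weighted
#' by the recall increment). Tied scores are treated as a single
#' threshold. The error rate is `1 - AUPR` exactly.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return A list of class `MetricsReport`: `auc`, `aupr`, `er`, and the
#'   `curve` data.frame of per-threshold confusion counts
#'   (tp, fp, fn, precision, recall, fpr).
#' @examples
#' computeMetrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$aupr  # 1
#' @export
computeMetrics <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("both a positive and a negative label are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rle(s)$lengths)   # last index of each tied-score block
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  fn <- P - tp
  precision <- tp / (tp + fp)
  recall <- tp / P
  fpr <- fp / N
  auc <- sum(diff(c(0, fpr)) * (c(0, utils::head(recall, -1)) + recall) / 2)
  dtp <- diff(c(0, tp))
  aupr <- sum(precision[dtp > 0] * dtp[dtp > 0]) / P
  out <- list(auc = auc, aupr = aupr, er = 1 - aupr,
    curve = data.frame(threshold = s[last], tp = tp, fp = fp, fn = fn,
      precision = precision, recall = recall, fpr = fpr))
  class(out) <- "MetricsReport"
  out
}

#' Error rate and relative error reduction
#'
#' `errorRate(aupr)` is `1 - AUPR`, the residual precision-recall error.
#' `errorReduction(er1, er2)` is `(er2 - er1) / er2`, the relative
#' reduction achieved by the best method (error `er1`) over the
#' second-best (`er2`).
#'
#' @param aupr area under the precision-recall curve, in \[0, 1\].
#' @param er1,er2 error rates of the best and second-best methods;
#'   `er2` must be positive.
#' @return A single number.
#' @examples
#' errorRate(0.92)              # 0.08
#' errorReduction(0.18, 0.34)   # ~0.47
#' @export
errorRate <- function(aupr) {
  if (any(aupr < 0 | aupr > 1)) stop("aupr must lie in [0, 1]")
  1 - aupr
}

#' @rdname errorRate
#' @export
errorReduction <- function(er1, er2) {
  if (any(er2 <= 0))
    stop("error reduction is undefined when the reference error rate is 0")
  (er2 - er1) / er2
}

# Average precision of a single ranking (ties grouped), shared by
# computeMetrics and the MAP calculation.
averagePrecision <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  last <- cumsum(rle(scores[ord])$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  dtp <- diff(c(0, tp))
  sum((tp / (tp + fp))[dtp > 0] * dtp[dtp > 0]) / P
}

#' Mean average precision over drugs and folds
#'
#' Average precision is computed per drug within each fold over that
#' drug's test pairs; folds where a drug has no positive test pair are
#' skipped for that drug. Per-drug APs are averaged over contributing
#' folds, and MAP is the mean over drugs with at least one contributing
#' fold. A high MAP indicates performance is not driven by a few hub
#' drugs.
#'
#' @param perFold list of data.frames, one per fold, with columns `drug`,
#'   `score`, `label`.
#' @return A list with `map` and the per-drug AP table `perDrug`.
#' @export
meanAveragePrecision <- function(perFold) {
  ap <- list()
  for (fd in perFold) {
    for (d in unique(fd$drug)) {
      rows <- fd[fd$drug == d, ]
      if (sum(rows$label == 1) == 0) next
      ap[[d]] <- c(ap[[d]], averagePrecision(rows$score, rows$label))
    }
  }
  if (!length(ap))
    stop("no drug has a positive test pair in any fold; MAP is undefined")
  perDrug <- data.frame(drug = names(ap),
    ap = vapply(ap, mean, numeric(1)),
    folds = lengths(ap), row.names = NULL)
  list(map = mean(perDrug$ap), perDrug = perDrug)
}

# ---- exact Wilcoxon fold comparisons --------------------------------------

# Exact null distributions computed by dynamic programming over doubled
# (average) ranks, so tied ranks are handled exactly. Two-sided p-values
# are twice the smaller tail, capped at 1.

signedRankExact <- function(d) {
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero; test undefined")
  r2 <- round(2 * rank(abs(d)))
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  prob <- c(1, numeric(total))           # P(W2 = s), s = 0..total
  for (r in r2) {
    shifted <- c(numeric(r), prob[seq_len(total + 1 - r)])
    prob <- (prob + shifted) / 2
  }
  lo <- sum(prob[seq_len(w2 + 1)])
  hi <- sum(prob[(w2 + 1):(total + 1)])
  min(1, 2 * min(lo, hi))
}

rankSumExact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r2 <- round(2 * rank(pooled))
  w2 <- sum(r2[seq_len(na)])
  total <- sum(r2)
  # count[k+1, s+1] = subsets of size k with doubled-rank-sum s
  count <- matrix(0, na + 1, total + 1)
  count[1, 1] <- 1
  for (r in r2) {
    for (k in na:1) {                     # iterate k downwards to avoid reuse
      nz <- which(count[k, ] > 0)
      if (length(nz))
        count[k + 1, nz + r] <- count[k + 1, nz + r] + count[k, nz]
    }
  }
  dist <- count[na + 1, ]
  dist <- dist / sum(dist)
  lo <- sum(dist[seq_len(w2 + 1)])
  hi <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(lo, hi))
}

#' Exact Wilcoxon comparison of per-fold AUPRs
#'
#' Two-sided p-value from the exact small-sample null distribution
#' (enumerated by dynamic programming, so tied ranks — common when fold
#' scores repeat — are handled without falling back to a normal
#' approximation). `signed_rank` pairs folds; `rank_sum` compares
#' independent samples.
#'
#' @param a,b numeric vectors of per-fold AUPRs (equal length for
#'   `signed_rank`).
#' @param variant `"signed_rank"` or `"rank_sum"`.
#' @return The two-sided p-value.
#' @examples
#' compareFolds(seq(0.8, 0.89, 0.01) + 0.1, seq(0.8, 0.89, 0.01))  # ~0.002
#' @export
compareFolds <- function(a, b, variant = c("signed_rank", "rank_sum")) {
  variant <- match.arg(variant)
  if (variant == "signed_rank") {
    if (length(a) != length(b))
      stop("signed-rank comparison requires equal-length fold vectors")
    if (length(a) > 25) stop("exact enumeration supports up to 25 folds")
    signedRankExact(a - b)
  } else {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    if (length(a) + length(b) > 50) stop("exact enumeration supports up to 50 folds")
    rankSumExact(a, b)
  }
}

# ---- orchestrators --------------------------------------------------------

# One fold's training: rebuild graph from training positives, embed,
# normalise (fit on train), oversample, fit the booster. Test information
# never enters: only training indices and their labels are consumed.
fitFoldModel <- function(universe, trainIdx, ddEdges, ttEdges, config, seed) {
  train <- universe[trainIdx, , drop = FALSE]
  if (!is.null(config$max_negatives)) {
    neg <- which(train$label == 0)
    if (length(neg) > config$max_negatives) {
      set.seed(seed)
      drop <- neg[-sample.int(length(neg), config$max_negatives)]
      train <- train[-drop, , drop = FALSE]
    }
  }
  trainPos <- train[train$label == 1, c("drug", "target")]
  graph <- buildHeterogeneousGraph(trainPos, ddEdges, ttEdges)
  embCfg <- config$embedding
  embCfg$seed <- seed
  emb <- embedGraph(graph, embCfg)
  trainSet <- buildFeatureSet(emb, train, train$label, config$fusion)
  params <- fitMinMax(trainSet)
  balanced <- oversampleMinority(applyMinMax(trainSet, params), seed = seed)
  spec <- config$booster
  spec$seed <- seed
  list(model = trainBooster(balanced, spec), params = params, emb = emb)
}

#' Run cross-validation of the full pipeline
#'
#' For each fold the heterogeneous graph is rebuilt from training
#' positives only (test interaction edges are removed before embedding),
#' node embeddings are re-learned, features are normalised with
#' training-fitted parameters, the minority class is oversampled, the
#' booster is trained, and the held-out pairs are scored. Per-fold seeds
#' derive deterministically from the plan's seed plus the fold index, so
#' the whole report is reproducible from one master seed.
#'
#' @param dataset list with `network`, `drugSim`, `targetSim`.
#' @param config a [pipelineConfig()].
#' @param plan a `SplitPlan` from [makeRandomPairFolds()] or
#'   [makeNewDrugFolds()].
#' @return A list of class `CVReport`: per-fold metrics data.frame
#'   `folds`, aggregate `mean` and `sd`, `map`, out-of-fold scores
#'   `scores`, and the `config`/`plan` used.
#' @export
runCV <- function(dataset, config, plan) {
  stopifnot(inherits(plan, "SplitPlan"), inherits(config, "PipelineConfig"))
  net <- dataset$network
  universe <- pairUniverse(net)
  ddEdges <- knnFilter(dataset$drugSim, config$k_drug)
  ttEdges <- knnFilter(dataset$targetSim, config$k_target)
  nFolds <- length(plan$folds)
  foldRows <- vector("list", nFolds)
  perFoldDrug <- vector("list", nFolds)
  oof <- universe
  oof$score <- NA_real_
  oof$fold <- NA_integer_
  for (f in seq_len(nFolds)) {
    testIdx <- plan$folds[[f]]
    trainIdx <- setdiff(seq_len(nrow(universe)), testIdx)
    seedF <- plan$seed + f
    fit <- fitFoldModel(universe, trainIdx, ddEdges, ttEdges, config, seedF)
    test <- universe[testIdx, , drop = FALSE]
    testSet <- applyMinMax(
      buildFeatureSet(fit$emb, test, test$label, config$fusion), fit$params)
    scores <- predictScores(fit$model, testSet)
    m <- computeMetrics(scores, test$label)
    foldRows[[f]] <- data.frame(fold = f, aupr = m$aupr, auc = m$auc,
      er = m$er, n_test = nrow(test), n_pos = sum(test$label))
    perFoldDrug[[f]] <- data.frame(drug = test$drug, score = scores,
      label = test$label)
    oof$score[testIdx] <- scores
    oof$fold[testIdx] <- f
  }
  folds <- do.call(rbind, foldRows)
  report <- list(
    folds = folds,
    mean = list(aupr = mean(folds$aupr), auc = mean(folds$auc),
      er = mean(folds$er)),
    sd = list(aupr = stats::sd(folds$aupr), auc = stats::sd(folds$auc)),
    map = meanAveragePrecision(perFoldDrug)$map,
    scores = oof,
    mode = plan$mode,
    seed = plan$seed,
    config = config)
  class(report) <- "CVReport"
  report
}

#' Single train/validation/test hold-out evaluation
#'
#' Fits the pipeline on the training split and reports metrics on both
#' the validation split (for model selection) and the test split.
#'
#' @param dataset list with `network`, `drugSim`, `targetSim`.
#' @param config a [pipelineConfig()].
#' @param fractions train/valid/test fractions, see [makeHoldoutSplit()].
#' @param seed integer seed.
#' @return A list with `valid` and `test` [computeMetrics()] reports and
#'   the `plan`.
#' @export
runHoldout <- function(dataset, config, fractions = c(0.7, 0.1, 0.2),
                       seed = 1L) {
  net <- dataset$network
  plan <- makeHoldoutSplit(net, fractions, seed)
  universe <- pairUniverse(net)
  ddEdges <- knnFilter(dataset$drugSim, config$k_drug)
  ttEdges <- knnFilter(dataset$targetSim, config$k_target)
  fit <- fitFoldModel(universe, plan$folds$train, ddEdges, ttEdges, config,
    seed + 1L)
  evalSplit <- function(idx) {
    part <- universe[idx, , drop = FALSE]
    fs <- applyMinMax(
      buildFeatureSet(fit$emb, part, part$label, config$fusion), fit$params)
    computeMetrics(predictScores(fit$model, fs), part$label)
  }
  list(valid = evalSplit(plan$folds$valid), test = evalSplit(plan$folds$test),
    plan = plan)
}

#' Rank candidate novel interactions
#'
#' Trains on all known positives plus a random half of the unknown
#' pairs, scores the held-out unknown pairs, and returns the `top_n`
#' highest-scoring candidates — the pipeline's prioritisation list for
#' experimental follow-up.
#'
#' @param dataset list with `network`, `drugSim`, `targetSim`.
#' @param config a [pipelineConfig()].
#' @param top_n number of candidates to return.
#' @param seed integer seed.
#' @return data.frame with `rank`, `drug`, `target`, `score`, ordered by
#'   descending score (ties broken by drug then target id).
#' @export
rankNovel <- function(dataset, config, top_n = 5L, seed = 1L) {
  net <- dataset$network
  universe <- pairUniverse(net)
  neg <- which(universe$label == 0)
  set.seed(seed)
  trainNeg <- sort(neg[sample.int(length(neg), floor(length(neg) / 2))])
  heldNeg <- setdiff(neg, trainNeg)
  trainIdx <- sort(c(which(universe$label == 1), trainNeg))
  ddEdges <- knnFilter(dataset$drugSim, config$k_drug)
  ttEdges <- knnFilter(dataset$targetSim, config$k_target)
  fit <- fitFoldModel(universe, trainIdx, ddEdges, ttEdges, config, seed + 1L)
  held <- universe[heldNeg, , drop = FALSE]
  fs <- applyMinMax(
    buildFeatureSet(fit$emb, held, held$label, config$fusion), fit$params)
  scores <- predictScores(fit$model, fs)
  ord <- order(-scores, held$drug, held$target)
  if (top_n > length(ord)) {
    warning(sprintf("only %d held-out negatives available; truncating top_n",
      length(ord)))
    top_n <- length(ord)
  }
  sel <- ord[seq_len(top_n)]
  data.frame(rank = seq_len(top_n), drug = held$drug[sel],
    target = held$target[sel], score = scores[sel], row.names = NULL)
}

#' Serialize a CVReport
#'
#' Writes the per-fold metric table (tab-separated) followed by an
#' aggregate summary block. Contains no timestamps, so identical runs
#' produce byte-identical files.
#'
#' @param report a `CVReport` from [runCV()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeCVReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  f <- report$folds
  writeLines("fold\taupr\tauc\ter\tn_test\tn_pos", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("%d\t%.6f\t%.6f\t%.6f\t%d\t%d",
      f$fold[i], f$aupr[i], f$auc[i], f$er[i], f$n_test[i], f$n_pos[i]), con)
  }
  writeLines("", con)
  writeLines(c(
    sprintf("mean_aupr\t%.6f", report$mean$aupr),
    sprintf("mean_auc\t%.6f", report$mean$auc),
    sprintf("mean_er\t%.6f", report$mean$er),
    sprintf("sd_aupr\t%.6f", report$sd$aupr),
    sprintf("map\t%.6f", report$map),
    sprintf("mode\t%s", report$mode),
    sprintf("seed\t%d", report$seed)), con)
  invisible(path)
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport (%s, %d folds): mean AUPR %.3f (sd %.3f), mean AUC %.3f, MAP %.3f\n",
    x$mode, nrow(x$folds), x$mean$aupr, x$sd$aupr, x$mean$auc, x$map))
  invisible(x)
}
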