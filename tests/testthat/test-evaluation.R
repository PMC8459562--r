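# Random network with a positive count set exactly, every node covered.
netWithPositives <- function(m, n, nPos, seed) {
  set.seed(seed)
  y <- matrix(0, m, n)
  y[cbind(1:m, sample.int(n, m, replace = TRUE))] <- 1  # cover drugs
  for (j in which(colSums(y) == 0)) y[sample.int(m, 1), j] <- 1
  while (sum(y) < nPos) y[sample(which(y == 0), 1)] <- 1
  dimnames(y) <- list(sprintf("d%02d", 1:m), sprintf("t%02d", 1:n))
  DrugTargetNetwork(y)
}

test_that("random-pair folds are stratified partitions of the pair universe", {
  net <- netWithPositives(10, 10, 20, seed = 1)
  plan <- suppressWarnings(makeRandomPairFolds(net, 10, seed = 2))
  expect_length(plan$folds, 10)
  all_idx <- sort(unlist(plan$folds))
  expect_equal(all_idx, 1:100)                      # disjoint cover
  labels <- pairUniverse(net)$label
  posPerFold <- vapply(plan$folds, function(f) sum(labels[f]), numeric(1))
  expect_true(all(posPerFold == 2))
  expect_true(all(lengths(plan$folds) == 10))

  net25 <- netWithPositives(10, 10, 25, seed = 3)
  plan25 <- suppressWarnings(makeRandomPairFolds(net25, 10, seed = 4))
  pos25 <- vapply(plan25$folds, function(f) sum(pairUniverse(net25)$label[f]),
    numeric(1))
  expect_true(all(pos25 %in% c(2, 3)))
  expect_equal(sum(pos25), 25)
})

test_that("fold construction warns when a node loses all its positives", {
  y <- matrix(0, 4, 3, dimnames = list(paste0("d", 1:4), paste0("t", 1:3)))
  y[2:4, ] <- 1
  y[1, 1] <- 1   # d1 has a single positive: its test fold must warn
  net <- DrugTargetNetwork(y)
  warns <- testthat::capture_warnings(makeRandomPairFolds(net, 3, seed = 1))
  expect_true(any(grepl("without positives", warns)))
  expect_error(makeRandomPairFolds(netWithPositives(4, 4, 5, 1), 10),
    "fewer positive")
})

test_that("new-drug rounds partition drugs and quarantine their pairs", {
  net <- netWithPositives(10, 8, 20, seed = 5)
  plan <- makeNewDrugFolds(net, 5, seed = 6)
  expect_length(plan$folds, 5)
  expect_true(all(lengths(plan$heldOutDrugs) == 2))
  expect_setequal(unlist(plan$heldOutDrugs), drugIds(net))
  universe <- pairUniverse(net)
  for (r in 1:5) {
    held <- plan$heldOutDrugs[[r]]
    expect_setequal(unique(universe$drug[plan$folds[[r]]]), held)
    train <- universe[-plan$folds[[r]], ]
    expect_false(any(train$drug %in% held))
  }
  expect_error(makeNewDrugFolds(net, 11), "more rounds")
})

test_that("holdout split is stratified by the requested fractions", {
  net <- netWithPositives(20, 20, 60, seed = 7)
  plan <- makeHoldoutSplit(net, c(0.7, 0.1, 0.2), seed = 8)
  expect_equal(sort(unname(unlist(plan$folds))), 1:400)
  labels <- pairUniverse(net)$label
  expect_equal(sum(labels[plan$folds$train]), 42)
  expect_equal(sum(labels[plan$folds$valid]), 6)
  expect_equal(sum(labels[plan$folds$test]), 12)
  expect_error(makeHoldoutSplit(net, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("computeMetrics matches hand-worked and degenerate cases", {
  perfect <- computeMetrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$er, 0)
  expect_equal(computeMetrics(c(0.7, 0.2), c(0, 1))$aupr, 0.5)
  expect_error(computeMetrics(c(1, 0), c(1, 1)), "both")
})

test_that("AUPR equals a brute-force average-precision oracle", {
  # oracle for distinct scores: mean over positives of precision at their rank
  bruteAP <- function(scores, labels) {
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord]
    ranks <- which(y == 1)
    mean(vapply(ranks, function(r) sum(y[1:r]) / r, numeric(1)))
  }
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq_len(1000), n) / 1000  # distinct
    m <- computeMetrics(scores, labels)
    expect_equal(m$aupr, bruteAP(scores, labels), tolerance = 1e-12)
    expect_identical(m$er + m$aupr, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (rep in 1:10) {
    labels <- sample(c(0, 1), 80, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    scores <- stats::rnorm(80) + labels
    ours <- computeMetrics(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
      direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("random scores give AUPR near prevalence", {
  set.seed(41)
  labels <- rbinom(10000, 1, 0.05)
  scores <- stats::runif(10000)
  expect_lt(abs(computeMetrics(scores, labels)$aupr - 0.05), 0.02)
})

test_that("error rate and relative error reduction arithmetic", {
  expect_equal(errorRate(0.92), 0.08)
  expect_equal(errorReduction(0.18, 0.34), 16 / 34)
  expect_equal(errorReduction(0.2, 0.2), 0)
  expect_equal(errorReduction(0, 0.2), 1)
  expect_error(errorReduction(0.1, 0), "undefined")
  expect_error(errorRate(1.2), "\\[0, 1\\]")
  # monotone decreasing in the best method's error
  ers <- errorReduction(c(0.3, 0.2, 0.1), 0.4)
  expect_true(all(diff(ers) > 0))
})

test_that("mean average precision follows the per-drug per-fold convention", {
  one <- list(data.frame(drug = "d1", score = c(0.9, 0.1), label = c(1, 0)))
  expect_equal(meanAveragePrecision(one)$map, 1)
  flipped <- list(data.frame(drug = "d1", score = c(0.9, 0.1), label = c(0, 1)))
  expect_equal(meanAveragePrecision(flipped)$map, 0.5)
  two <- list(data.frame(
    drug = c("d1", "d1", "d2", "d2"),
    score = c(0.9, 0.1, 0.2, 0.8),
    label = c(1, 0, 1, 0)))
  expect_equal(meanAveragePrecision(two)$map, 0.75)
  # a fold with no positive for a drug is skipped for that drug
  twoFolds <- list(
    data.frame(drug = "d1", score = c(0.9, 0.1), label = c(1, 0)),
    data.frame(drug = "d1", score = c(0.5, 0.4), label = c(0, 0)))
  res <- meanAveragePrecision(twoFolds)
  expect_equal(res$map, 1)
  expect_equal(res$perDrug$folds, 1)
  none <- list(data.frame(drug = "d1", score = 0.5, label = 0))
  expect_error(meanAveragePrecision(none), "undefined")
})

test_that("exact Wilcoxon p-values match closed forms and stats::wilcox.test", {
  b <- seq(0.8, 0.89, 0.01)
  expect_equal(compareFolds(b + 0.1, b, "signed_rank"), 2 / 1024,
    tolerance = 1e-12)
  expect_error(compareFolds(b, b, "signed_rank"), "zero")
  expect_equal(compareFolds(1:5, 6:10, "rank_sum"), 2 / 252, tolerance = 1e-12)
  expect_error(compareFolds(1:4, 1:5, "signed_rank"), "equal-length")

  set.seed(9)
  for (rep in 1:10) {
    a <- stats::rnorm(8); c2 <- stats::rnorm(8)
    expect_equal(compareFolds(a, c2, "signed_rank"),
      stats::wilcox.test(a, c2, paired = TRUE, exact = TRUE)$p.value,
      tolerance = 1e-10)
    expect_equal(compareFolds(a, c2, "rank_sum"),
      stats::wilcox.test(a, c2, exact = TRUE)$p.value,
      tolerance = 1e-10)
  }
})

test_that("fold-trained models never see test information (leakage audit)", {
  ds <- smallDataset(m = 16, n = 16, seed = 21)
  universe <- pairUniverse(ds$network)
  dd <- knnFilter(ds$drugSim, 3); tt <- knnFilter(ds$targetSim, 3)
  set.seed(1)
  trainIdx <- sort(sample.int(nrow(universe), 200))
  cfg <- pipelineConfig(k_drug = 3, embedding = fastEmbedding(seed = 1),
    booster = boosterSpec("xgboost", n_trees = 20))
  perturbed <- universe
  testRows <- setdiff(seq_len(nrow(universe)), trainIdx)
  perturbed$label[testRows] <- 1 - perturbed$label[testRows]
  fitA <- DTIembed:::fitFoldModel(universe, trainIdx, dd, tt, cfg, seed = 7)
  fitB <- DTIembed:::fitFoldModel(perturbed, trainIdx, dd, tt, cfg, seed = 7)
  expect_identical(embeddingVectors(fitA$emb), embeddingVectors(fitB$emb))
  probe <- featureMatrix(applyMinMax(buildFeatureSet(fitA$emb,
    universe[testRows, ], universe$label[testRows], cfg$fusion), fitA$params))
  expect_identical(predictScores(fitA$model, probe),
    predictScores(fitB$model, probe))
})

test_that("runCV produces a coherent, seed-reproducible report", {
  ds <- smallDataset(m = 20, n = 20, seed = 31)
  cfg <- pipelineConfig(k_drug = 3, embedding = fastEmbedding(d = 8),
    booster = boosterSpec("xgboost", n_trees = 30))
  plan <- suppressWarnings(makeRandomPairFolds(ds$network, 3, seed = 5))
  rep1 <- runCV(ds, cfg, plan)
  expect_equal(nrow(rep1$folds), 3)
  expect_identical(rep1$folds$er, 1 - rep1$folds$aupr)
  expect_true(all(is.finite(rep1$folds$aupr)))
  expect_false(anyNA(rep1$scores$score))
  expect_gt(rep1$mean$aupr, mean(pairUniverse(ds$network)$label))

  rep2 <- runCV(ds, cfg, plan)
  f1 <- tempfile(); f2 <- tempfile()
  writeCVReport(rep1, f1); writeCVReport(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("new-drug cross-validation runs end to end", {
  ds <- smallDataset(m = 20, n = 20, seed = 33)
  cfg <- pipelineConfig(k_drug = 3, embedding = fastEmbedding(d = 8),
    booster = boosterSpec("xgboost", n_trees = 30))
  plan <- makeNewDrugFolds(ds$network, 4, seed = 2)
  rep <- runCV(ds, cfg, plan)
  expect_equal(nrow(rep$folds), 4)
  expect_true(all(rep$folds$n_pos >= 1))
})

test_that("rankNovel returns held-out unknown pairs, highest scores first", {
  ds <- generateBlockDataset(syntheticConfig(m = 30, n = 30, blocks = 3,
    pi_in = 0.95, pi_out = 0.01, sim_noise_sd = 0.03, seed = 51))
  # deliberately zero out one same-block known interaction
  y <- interactionMatrix(ds$network)
  planted <- NULL
  for (i in seq_along(ds$drugBlocks)) {
    j <- which(y[i, ] == 1 & ds$targetBlocks == ds$drugBlocks[i])[1]
    if (!is.na(j)) { planted <- c(i, j); break }
  }
  y[planted[1], planted[2]] <- 0
  ds$network <- DrugTargetNetwork(y)
  cfg <- pipelineConfig(k_drug = 4,
    embedding = node2vecConfig(d = 16, walk_length = 30, num_walks = 5, seed = 1),
    booster = boosterSpec("xgboost", n_trees = 50))

  preds <- rankNovel(ds, cfg, top_n = 5, seed = 4)
  expect_equal(nrow(preds), 5)
  expect_true(all(diff(preds$score) <= 0))
  yOrig <- interactionMatrix(ds$network)
  expect_true(all(yOrig[cbind(preds$drug, preds$target)] == 0))

  # planted-signal recovery: if the zeroed pair is among the held-out
  # negatives it must rank in their top decile
  universe <- pairUniverse(ds$network)
  neg <- which(universe$label == 0)
  set.seed(4)
  trainNeg <- sort(neg[sample.int(length(neg), floor(length(neg) / 2))])
  heldNeg <- setdiff(neg, trainNeg)
  plantedRow <- which(universe$drug == drugIds(ds$network)[planted[1]] &
    universe$target == targetIds(ds$network)[planted[2]])
  expect_true(plantedRow %in% heldNeg)
  full <- rankNovel(ds, cfg, top_n = length(heldNeg), seed = 4)
  pos <- which(full$drug == drugIds(ds$network)[planted[1]] &
    full$target == targetIds(ds$network)[planted[2]])
  expect_lte(pos, ceiling(length(heldNeg) / 10))
})

test_that("holdout evaluation reports validation and test metrics", {
  ds <- smallDataset(m = 20, n = 20, seed = 61)
  cfg <- pipelineConfig(k_drug = 3, embedding = fastEmbedding(d = 8),
    booster = boosterSpec("xgboost", n_trees = 30))
  res <- runHoldout(ds, cfg, fractions = c(0.6, 0.2, 0.2), seed = 9)
  expect_true(res$valid$aupr >= 0 && res$valid$aupr <= 1)
  expect_true(res$test$aupr >= 0 && res$test$aupr <= 1)
  expect_identical(res$test$er, 1 - res$test$aupr)
})

test_that("selectK prefers a candidate that can see the block structure", {
  ds <- smallDataset(m = 18, n = 18, seed = 71)
  cfg <- pipelineConfig(embedding = fastEmbedding(d = 8),
    booster = boosterSpec("xgboost", n_trees = 30))
  res <- suppressWarnings(selectK(ds, c(1, 5), cfg, folds = 2, seed = 3))
  expect_true(res$k %in% c(1, 5))
  expect_equal(nrow(res$sweep), 2)
  k5 <- res$sweep$mean_aupr[res$sweep$k == 5]
  k1 <- res$sweep$mean_aupr[res$sweep$k == 1]
  expect_gte(k5, k1)
  single <- suppressWarnings(selectK(ds, 3, cfg, folds = 2, seed = 3))
  expect_equal(single$k, 3)
})
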