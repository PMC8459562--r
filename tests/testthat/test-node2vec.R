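# Small helper: heterogeneous graph from explicit similarity edges only.
simOnlyGraph <- function(ddPairs, ids) {
  n <- length(ids)
  s <- matrix(0, n, n, dimnames = list(ids, ids)); diag(s) <- 1
  for (p in ddPairs) s[p[[1]], p[[2]]] <- s[p[[2]], p[[1]]] <- p[[3]]
  el <- knnFilter(SimilarityMatrix(s, ids = ids), n - 1)
  tt <- makeSim(c("tZ1", "tZ2"), list(list("tZ1", "tZ2", 0.5)))
  buildHeterogeneousGraph(data.frame(drug = character(), target = character()),
    el, knnFilter(tt, 1))
}

test_that("second-order transitions on an unweighted triangle are uniform", {
  g <- simOnlyGraph(list(list("a", "b", 1), list("b", "c", 1), list("a", "c", 1)),
    c("a", "b", "c"))
  model <- buildTransitionModel(g, p = 1, q = 1)
  for (pair in list(c("a", "b"), c("b", "c"), c("c", "a"))) {
    pr <- transitionProbability(model, current = pair[2], previous = pair[1])
    expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("a huge in-out parameter forces the walk to step back", {
  # star: center c with leaves l1..l4; previous node l1
  g <- simOnlyGraph(list(list("c", "l1", 1), list("c", "l2", 1),
    list("c", "l3", 1), list("c", "l4", 1)), c("c", "l1", "l2", "l3", "l4"))
  model <- buildTransitionModel(g, p = 1, q = 1e6)
  pr <- transitionProbability(model, current = "c", previous = "l1")
  expect_equal(unname(pr["l1"]), 1 / (1 + 3e-6), tolerance = 1e-5)
})

test_that("first steps are weight-proportional", {
  g <- simOnlyGraph(list(list("v", "a", 0.9), list("v", "b", 0.3)),
    c("v", "a", "b"))
  model <- buildTransitionModel(g, p = 1, q = 1)
  pr <- transitionProbability(model, current = "v")
  expect_equal(unname(pr["a"]), 0.75)
  expect_equal(unname(pr["b"]), 0.25)
  expect_error(buildTransitionModel(g, p = 0, q = 1), "positive")
})

test_that("alias sampling reproduces the target distribution", {
  probs <- c(0.02, 0.18, 0.5, 0.3)
  tab <- DTIembed:::aliasSetup(probs)
  expect_equal(sum(tab$probs), 1, tolerance = 1e-12)
  set.seed(123)
  draws <- replicate(1e5, DTIembed:::aliasDraw(tab))
  observed <- tabulate(draws, 4)
  chi <- stats::chisq.test(observed, p = probs)
  expect_gt(chi$p.value, 0.001)
  expect_true(all(abs(observed / 1e5 - probs) < 0.01))
})

test_that("with p = q = 1 second-order transitions equal the first-order walk", {
  ds <- smallDataset(m = 10, n = 10, seed = 6)
  g <- buildHeterogeneousGraph(interactionPairs(ds$network),
    knnFilter(ds$drugSim, 3), knnFilter(ds$targetSim, 3))
  model <- buildTransitionModel(g, p = 1, q = 1)
  nodes <- model$nodes
  for (v in which(lengths(model$nbr) > 0)[1:6]) {
    firstPr <- transitionProbability(model, nodes[v])
    for (t in model$nbr[[v]][1]) {
      # walking t -> v: with p=q=1 alpha is 1 everywhere except the return
      # step, which also has alpha 1, so the distribution matches first-order
      secondPr <- transitionProbability(model, nodes[v], nodes[t])
      expect_equal(secondPr, firstPr, tolerance = 1e-12)
    }
  }
})

test_that("transition distributions are scale-invariant in edge weights", {
  make <- function(scale) {
    simOnlyGraph(list(list("a", "b", 0.8 * scale), list("b", "c", 0.4 * scale),
      list("a", "c", 0.2 * scale)), c("a", "b", "c"))
  }
  m1 <- buildTransitionModel(make(1), p = 2, q = 0.5)
  m2 <- buildTransitionModel(make(0.5), p = 2, q = 0.5)
  for (v in c("a", "b", "c")) {
    expect_equal(transitionProbability(m1, v), transitionProbability(m2, v),
      tolerance = 1e-12)
    for (t in names(transitionProbability(m1, v))) {
      expect_equal(transitionProbability(m1, v, t),
        transitionProbability(m2, v, t), tolerance = 1e-12)
    }
  }
})

test_that("walks on a single edge alternate endpoints and honor counts", {
  dd <- makeSim(c("A", "B"), list(list("A", "B", 0.9)))
  tt <- makeSim(c("t1", "t2"), list(list("t1", "t2", 0.5)))
  g <- buildHeterogeneousGraph(
    data.frame(drug = character(), target = character()),
    knnFilter(dd, 1), knnFilter(tt, 1))
  model <- buildTransitionModel(g, 1, 1)
  corpus <- simulateWalks(model, node2vecConfig(walk_length = 3, num_walks = 2,
    seed = 1))
  expect_length(corpus$walks, 2 * 4)  # 4 non-isolated nodes
  ab <- corpus$walks[vapply(corpus$walks,
    function(w) corpus$nodes[w[1]] %in% c("A", "B"), logical(1))]
  expect_length(ab, 4)
  for (w in ab) {
    expect_length(w, 3)
    expect_equal(corpus$nodes[w][c(1, 3)], rep(corpus$nodes[w[1]], 2))
  }
})

test_that("empirical second-step frequencies match the analytic distribution", {
  g <- simOnlyGraph(list(list("c", "l1", 0.9), list("c", "l2", 0.6),
    list("c", "l3", 0.3), list("l1", "l2", 0.5)), c("c", "l1", "l2", "l3"))
  model <- buildTransitionModel(g, p = 0.5, q = 2)
  pr <- transitionProbability(model, current = "c", previous = "l1")
  tab <- get(sprintf("%d,%d", match("l1", model$nodes), match("c", model$nodes)),
    envir = model$second)
  set.seed(99)
  draws <- replicate(1e5, DTIembed:::aliasDraw(tab))
  freq <- tabulate(draws, length(pr)) / 1e5
  expect_true(all(abs(freq - unname(pr)) < 0.01))
})

test_that("walk simulation and skip-gram training are seed-deterministic", {
  ds <- smallDataset(m = 12, n = 12, seed = 2)
  g <- buildHeterogeneousGraph(interactionPairs(ds$network),
    knnFilter(ds$drugSim, 3), knnFilter(ds$targetSim, 3))
  model <- buildTransitionModel(g, 1, 1)
  cfg <- fastEmbedding(seed = 77)
  c1 <- simulateWalks(model, cfg)
  c2 <- simulateWalks(model, cfg)
  expect_identical(c1, c2)
  e1 <- trainSkipgram(c1, cfg)
  e2 <- trainSkipgram(c2, cfg)
  expect_identical(embeddingVectors(e1), embeddingVectors(e2))
  expect_true(all(is.finite(embeddingVectors(e1))))
  expect_equal(embeddingDim(e1), cfg$d)
})

test_that("two disjoint cliques separate in embedding space", {
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  pairs <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    pairs <- c(pairs, list(list(ids[i], ids[j], 0.9)),
      list(list(ids[5 + i], ids[5 + j], 0.9)))
  }
  g <- simOnlyGraph(pairs, ids)
  emb <- embedGraph(g, node2vecConfig(d = 8, walk_length = 20, num_walks = 10,
    window = 4, epochs = 5, seed = 13))
  v <- embeddingVectors(emb)[ids, ]
  v <- v / sqrt(rowSums(v^2))
  cs <- v %*% t(v)
  within <- c(cs[1:5, 1:5][upper.tri(diag(5))], cs[6:10, 6:10][upper.tri(diag(5))])
  across <- cs[1:5, 6:10]
  expect_gt(mean(within), mean(across))
})

test_that("isolated nodes are flagged and excluded from the table", {
  dd <- makeSim(c("d1", "d2", "d3"), list(list("d1", "d2", 0.8)))
  tt <- makeSim(c("t1", "t2"), list(list("t1", "t2", 0.5)))
  el <- knnFilter(dd, 1)   # d3 has only zero similarities -> isolated
  g <- buildHeterogeneousGraph(
    data.frame(drug = character(), target = character()), el, knnFilter(tt, 1))
  expect_message(
    emb <- embedGraph(g, fastEmbedding(d = 4, seed = 1)),
    "isolated")
  expect_false("d3" %in% rownames(embeddingVectors(emb)))
  expect_setequal(rownames(embeddingVectors(emb)), c("d1", "d2", "t1", "t2"))
})

test_that("corpus and embedding exports use the documented text formats", {
  dd <- makeSim(c("A", "B"), list(list("A", "B", 0.9)))
  tt <- makeSim(c("t1", "t2"), list(list("t1", "t2", 0.5)))
  g <- buildHeterogeneousGraph(
    data.frame(drug = character(), target = character()),
    knnFilter(dd, 1), knnFilter(tt, 1))
  model <- buildTransitionModel(g, 1, 1)
  corpus <- simulateWalks(model, node2vecConfig(walk_length = 3, num_walks = 1,
    seed = 1))
  f <- tempfile()
  writeWalkCorpus(corpus, f)
  expect_length(readLines(f), 4)
  emb <- trainSkipgram(corpus, fastEmbedding(d = 2, seed = 1))
  f2 <- tempfile()
  writeEmbedding(emb, f2)
  lines <- readLines(f2)
  expect_equal(lines[1], "4 2")
  expect_length(strsplit(lines[2], " ")[[1]], 3)
})
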