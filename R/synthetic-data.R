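#' Configuration for the synthetic block-structured generator
#'
#' The generator plants the statistical structure the prediction method
#' exploits: similar drugs tend to interact with similar targets. Drugs
#' and targets are assigned round-robin to `blocks` communities; a pair
#' interacts with probability `pi_in` when drug and target share a block
#' and `pi_out` otherwise, and within-family similarity is raised by
#' `sim_bonus` for same-block pairs.
#'
#' @param m,n drug and target counts.
#' @param blocks number of planted communities (must not exceed `min(m, n)`).
#' @param pi_in,pi_out within-/cross-block interaction probabilities
#'   (`pi_in >= pi_out`).
#' @param sim_base baseline similarity for cross-block pairs.
#' @param sim_bonus similarity added for same-block pairs
#'   (`sim_base + sim_bonus <= 1`).
#' @param sim_noise_sd standard deviation of Gaussian noise added to
#'   similarities before clipping to (0, 1].
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(m = 200L, n = 200L, blocks = 4L,
                            pi_in = 0.3, pi_out = 0.01,
                            sim_base = 0.2, sim_bonus = 0.6,
                            sim_noise_sd = 0.05, seed = 1L) {
  cfg <- list(m = as.integer(m), n = as.integer(n), blocks = as.integer(blocks),
    pi_in = pi_in, pi_out = pi_out, sim_base = sim_base,
    sim_bonus = sim_bonus, sim_noise_sd = sim_noise_sd,
    seed = as.integer(seed))
  if (cfg$m < 1 || cfg$n < 1) stop("m and n must be positive")
  if (cfg$blocks < 1 || cfg$blocks > min(cfg$m, cfg$n))
    stop("blocks must satisfy 1 <= blocks <= min(m, n)")
  for (p in c("pi_in", "pi_out"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must lie in [0, 1]", p))
  if (cfg$pi_in < cfg$pi_out) stop("pi_in must be >= pi_out")
  if (cfg$sim_base + cfg$sim_bonus > 1)
    stop("sim_base + sim_bonus must not exceed 1")
  if (cfg$sim_noise_sd < 0) stop("sim_noise_sd must be non-negative")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a seeded synthetic DTI dataset with planted block structure
#'
#' Produces an interaction network plus drug-drug and target-target
#' similarity matrices whose community structure is predictive of the
#' interactions. A repair pass adds one same-block interaction to any
#' drug row or target column left all-zero, so every node is seen
#' interacting at least once (as the random cross-validation setting
#' assumes). Similarities are clipped below to the smallest positive
#' double so similarity edge weights stay in (0, 1].
#'
#' @param cfg a [syntheticConfig()].
#' @return A list with elements `network` ([DrugTargetNetwork-class]),
#'   `drugSim`, `targetSim` ([SimilarityMatrix-class]) and the block
#'   assignments `drugBlocks`, `targetBlocks`.
#' @examples
#' ds <- generateBlockDataset(syntheticConfig(m = 30, n = 30, seed = 7))
#' ds$network
#' @export
generateBlockDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  drugBlocks <- rep_len(seq_len(cfg$blocks), cfg$m)
  targetBlocks <- rep_len(seq_len(cfg$blocks), cfg$n)
  same <- outer(drugBlocks, targetBlocks, `==`)
  prob <- ifelse(same, cfg$pi_in, cfg$pi_out)
  y <- matrix(as.numeric(stats::runif(cfg$m * cfg$n) < prob), cfg$m, cfg$n)

  # repair: every drug row and target column keeps >= 1 interaction
  for (i in which(rowSums(y) == 0)) {
    cand <- which(targetBlocks == drugBlocks[i])
    if (!length(cand)) cand <- seq_len(cfg$n)
    y[i, cand[sample.int(length(cand), 1L)]] <- 1
  }
  for (j in which(colSums(y) == 0)) {
    cand <- which(drugBlocks == targetBlocks[j])
    if (!length(cand)) cand <- seq_len(cfg$m)
    y[cand[sample.int(length(cand), 1L)], j] <- 1
  }

  drugIds <- sprintf("D%03d", seq_len(cfg$m))
  targetIds <- sprintf("T%03d", seq_len(cfg$n))
  dimnames(y) <- list(drugIds, targetIds)

  drugSim <- blockSimilarity(drugBlocks, drugIds, cfg)
  targetSim <- blockSimilarity(targetBlocks, targetIds, cfg)

  list(network = DrugTargetNetwork(y),
    drugSim = drugSim, targetSim = targetSim,
    drugBlocks = drugBlocks, targetBlocks = targetBlocks)
}

blockSimilarity <- function(blocks, ids, cfg) {
  n <- length(blocks)
  s <- cfg$sim_base + cfg$sim_bonus * outer(blocks, blocks, `==`)
  if (cfg$sim_noise_sd > 0) {
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- stats::rnorm(n * (n - 1) / 2, sd = cfg$sim_noise_sd)
    s <- s + noise + t(noise)
  }
  s <- pmin(pmax(s, .Machine$double.xmin), 1)
  diag(s) <- 1
  SimilarityMatrix(s, ids = ids)
}

#' Summarise a DTI dataset (known/unknown pairs and sparsity ratio)
#'
#' The sparsity ratio is the number of known interactions divided by the
#' number of unknown pairs, the standard imbalance statistic quoted for
#' the Yamanishi_08 benchmarks. `summarizeCounts()` is the counting core,
#' usable directly from printed drug/target/known counts without
#' materialising a matrix.
#'
#' @param net a [DrugTargetNetwork-class].
#' @return A list with `m`, `n`, `known`, `unknown`, `sparsity_ratio`.
#'   `sparsity_ratio` is 0 when there are no known interactions and the
#'   call errors when there are no unknown pairs (ratio undefined).
#' @examples
#' summarizeCounts(54, 26, 90)  # unknown 1314, sparsity 0.068
#' @export
summarizeDataset <- function(net) {
  y <- interactionMatrix(net)
  summarizeCounts(nrow(y), ncol(y), sum(y))
}

#' @rdname summarizeDataset
#' @param m,n,known drug count, target count and known-interaction count.
#' @export
summarizeCounts <- function(m, n, known) {
  unknown <- m * n - known
  if (unknown < 0) stop("known interactions exceed the m x n pair universe")
  if (unknown == 0)
    stop("complete interaction matrix: sparsity ratio is undefined (no unknown pairs)")
  list(m = m, n = n, known = known, unknown = unknown,
    sparsity_ratio = if (known == 0) 0 else known / unknown)
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticConfig: %d drugs x %d targets, %d blocks, pi_in=%g pi_out=%g, seed=%d\n",
    x$m, x$n, x$blocks, x$pi_in, x$pi_out, x$seed))
  invisible(x)
}
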