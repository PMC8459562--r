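# Small in-code fixtures shared across test files.

# A named square similarity matrix object from an upper-triangle spec.
makeSim <- function(ids, pairs) {
  n <- length(ids)
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(s) <- 1
  for (p in pairs) s[p[[1]], p[[2]]] <- s[p[[2]], p[[1]]] <- p[[3]]
  SimilarityMatrix(s, ids = ids)
}

# Write a tab-separated matrix file in the distribution dialect.
writeMatrixFixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# A small synthetic dataset used by pipeline-level tests.
smallDataset <- function(m = 24, n = 24, seed = 42, pi_in = 0.5) {
  generateBlockDataset(syntheticConfig(m = m, n = n, blocks = 3,
    pi_in = pi_in, pi_out = 0.02, sim_noise_sd = 0.03, seed = seed))
}

# Fast embedding settings for tests that only need structure, not quality.
fastEmbedding <- function(d = 8, seed = 1) {
  node2vecConfig(d = d, walk_length = 15, num_walks = 3, window = 3,
    epochs = 2, seed = seed)
}

# Independent brute-force KNN oracle: per-node top-k by similarity (ties by
# ascending id, zero similarities dropped), then union-symmetrised.
bruteForceKnn <- function(sim, k) {
  ids <- nodeIds(sim)
  s <- similarityValues(sim)
  sel <- character(0)
  for (id in ids) {
    others <- setdiff(ids, id)
    ord <- others[order(-s[id, others], others)]
    top <- ord[seq_len(k)]
    top <- top[s[id, top] > 0]
    sel <- c(sel, paste(pmin(id, top), pmax(id, top)))
  }
  sort(unique(sel))
}
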