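---
title: "Predicting drug-target interactions with heterogeneous network embeddings and boosting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions with heterogeneous network embeddings and boosting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DTIembed)
```

## The problem and the model

Identifying which drugs bind which protein targets is a bottleneck of drug
repositioning: experimentally confirmed interactions are scarce, while the
space of candidate drug-target pairs is enormous. DTIembed casts the task
as link prediction on a weighted heterogeneous graph $G(V, E)$ whose nodes
are $m$ drugs and $n$ targets. Three edge families make up $E$:

* **interaction edges** between a drug and a target, weight exactly 1,
  taken from the binary label matrix $Y \in \{0,1\}^{m \times n}$
  ($y_{ij} = 1$ when the interaction is known);
* **drug-drug similarity edges** with weights in $(0, 1]$ (e.g. chemical
  substructure similarity);
* **target-target similarity edges** with weights in $(0, 1]$ (e.g.
  normalised sequence-alignment scores).

Similarity scores are consumed as input, never computed here. All
unlabelled pairs form the negative class — the realistic regime in which
negatives vastly outnumber positives (for the classic four-family
gold-standard benchmarks, sparsity ratios known/unknown range from 0.068
down to 0.005; `summarizeCounts()` reproduces that arithmetic).

The pipeline has five stages:

1. **KNN sparsification** (`knnFilter()`): each similarity network keeps
   only every node's $k$ highest-scoring neighbours, cutting the edge
   count from $m(m-1)/2$ to at most $k\,m$ and discarding uninformative
   near-zero similarities. The subgraph is union-symmetrised — an edge
   survives if either endpoint selected the other — which preserves each
   node's stated neighbourhood and keeps the $k\,m$ bound. Similarity
   ties break by ascending identifier so results are deterministic;
   zero-similarity candidates are dropped even inside the top-$k$, since
   similarity edges must carry strictly positive weight.
2. **Graph assembly** (`buildHeterogeneousGraph()`): training interaction
   edges plus the two KNN subgraphs. Only training positives are passed
   in, so held-out interaction edges are structurally absent before any
   embedding is computed.
3. **Node embedding** (`embedGraph()`): second-order biased random walks
   in the node2vec style learn a map $f : V \to \mathbb{R}^d$. The first
   step from a node is weight-proportional; a later step from $v$ after
   arriving from $t$ weights each neighbour $x$ by
   $\alpha(t,x)\,w(v,x)$ with $\alpha = 1/p$ for the return move
   $x = t$, $1$ if $x$ is adjacent to $t$, and $1/q$ otherwise. The bias
   multiplies the edge weight because the graph is weighted — similarity
   strength must shape the walk. All transition distributions are stored
   as alias tables (constant-time sampling). Walk sentences feed a
   skip-gram model with negative sampling (5 negatives, initial learning
   rate 0.025, minimum count 1), trained single-threaded so a fixed seed
   gives bit-identical embeddings; multi-worker throughput was
   deliberately traded away for that reproducibility guarantee. Walks
   cross node types freely (drug → target → drug …): the heterogeneous
   graph is embedded as one network.
4. **Edge features** (`buildFeatureSet()`): a fusion operator turns the
   two node vectors of a pair into one edge vector — concatenation
   (drug first, length $2d$), Hadamard product, average, weighted-L1
   $|f(d) - f(t)|$, or weighted-L2 $(f(d) - f(t))^2$, the last two
   elementwise so the output stays a $d$-vector. Features are min-max
   normalised with parameters fitted on training rows only; test values
   are *not* clipped to $[0,1]$ — out-of-range signal is information.
   Constant training features map to 0. The minority class is then
   randomly oversampled with replacement to parity (training data only;
   every synthetic row is an exact copy).
5. **Boosting classifier** (`trainBooster()`): XGBoost
   (gradient-boosted trees, single thread, seeded) or AdaBoost — the
   classical reweighting ensemble of depth-1 decision stumps, the
   canonical weak learner when no depth is otherwise specified. AdaBoost
   scores are the normalised signed vote margin mapped to $[0,1]$.
   Hyperparameters can be tuned by grid or randomized search
   (`tuneHyperparameters()`), scored by mean AUPR over stratified folds
   of the training rows only.

## Evaluation protocols

`runCV()` implements the two cross-validation regimes:

* **Random-pair CV**: the full $m \times n$ pair universe is partitioned
  into stratified folds (per-fold positive counts differ from the ideal
  quota by at most one pair). For each fold the graph is rebuilt from
  training positives only, the embedding is re-learned, normalisation is
  re-fitted, the classifier retrained, and the held-out pairs scored.
  Per-fold seeds derive from the master seed plus the fold index.
* **New-drug CV**: drugs are partitioned into held-out groups; a round's
  test set is every pair involving its held-out drugs. Held-out drugs
  keep their similarity edges — the only mechanism by which a drug with
  no known interactions can be embedded — but contribute no interaction
  edges.

A single stratified train/validation/test split (`runHoldout()`, default
0.7/0.1/0.2 — the source experiment names no fractions, so the package
fixes conventional ones) mirrors the hold-out protocol used for large
datasets, and `rankNovel()` implements novel-interaction ranking: train
on all positives plus a seeded random half of the unknown pairs, score
the held-out half, report the top candidates. The negative split is a
single seeded partition rather than a re-use of the CV machinery — the
simpler reading of the protocol, recorded here as the package's choice.

Metrics (`computeMetrics()`): recall $= TP/(TP+FN)$, precision
$= TP/(TP+FP)$ across score thresholds; AUC by trapezoid under the ROC;
AUPR by the average-precision convention — precision summed at each newly
recalled positive, weighted by the recall increment, with tied scores
treated as one threshold. This convention is pinned down explicitly
because "area under the PR curve" is ambiguous (interpolated trapezoids
can differ); every comparison in the package uses the same rule, and an
exhaustive brute-force oracle verifies it in the tests. The error rate
is $ER = 1 - AUPR$ exactly, and the relative error reduction between a
best and second-best method is $\Delta ER = (ER_2 - ER_1)/ER_2$.
`meanAveragePrecision()` averages per-drug average precision over folds
(a fold with no positive test pair for a drug is skipped for that drug —
the convention is otherwise undefined), then over drugs: high MAP means
performance is not driven by a few promiscuous hub drugs.

`compareFolds()` gives two-sided Wilcoxon p-values (signed-rank or
rank-sum) from the *exact* small-sample null, enumerated by dynamic
programming over doubled average ranks. This matters in practice:
per-fold AUPRs often produce tied ranks, where the standard
implementation silently falls back to a normal approximation.

## The synthetic data generator

`generateBlockDataset()` plants the one statistical property the method
exploits — similar drugs tend to interact with similar targets. Drugs
and targets are assigned round-robin to $B$ blocks (deterministic
assignment, so block sizes are reproducible); a pair interacts with
probability `pi_in` inside a block and `pi_out` across blocks, and
within-family similarity is `sim_base` plus `sim_bonus` for same-block
pairs plus Gaussian noise, clipped below to the smallest positive double
so similarity edge weights stay in $(0, 1]$. A repair pass gives any
all-zero drug row or target column one same-block interaction, because
the random CV setting assumes every node is seen interacting in
training. Defaults: `m = n = 200`, `B = 4`, `pi_in = 0.3`,
`pi_out = 0.01`, `sim_base = 0.2`, `sim_bonus = 0.6`,
`sim_noise_sd = 0.05` — a sparse matrix (prevalence ≈ 8%) with strong
but noisy community similarity, the regime the real benchmarks occupy at
desk scale.

What the generator does *not* emulate: realistic chemical/sequence
similarity distributions (heavy-tailed, block-free structure), hub
drugs, correlated interaction profiles within a block, or the extreme
sparsity of the large benchmarks. Passing tests on synthetic data
therefore demonstrate that the machinery is correct and leak-free, not
that the published benchmark numbers are reproduced; those require the
original distribution files.

### What block data can and cannot show

One consequence deserves emphasis. Within a block, labels are
independent Bernoulli(`pi_in`) draws. Once test interaction edges are
removed before embedding — as the protocol requires — a test pair's
label is conditionally independent of everything the model can observe,
given block membership. The Bayes-optimal score is therefore the block
posterior, and with `pi_in = 0.5` its expected average precision over
stratified folds is ≈ 0.48 (simulation; a perfect block-membership
oracle on a realized 60 × 60, 4-block dataset scores ≈ 0.47). The
pipeline's measured mean out-of-fold AUPR of ≈ 0.5 on that
configuration — against a prevalence of ≈ 0.13 and a shuffled-label
control at prevalence — is thus *complete* signal recovery: the
generator simply does not put more recoverable signal into a
`pi_in = 0.5` block than that. Pushing AUPR materially higher on such
data would require leaking test edges into the embedding graph, which
this package structurally prevents. Higher `pi_in` (e.g. 0.9) raises
the ceiling accordingly and is what the novel-ranking tests use.

## Numerical and design choices

* **File dialect**: tab-separated matrices, header row of column
  identifiers (leading cell may be empty), targets-in-rows by default —
  the convention of the gold-standard distribution files. Internally Y
  is always drugs-in-rows.
* **Similarity asymmetry**: repaired by averaging when at most `1e-6`
  (rounding noise in distributed files), rejected beyond that; the
  stored matrix must be symmetric within `1e-9` with unit diagonal.
* **KNN symmetrisation**: union rather than intersection; the source
  protocol does not say which, so the package picks the variant that
  preserves every node's chosen neighbourhood (and the $k\,m$ bound) and
  documents it.
* **Embedding defaults**: $p = q = 1$, $d = 64$, walk length 80, 10
  walks per node, window 5, 5 epochs — the customary reference-tool
  defaults; published per-dataset optima live in supplementary material
  and are deliberately config-exposed rather than hard-coded. The
  skip-gram context window is symmetric and fixed (no random shrinking),
  one fewer source of run-to-run variation.
* **Model selection criterion**: AUPR, not AUC — the imbalance makes
  AUC over-optimistic; inner search folds default to 10 and are
  reducible for speed.
* **Negative universe**: all unknown pairs participate in CV; an
  optional uniform subsampling cap exists for very large synthetic runs
  and is off by default.
* **Degenerate inputs**: a complete interaction matrix makes the
  sparsity ratio undefined (error); single-class training labels,
  zero-reference error reductions, and all-zero Wilcoxon differences are
  all signalled explicitly rather than returning NaN.
* **Problem sizes in the checks**: the test-suite pipeline runs use
  16–24 node families with reduced walk counts; the acceptance run uses
  the 60 × 60, 4-block configuration with $d = 32$, Hadamard fusion,
  XGBoost and 5 folds. These sizes were chosen as the smallest at which
  block recovery is stable.

## Known limitations

* New-target and new-drug/new-target predictions are out of scope: a
  target with neither interaction nor similarity edges cannot be
  embedded.
* Determinism is guaranteed only single-threaded; the `workers` knob is
  accepted for API compatibility but training always runs one thread.
* AdaBoost with stumps on high-dimensional fused features is slow
  relative to XGBoost and is most useful on small datasets, which
  matches where it shines in published comparisons.
* Published benchmark AUPRs are not reproduced at desk scale; the
  shipped reference tables (`benchmarkStatistics()`, `referenceAUPR()`)
  exist so the arithmetic utilities can be exercised against the
  published numbers, not as a substitute for the data.
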