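---
title: "Methods: graph-attention classification of bifunctional lncRNAs"
author: "cncgat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-attention classification of bifunctional lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices and the open
design decisions behind `cncgat`, in the spirit of a methods supplement.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Model overview

A transcript is classified in four stages: (i) conversion into a weighted
directed De Bruijn graph over its k-mers, (ii) node featurization with
CBOW word2vec embeddings, (iii) a multi-head graph attention layer with
mean readout, (iv) a two-layer fully connected head with a logistic
output. Training is stratified 5-fold cross-validation with early
stopping; prediction averages the five fold models.

## Sequence handling

Input is FASTA; sequences are uppercased and RNA `U` is mapped to `T`, so
transcripts may arrive as RNA or DNA. The working alphabet is
`{A,C,G,T}` plus the ambiguity code `N`. Any k-mer window containing `N`
becomes a `skip` sentinel: it contributes no node, and no edge is drawn
across it. The alternative — enumerating the compatible concrete k-mers —
would fabricate counts the data do not contain, which matters because the
edge weights *are* (k+1)-mer counts.

## Graph construction

For k-mer size `k` (default 3) the nodes are the distinct k-mers in order
of first occurrence (a determinism guarantee used by the serialization
and the tests), and the raw weight of edge `i → j` is the number of
adjacent occurrences of the two k-mers, i.e. the count of the spanning
(k+1)-mer. Self-loops from homopolymer runs are legitimate counts and are
kept at this stage.

Normalization divides each weight by
`sqrt(S_down(i) * S_up(j))`, where `S_down(i)` is the summed raw weight of
node i's out-edges and `S_up(j)` that of node j's in-edges. The
formulation of this normalization admits a second reading — division by
the bare product of the two sums — and the bare product is retained as
`normalizeEdgeWeights(g, method = "product")`. The square-root form is the
default because it is invariant to scaling all counts by a constant
(doubling the coverage of the same composition should not change the
graph the model sees) and because it leaves every weight of a simple
chain at exactly 1; the product form shrinks weights quadratically with
sequence length. The unit tests pin both properties.

## Node features: CBOW embeddings

k-mers are treated as words and each transcript's k-mer sequence as one
sentence (skip sentinels split sentences). Embeddings are trained with
the continuous bag-of-words objective: the mean of the context embeddings
predicts the center k-mer. Defaults: dimension 64, window 5, 10 epochs,
minimum count 1. Window and epoch count are conventional word2vec values
and are exposed in the configuration.

Because the default vocabulary holds at most 64 words (all 3-mers), the
softmax over the vocabulary is computed exactly — no negative sampling or
hierarchical approximation is needed. Optimization is minibatch SGD with
the *summed* batch gradient, which makes a batch update equivalent (to
first order) to the classic per-token word2vec updates at the same
learning rate (0.05, decaying linearly to 0.005). Training is
single-stream and fully determined by the seed; the same corpus,
parameters and seed reproduce the table bit for bit.

Out-of-vocabulary k-mers (possible only for k > 3 or restricted corpora)
map to the zero vector with a warning. Embeddings are trained on training
transcripts only; the trainer asserts that no test identifier reaches the
embedding corpus or any fold split.

## The attention layer

Messages flow along the edge direction (5'→3'): the attention
neighborhood of node i is its in-neighbors plus i itself, matching the
self term `α_ii` in the output formula

```
h'_i = ||_{k=1..K} ( α_ii^k W^k h_i + Σ_{j∈N(i)} α_ij^k W^k h_j ).
```

Scores are `e_ij = LeakyReLU(aᵀ [W h_i ‖ W h_j])` with negative slope 0.2
(the conventional GAT value; only the activation family is prescribed).

The graph's normalized edge weights enter the attention through a
multiplicative softmax bias:

```
α_ij = W̃_ij exp(e_ij) / Σ_m W̃_im exp(e_im),   W̃_ii = 1.
```

The plain formulation of GAT attention ignores edge weights entirely, yet
the De Bruijn weights are constructed for a reason and the attention
entropy analysis downstream is explicitly "based on the edge weights".
The multiplicative bias is the smallest coupling that preserves the
softmax normalization and reduces to the plain form on unweighted graphs;
`edgeBias = "none"` keeps the literal unweighted variant selectable. How
exactly the two interacted in the original design is an open question;
this is the package's resolution of it.

A De Bruijn self-loop (e.g. `AAA → AAA`) is merged into the always-added
self term with bias weight 1 rather than duplicated; its raw count still
shaped the normalization of the node's other edges.

Readout is the arithmetic mean over node outputs — size-invariant across
transcripts whose k-mer counts differ by an order of magnitude; sum and
max are selectable. The head is `K·hidden → 64 (ReLU) → 1 (logistic)`:
the architecture only fixes "multiple" fully connected layers, and two
layers are the smallest stack that is not a bare linear probe. Dropout
0.1 is applied to the readout vector during training only.

## Training

* Loss: binary cross-entropy on the logistic output (the standard choice
  for a probability output; the loss is otherwise unspecified).
* Optimizer: Adam, learning rate 1e-4, batch size 64, at most 200 epochs.
* Early stopping: validation loss, patience 10, restoring the parameters
  of the best validation epoch.
* Class balance: training negatives are downsampled to a 1:1 ratio with
  positives (configurable), avoiding the SN/SP imbalance that plagued
  attention-free baselines on this task.
* Folds: stratified, deterministic under the seed; every training
  sequence sits in exactly one validation fold.

### Implementation notes

Training runs on minibatches of disjoint per-sequence graphs concatenated
into one block-diagonal graph. Two structural facts make this fast in
pure R: every node feature is one of at most `|vocab|+1` embedding rows,
so the per-head linear transform is computed once on the vocabulary
matrix; and with a single attention layer and mean readout, the per-head
graph vector equals `m_g %*% (V W)` where `m_g[v]` is the mean attention
mass received by vocabulary row `v` as a message source within graph `g`.
The node dimension therefore never materializes during training — forward
and backward passes reduce to per-edge vector arithmetic, grouped sums
over precomputed orderings, and vocabulary-sized dense products. The
batched path is tested to agree with the per-node single-graph layer to
1e-10, and its analytic gradients were verified against central
differences.

Minibatch composition is fixed once per fold (so the grouped-sum
structures are precomputed) and only the batch order is reshuffled each
epoch; with graphs this homogeneous the difference from full reshuffling
is negligible, and it keeps every epoch's cost flat.

Softmax stabilization subtracts a per-destination upper bound
`max(0, s_i + max_j t_j)` on the attention scores, which is constant
within each softmax group and therefore exact. A degenerate softmax
(all-zero mass) or a non-finite loss aborts training with a diagnostic
rather than continuing silently.

## Interpretability

* **Attention entropy** (base-2 Shannon entropy of a node's attention
  row, `0·log2 0 := 0`) is computed on the head-averaged — and, after
  training, member-averaged — attention distribution, renormalized per
  node before the entropy. Per-head or per-fold entropies are a
  configuration away, but averaging first matches the ensemble nature of
  the final predictor.
* **Entropy–frequency correlation** uses Spearman's rank correlation:
  k-mer frequencies are heavy-tailed and no particular coefficient is
  canonical here.
* **Rank shifts** rank k-mers by mean entropy within each class (rank 1 =
  highest; ties broken lexicographically for determinism) and report
  `rank_neg − rank_pos`.
* **EPC centrality** is operationalized as edge-percolation Monte Carlo in
  the cytoHubba tradition: each edge survives independently with
  probability equal to its (attention) weight, and a node's score is the
  expected size of its weakly connected component (default 1000
  replicates, seeded). The estimator is unbiased; the tests compare it to
  exhaustive enumeration over all edge subsets on small networks.
* **Motif enrichment** uses a 2×2 presence/absence table per class and
  Pearson's chi-squared test without continuity correction — intended
  sample sizes are hundreds of sequences per class, where the correction
  only biases the statistic.
* The attention network keeps all edges by default; a pruning threshold
  exists purely for display.

## The synthetic benchmark

The curated databases behind the original training corpus are external
resources, so the package generates its own labeled data with the signal
structure the classifier is supposed to exploit:

* background: i.i.d. nucleotides at GC 0.45 (a typical transcriptomic
  value); a higher-order Markov background is a configuration option, but
  the i.i.d. model is the simplest one in which the planted motifs
  dominate;
* positives: one planted ORF per transcript — the Kozak-context hexamer
  `GCCATG` (whose terminal ATG is the start), at least 30 stop-free sense
  codons drawn from the background codon distribution, one stop codon;
  coordinates are recorded in a ground-truth table;
* negatives: the same background with the in-frame stop-codon density
  boosted 2× (codon replacement in frame 0) and every spurious ORF longer
  than 15 codons removed by ablating its start codon. Replacing the ATG
  itself (with TAA/TAG) cannot create a new ATG at any junction, so the
  scrub provably terminates — an insertion-in-the-middle strategy can
  oscillate between reading frames indefinitely.
* lengths: uniform 200–1500 nt, spanning the short-lncRNA range.

What passing the end-to-end tests shows — and what it does not: the
pipeline can recover a planted, fairly strong translation-initiation
signal from ~800 nt of background at n = 400 with held-out AUC ≥ 0.9,
and its attention analytics localize that signal (ATG among the top
positively rank-shifted 3-mers, `GCCATG` enrichment). Real bifunctional
lncRNAs carry weaker, more heterogeneous signals entangled with
composition and homology structure; performance on the synthetic
benchmark is an upper bound of convenience, not an estimate of
performance on curated data.

## Problem sizes and determinism

The shipped verification uses 400 training and 100 held-out transcripts
(balanced), three fixed seeds for the stochastic end-to-end checks, 1000
Monte-Carlo replicates for EPC, and 200 random sequences for the
graph-counting oracle — sizes at which every stage's behaviour is already
stable. All entry points take explicit seeds and restore the caller's RNG
state; identical seeds give identical results, including bit-identical
embedding tables and synthetic datasets.

## Known limitations

* One GAT layer only; deeper stacks are deliberately out of scope.
* The k = 3 default makes the vocabulary exhaustive; for k ≥ 5 the exact
  softmax in the CBOW trainer grows with 4^k and negative sampling would
  be the natural extension.
* The synthetic generator does not emulate database composition,
  redundancy structure (CD-HIT-style), or species codon usage.
* Attention entropy is a descriptive statistic of the trained model; it
  reports where attention spreads, not a causal claim about translation.
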