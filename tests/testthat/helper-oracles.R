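# Independent oracles and fixture builders used across the suite.

random_dna <- function(L, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), L, replace = TRUE, prob = probs),
        collapse = "")
}

# Brute-force (k+1)-mer count by substring scanning, independent of the
# graph builder.
count_substring <- function(seq, pat) {
  L <- nchar(seq); w <- nchar(pat)
  if (L < w) return(0L)
  starts <- seq_len(L - w + 1L)
  sum(substring(seq, starts, starts + w - 1L) == pat)
}

# Dense reference implementation of the attention layer: explicit loops
# over heads and nodes, neighborhood = in-neighbors plus self, softmax
# biased multiplicatively by the normalized edge weight (self weight 1).
dense_gat_oracle <- function(X, g, params) {
  nodes <- kmerNodes(g)
  n <- length(nodes)
  et <- edgeTable(g)
  K <- length(params@W)
  h <- ncol(params@W[[1L]])
  slope <- params@slope
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  out <- matrix(0, n, K * h)
  for (k in seq_len(K)) {
    W <- params@W[[k]]; a <- params@a[[k]]
    H <- X %*% W
    for (i in seq_len(n)) {
      inn <- which(et$to == nodes[i] & et$from != nodes[i])
      js <- match(et$from[inn], nodes)
      wts <- et$norm_weight[inn]
      nb <- c(i, js)            # self first
      ws <- c(1, wts)
      if (params@edgeBias == "none") ws[] <- 1
      e <- vapply(nb, function(j)
        lrelu(sum(a * c(H[i, ], H[j, ]))), 0)
      al <- ws * exp(e)
      al <- al / sum(al)
      acc <- numeric(h)
      for (m in seq_along(nb)) acc <- acc + al[m] * H[nb[m], ]
      out[i, (k - 1L) * h + seq_len(h)] <- acc
    }
  }
  out
}

# Exhaustive EPC expectation (and variance): enumerate every edge subset
# of a small weighted directed network and average weak-component sizes.
epc_exhaustive <- function(net) {
  m <- igraph::ecount(net)
  n <- igraph::vcount(net)
  w <- pmin(pmax(igraph::E(net)$weight, 0), 1)
  e1 <- numeric(n); e2 <- numeric(n)
  for (mask in 0:(2^m - 1L)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    pr <- prod(ifelse(keep, w, 1 - w))
    if (pr == 0) next
    sub <- igraph::subgraph_from_edges(net, which(keep),
                                       delete.vertices = FALSE)
    comp <- igraph::components(sub, mode = "weak")
    sz <- comp$csize[comp$membership]
    e1 <- e1 + pr * sz
    e2 <- e2 + pr * sz^2
  }
  list(mean = e1, var = pmax(e2 - e1^2, 0))
}

# Small trained fixtures are expensive; build them once per session.
.fixtures <- new.env(parent = emptyenv())

toy_separable_dataset <- function(n_per_class, seed, len = 210L) {
  # positives: tandem ORF-like repeats with Kozak context; negatives:
  # stop-codon-saturated background
  with_seed_test(seed, {
    unit <- "GCCATGGCTGACGAAGGCTTGATC"
    pos <- vapply(seq_len(n_per_class), function(i) {
      s <- paste(rep(unit, ceiling(len / nchar(unit))), collapse = "")
      substr(s, 1, len)
    }, "")
    neg <- vapply(seq_len(n_per_class), function(i) {
      cods <- sample(c("TAA", "TGA", "TAG", "CGT", "ACG"), ceiling(len / 3),
                     replace = TRUE, prob = c(.25, .25, .25, .15, .1))
      substr(paste(cods, collapse = ""), 1, len)
    }, "")
    ids <- c(sprintf("p%03d", seq_len(n_per_class)),
             sprintf("n%03d", seq_len(n_per_class)))
    seqs <- Biostrings::DNAStringSet(c(pos, neg))
    names(seqs) <- ids
    labs <- stats::setNames(rep(c(1L, 0L), each = n_per_class), ids)
    LabeledTranscripts(seqs, labs)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# One ensemble + held-out predictions per seed at the benchmark scale
# (400 train / 100 test, balanced). Cached so the recovery and the
# interpretability checks reuse the same runs.
e2e_run <- function(seed) {
  key <- paste0("e2e_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  train <- generateDataset(syntheticConfig(n_pos = 200L, n_neg = 200L,
                                           seed = seed))
  test <- generateDataset(syntheticConfig(n_pos = 50L, n_neg = 50L,
                                          seed = seed + 5000L))
  ens <- trainEnsemble(train, trainConfig(seed = seed))
  pred <- predictEnsemble(ens, test)
  res <- list(train = train, test = test, ensemble = ens, pred = pred,
              metrics = computeMetrics(classLabels(test),
                                       pred$probability))
  .fixtures[[key]] <- res
  res
}
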