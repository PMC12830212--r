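# Multi-head graph attention layer, readout, and classification head.
#
# Message passing follows the edge direction (5'->3'): the attention
# neighborhood of node i is its in-neighbors plus i itself, so
#   h'_i = || over heads [ alpha_ii W h_i + sum_{j in N(i)} alpha_ij W h_j ]
# with alpha from a softmax of LeakyReLU(a^T [W h_i || W h_j]) over that
# neighborhood. When edgeBias = "multiplicative" the softmax terms are
# weighted by the normalized De Bruijn edge weights (self term weight 1),
# which is how the graph's count structure informs attention.

#' Initialize GAT + classifier parameters
#'
#' Glorot-uniform initialization for the transform matrices, attention
#' vectors and fully connected head (K*hidden -> fcHidden -> 1).
#'
#' @param d input feature dimension (embedding size).
#' @param hidden per-head hidden width.
#' @param heads number of attention heads K.
#' @param fcHidden width of the intermediate fully connected layer.
#' @param slope LeakyReLU negative slope for attention scores.
#' @param edgeBias `"multiplicative"` (default) or `"none"`; see
#'   [gatForward()].
#' @param dropout dropout rate on the readout vector during training.
#' @param seed RNG seed.
#' @return a [GatParameters] object.
#' @export
initGatParameters <- function(d = 64L, hidden = 64L, heads = 3L,
                              fcHidden = 64L, slope = 0.2,
                              edgeBias = c("multiplicative", "none"),
                              dropout = 0.1, seed = 1L) {
  edgeBias <- match.arg(edgeBias)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    W <- replicate(heads, glorot(d, hidden), simplify = FALSE)
    a <- replicate(heads,
                   runif(2L * hidden, -sqrt(6 / (2 * hidden + 1)),
                         sqrt(6 / (2 * hidden + 1))),
                   simplify = FALSE)
    new("GatParameters",
        W = W, a = a,
        fcW1 = glorot(heads * hidden, fcHidden),
        fcB1 = numeric(fcHidden),
        fcW2 = as.vector(glorot(fcHidden, 1L)),
        fcB2 = 0,
        slope = slope, edgeBias = edgeBias, dropout = dropout)
  })
}

## Extended attention edge list of a graph: the graph's directed edges
## (message src -> dst) plus one self edge per node. w = softmax bias
## weight (normalized edge weight, or 1 for self edges / edgeBias "none").
attention_edges <- function(g, edgeBias) {
  n <- length(g@nodes)
  if (edgeBias == "multiplicative") {
    if (!length(g@normWeights))
      stop("edgeBias='multiplicative' needs normalized edge weights; ",
           "run normalizeEdgeWeights() first")
    w <- g@normWeights
  } else {
    w <- rep(1, nrow(g@edges))
  }
  # The layer always adds one self attention edge per node with bias
  # weight 1; a De Bruijn self-loop (homopolymer run) is merged into that
  # self term rather than duplicated, though its raw count still shaped the
  # normalization of the node's other edges.
  self <- g@edges[, 1L] == g@edges[, 2L]
  list(
    src = c(g@edges[!self, 1L], seq_len(n)),
    dst = c(g@edges[!self, 2L], seq_len(n)),
    w = c(w[!self], rep(1, n))
  )
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

## Core per-head attention computation over an (extended) edge list.
## Returns alpha (per edge) and the aggregated node outputs.
gat_head <- function(X, src, dst, w, W, a, slope, n) {
  h <- ncol(W)
  H <- X %*% W
  s <- as.vector(H %*% a[seq_len(h)])          # a1 . (W h_i), i = dst role
  t <- as.vector(H %*% a[h + seq_len(h)])      # a2 . (W h_j), j = src role
  pre <- s[dst] + t[src]
  e <- leaky_relu(pre, slope)
  # per-destination stabilization: c_i >= every e with dst i
  cstab <- pmax(0, s + max(t))
  ex <- w * exp(e - cstab[dst])
  Z <- as.vector(group_rowsum(ex, dst))
  if (any(!is.finite(Z)) || any(Z <= 0))
    stop("attention softmax degenerate (non-finite parameters?)")
  alpha <- ex / Z[dst]
  out <- group_rowsum(alpha * H[src, , drop = FALSE], dst)
  list(alpha = alpha, out = out, H = H, pre = pre)
}

#' Forward pass of the graph attention layer
#'
#' Computes per-head attention coefficients over each node's in-neighborhood
#' (plus self) and the concatenated multi-head node outputs.
#'
#' @param features numeric matrix of node features, one row per graph node.
#' @param g the [KmerGraph] (normalized weights required when
#'   `params@edgeBias == "multiplicative"`).
#' @param params a [GatParameters] object.
#' @return list with `output` (nodes x K*hidden matrix) and `attention`
#'   (an [AttentionRecord]).
#' @export
gatForward <- function(features, g, params) {
  stopifnot(is(g, "KmerGraph"), is(params, "GatParameters"))
  n <- length(g@nodes)
  if (nrow(features) != n)
    stop("feature rows must match node count")
  if (!all(is.finite(features))) stop("non-finite features")
  ae <- attention_edges(g, params@edgeBias)
  K <- length(params@W)
  outs <- vector("list", K)
  alphas <- matrix(NA_real_, length(ae$src), K)
  for (k in seq_len(K)) {
    hk <- gat_head(features, ae$src, ae$dst, ae$w,
                   params@W[[k]], params@a[[k]], params@slope, n)
    outs[[k]] <- hk$out
    alphas[, k] <- hk$alpha
  }
  rec <- new("AttentionRecord", nodes = g@nodes,
             src = as.integer(ae$src), dst = as.integer(ae$dst),
             alpha = alphas)
  list(output = do.call(cbind, outs), attention = rec)
}

#' Graph-level readout
#'
#' Pools node outputs into a single graph vector.
#'
#' @param nodeOutputs matrix of per-node outputs.
#' @param method `"mean"` (default, size-invariant across transcripts),
#'   `"sum"`, or `"max"`.
#' @return numeric vector of length `ncol(nodeOutputs)`.
#' @export
readoutGraph <- function(nodeOutputs, method = c("mean", "sum", "max")) {
  method <- match.arg(method)
  if (!is.matrix(nodeOutputs) || nrow(nodeOutputs) == 0L)
    stop("empty node output matrix")
  switch(method,
         mean = colMeans(nodeOutputs),
         sum = colSums(nodeOutputs),
         max = apply(nodeOutputs, 2L, max))
}

#' Classify a graph vector
#'
#' Passes the readout vector through the fully connected head
#' (ReLU-activated intermediate layer, logistic output).
#'
#' @param graphVector numeric vector, length `nrow(params@fcW1)`.
#' @param params a [GatParameters] object.
#' @return the probability of bifunctionality, in (0, 1).
#' @export
classifyGraph <- function(graphVector, params) {
  if (length(graphVector) != nrow(params@fcW1))
    stop(sprintf("graph vector width %d != expected %d",
                 length(graphVector), nrow(params@fcW1)))
  z1 <- as.vector(graphVector %*% params@fcW1) + params@fcB1
  u <- pmax(z1, 0)
  z2 <- sum(u * params@fcW2) + params@fcB2
  plogis(z2)
}

#' Score one graph with one trained member
#'
#' Convenience wrapper: embedding lookup, attention layer, mean readout,
#' classification.
#'
#' @param g a normalized [KmerGraph].
#' @param table an [EmbeddingTable].
#' @param params a [GatParameters].
#' @return list with `probability` and `attention`.
#' @export
predictGraph <- function(g, table, params) {
  X <- embedNodes(g, table)
  fw <- gatForward(X, g, params)
  p <- classifyGraph(readoutGraph(fw$output), params)
  list(probability = p, attention = fw$attention)
}
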