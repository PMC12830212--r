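# Internal batched training engine.
#
# Disjoint per-sequence graphs are concatenated into one block-diagonal
# graph per minibatch. Two structural facts keep the cost low:
#   * every node feature is one of at most |vocab|+1 embedding rows, so the
#     per-head transform is computed once on the vocabulary matrix (HV) and
#     addressed by vocab index;
#   * with one attention layer and mean readout, the graph vector per head
#     is  R_g = m_g %*% HV  where m_g[v] is the mean attention mass that
#     vocabulary row v receives as a message source within graph g. The
#     node dimension therefore never materializes during training: forward
#     and backward reduce to per-edge vector arithmetic, grouped sums, and
#     |vocab|-sized dense products.
# Grouped sums reuse a precomputed ordering per batch (order + cumsum), so
# minibatch composition is fixed per fold; only the batch order is
# reshuffled every epoch.

## Per-sequence structure used in batches: vocab index per node, extended
## attention edge list (in-edges plus self, softmax bias weights), node
## count.
graph_item <- function(g, table) {
  ae <- attention_edges(g, "multiplicative")
  vid <- match(g@nodes, table@vocab)
  vid[is.na(vid)] <- length(table@vocab) + 1L  # pad row = zero vector
  list(vid = as.integer(vid), src = as.integer(ae$src),
       dst = as.integer(ae$dst), w = ae$w, n = length(g@nodes),
       graph = g)
}

## Build graph items for a set of sequences. Returns items plus the ids of
## sequences that could not be converted (too short / no edges).
prepare_graph_items <- function(seqs, k, table, onError = c("stop", "drop")) {
  onError <- match.arg(onError)
  items <- vector("list", length(seqs))
  failed <- character(0)
  reasons <- character(0)
  ids <- names(seqs)
  for (i in seq_along(seqs)) {
    res <- tryCatch({
      toks <- tokenizeKmers(seqs[[i]], k)
      g <- buildKmerGraph(toks, k, sequenceId = ids[i])
      g <- normalizeEdgeWeights(g)
      graph_item(g, table)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (onError == "stop")
        stop(sprintf("sequence '%s': %s", ids[i], conditionMessage(res)))
      failed <- c(failed, ids[i])
      reasons <- c(reasons, conditionMessage(res))
      items[i] <- list(NULL)
    } else items[[i]] <- res
  }
  list(items = items, failed = failed, reasons = setNames(reasons, failed))
}

## Fixed-group summation: precompute the ordering once, then every call is
## a permutation + cumsum. Returns a dense length-n vector.
make_grouper <- function(group, n) {
  ord <- order(group)
  g_sorted <- group[ord]
  len <- length(g_sorted)
  ends <- which(c(g_sorted[-1L] != g_sorted[-len], TRUE))
  ids <- g_sorted[ends]
  function(x) {
    cs <- cumsum(x[ord])
    out <- numeric(n)
    out[ids] <- diff(c(0, cs[ends]))
    out
  }
}

## Assemble a minibatch: concatenated edge lists with per-edge vocab ids,
## graph membership, and grouped-sum closures. `nv` = vocab size + pad row.
assemble_batch <- function(items, labels = NULL, nv) {
  ns <- vapply(items, `[[`, 0L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  vid <- unlist(lapply(items, `[[`, "vid"), use.names = FALSE)
  src <- unlist(Map(function(it, o) it$src + o, items, offs),
                use.names = FALSE)
  dst <- unlist(Map(function(it, o) it$dst + o, items, offs),
                use.names = FALSE)
  w <- unlist(lapply(items, `[[`, "w"), use.names = FALSE)
  G <- length(items)
  N <- length(vid)
  graphIdx <- rep(seq_len(G), ns)
  svidE <- vid[src]
  dvidE <- vid[dst]
  graphE <- graphIdx[dst]
  key <- graphE + G * (svidE - 1L)  # column-major index into a G x nv mass
  b <- list(
    vid = vid, src = src, dst = dst, w = w, graphIdx = graphIdx,
    nNodes = ns, y = labels, G = G, N = N, nv = nv,
    svidE = svidE, dvidE = dvidE, graphE = graphE, key = key,
    invnE = 1 / ns[graphE],
    sumDst = make_grouper(dst, N),
    sumSvid = make_grouper(svidE, nv),
    sumDvid = make_grouper(dvidE, nv),
    sumKey = make_grouper(key, G * nv)
  )
  b
}

## Forward pass over a batch. Vpad = vocab embedding matrix with a zero pad
## row appended. Returns logits, probabilities and the caches backward
## needs. R_g per head is the mean-readout graph vector.
forward_batch <- function(params, Vpad, b, training = FALSE) {
  K <- length(params@W)
  h <- ncol(params@W[[1L]])
  heads <- vector("list", K)
  R <- matrix(0, b$G, K * h)
  for (k in seq_len(K)) {
    HV <- Vpad %*% params@W[[k]]
    sv <- as.vector(HV %*% params@a[[k]][seq_len(h)])
    tv <- as.vector(HV %*% params@a[[k]][h + seq_len(h)])
    pre <- sv[b$dvidE] + tv[b$svidE]
    pos <- pre > 0
    e <- pre * (params@slope + (1 - params@slope) * pos)
    # per-destination upper bound keeps exp() in range; constant per group,
    # so the softmax is unchanged
    cE <- pmax(0, sv[b$dvidE] + max(tv[b$vid]))
    ex <- b$w * exp(e - cE)
    Z <- b$sumDst(ex)
    if (any(!is.finite(Z[b$dst])) || any(Z[b$dst] <= 0))
      stop("training diverged (degenerate attention softmax)")
    alpha <- ex / Z[b$dst]
    Mv <- matrix(b$sumKey(alpha * b$invnE), b$G, b$nv)
    R[, (k - 1L) * h + seq_len(h)] <- Mv %*% HV
    heads[[k]] <- list(HV = HV, alpha = alpha, pos = pos, Mv = Mv)
  }
  mask <- NULL
  Rd <- R
  if (training && params@dropout > 0) {
    mask <- matrix(rbinom(length(R), 1L, 1 - params@dropout), nrow(R)) /
      (1 - params@dropout)
    Rd <- R * mask
  }
  Z1 <- sweep(Rd %*% params@fcW1, 2L, params@fcB1, `+`)
  U <- pmax(Z1, 0)
  z2 <- as.vector(U %*% params@fcW2) + params@fcB2
  phat <- plogis(z2)
  list(z2 = z2, phat = phat, heads = heads, R = R, Rd = Rd,
       mask = mask, Z1 = Z1, U = U, h = h, K = K)
}

## Numerically stable mean binary cross-entropy from logits.
bce_loss <- function(z2, y) {
  mean(pmax(z2, 0) - y * z2 + log1p(exp(-abs(z2))))
}

backward_batch <- function(params, Vpad, b, fw) {
  K <- fw$K; h <- fw$h
  dz2 <- (fw$phat - b$y) / b$G
  gfcW2 <- as.vector(crossprod(fw$U, dz2))
  gfcB2 <- sum(dz2)
  dU <- outer(dz2, params@fcW2)
  dZ1 <- dU * (fw$Z1 > 0)
  gfcW1 <- crossprod(fw$Rd, dZ1)
  gfcB1 <- colSums(dZ1)
  dR <- tcrossprod(dZ1, params@fcW1)
  if (!is.null(fw$mask)) dR <- dR * fw$mask

  slope <- params@slope
  gW <- vector("list", K); ga <- vector("list", K)
  for (k in seq_len(K)) {
    hd <- fw$heads[[k]]
    dRk <- dR[, (k - 1L) * h + seq_len(h), drop = FALSE]
    dMv <- tcrossprod(dRk, hd$HV)              # G x nv
    dalpha <- dMv[b$key] * b$invnE
    gs <- b$sumDst(hd$alpha * dalpha)
    de <- hd$alpha * (dalpha - gs[b$dst])
    dpre <- de * (slope + (1 - slope) * hd$pos)
    dsv <- b$sumDvid(dpre)
    dtv <- b$sumSvid(dpre)
    a1 <- params@a[[k]][seq_len(h)]
    a2 <- params@a[[k]][h + seq_len(h)]
    dHV <- crossprod(hd$Mv, dRk) + outer(dsv, a1) + outer(dtv, a2)
    gW[[k]] <- crossprod(Vpad, dHV)
    ga[[k]] <- c(as.vector(crossprod(hd$HV, dsv)),
                 as.vector(crossprod(hd$HV, dtv)))
  }
  list(W = gW, a = ga, fcW1 = gfcW1, fcB1 = gfcB1, fcW2 = gfcW2,
       fcB2 = gfcB2)
}

## ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  p <- params_as_list(params)
  list(m = zero_like(p), v = zero_like(p), t = 0L)
}

params_as_list <- function(params) {
  list(W = params@W, a = params@a, fcW1 = params@fcW1, fcB1 = params@fcB1,
       fcW2 = params@fcW2, fcB2 = params@fcB2)
}

list_as_params <- function(p, template) {
  template@W <- p$W; template@a <- p$a
  template@fcW1 <- p$fcW1; template@fcB1 <- p$fcB1
  template@fcW2 <- p$fcW2; template@fcB2 <- p$fcB2
  template
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  p <- params_as_list(params)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- Map(walk, p, grads, state$m, state$v)
  state$m <- lapply(out, `[[`, "m")
  state$v <- lapply(out, `[[`, "v")
  params <- list_as_params(lapply(out, `[[`, "p"), params)
  list(params = params, state = state)
}
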