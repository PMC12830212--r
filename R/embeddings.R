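# CBOW word2vec over k-mer sentences, and node feature lookup.
#
# The 3-mer vocabulary has at most 64 words, so the CBOW objective is
# optimized with an exact full softmax (no negative-sampling or hierarchical
# approximation) by minibatch SGD. Training is single-stream and fully
# determined by the seed.

#' Split a token vector into skip-free sentences
#'
#' Skip markers (ambiguous windows) terminate a sentence so that CBOW
#' contexts never span an ambiguous region.
#' @keywords internal
tokensToSentences <- function(tokens) {
  runs <- split(tokens, cumsum(tokens == "skip"))
  runs <- lapply(runs, function(r) r[r != "skip"])
  runs[lengths(runs) > 0L]
}

#' Learn k-mer embeddings with CBOW
#'
#' Treats each transcript's k-mer sequence as a sentence and learns dense
#' vectors by predicting the center k-mer from the mean of its context
#' embeddings (continuous bag-of-words), with an exact softmax over the
#' vocabulary. Every k-mer appearing in the corpus enters the vocabulary
#' (minimum count one). Identical corpus, parameters and seed reproduce an
#' identical table.
#'
#' @param corpus list of k-mer token vectors (skip markers allowed; they
#'   split sentences).
#' @param d embedding dimension, >= 2.
#' @param window context half-width in tokens.
#' @param epochs full passes over the corpus.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param batchSize minibatch size for the SGD updates; the summed batch
#'   gradient emulates classic per-token word2vec SGD at the same rate.
#' @param lr initial learning rate; decays linearly to `lr/10`.
#' @return an [EmbeddingTable].
#' @export
trainEmbeddings <- function(corpus, d = 64L, window = 5L, epochs = 10L,
                            seed = 1L, batchSize = 512L, lr = 0.05) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (d < 2L) stop("embedding dimension must be >= 2")
  sentences <- unlist(lapply(corpus, tokensToSentences), recursive = FALSE)
  if (length(sentences) == 0L) stop("corpus contains no usable tokens")
  k <- nchar(sentences[[1L]][1L])
  vocab <- sort(unique(unlist(sentences, use.names = FALSE)))
  V <- length(vocab)

  # Flatten sentences and precompute, for every position, the indices of its
  # context tokens (pad index V+1 marks a missing slot near a boundary).
  ids <- lapply(sentences, function(s) match(s, vocab))
  lens <- lengths(ids)
  flat <- unlist(ids, use.names = FALSE)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  N <- length(flat)
  pad <- V + 1L
  ctx <- matrix(pad, nrow = N, ncol = 2L * window)
  col <- 0L
  for (delta in c(-(window:1), 1:window)) {
    col <- col + 1L
    # position p in sentence s (global row offs[s]+p) has context p+delta
    pos_in_sent <- sequence(lens)
    tgt <- pos_in_sent + delta
    valid <- tgt >= 1L & tgt <= rep(lens, lens)
    rows <- which(valid)
    ctx[rows, col] <- flat[rows + delta]
  }
  nctx <- rowSums(ctx != pad)
  usable <- which(nctx > 0L)

  with_seed(seed, {
    Ein <- matrix(runif(V * d, -0.5, 0.5) / d, nrow = V)
    Eout <- matrix(0, nrow = V, ncol = d)
    Epad <- rbind(Ein, 0)                      # pad row stays zero
    total_steps <- max(1L, epochs * ceiling(length(usable) / batchSize))
    step <- 0L
    for (ep in seq_len(epochs)) {
      order_ <- sample(usable)
      nb <- ceiling(length(order_) / batchSize)
      for (b in seq_len(nb)) {
        step <- step + 1L
        rate <- lr * (1 - 0.9 * (step - 1) / total_steps)
        rows <- order_[((b - 1L) * batchSize + 1L):
                       min(b * batchSize, length(order_))]
        B <- length(rows)
        cids <- ctx[rows, , drop = FALSE]
        Cm <- matrix(0, B, d)
        for (j in seq_len(ncol(cids))) Cm <- Cm + Epad[cids[, j], , drop = FALSE]
        Cm <- Cm / nctx[rows]
        scores <- tcrossprod(Cm, Eout)          # B x V
        scores <- scores - apply(scores, 1L, max)
        P <- exp(scores)
        P <- P / rowSums(P)
        G <- P
        centers <- flat[rows]
        G[cbind(seq_len(B), centers)] <- G[cbind(seq_len(B), centers)] - 1
        dC <- (G %*% Eout) / nctx[rows]
        Eout <- Eout - rate * crossprod(G, Cm)
        flat_ids <- as.vector(cids)
        keep <- flat_ids != pad
        acc <- rowsum(dC[rep(seq_len(B), times = ncol(cids)), ,
                         drop = FALSE][keep, , drop = FALSE],
                      flat_ids[keep])
        touched <- as.integer(rownames(acc))
        Epad[touched, ] <- Epad[touched, ] - rate * acc
      }
    }
    Ein <- Epad[seq_len(V), , drop = FALSE]
    new("EmbeddingTable", vocab = vocab, vectors = unname(Ein),
        k = as.integer(k),
        meta = list(d = as.integer(d), window = as.integer(window),
                    epochs = as.integer(epochs), seed = as.integer(seed),
                    model = "cbow"))
  })
}

#' Look up node features for a graph
#'
#' Row m of the result is the embedding vector of the graph's m-th node.
#' K-mers absent from the vocabulary map to the zero vector with a warning;
#' with the default k = 3 every one of the 64 k-mers occurs in any realistic
#' training corpus, so this is an edge case rather than a modeling choice.
#'
#' @param g a [KmerGraph].
#' @param table an [EmbeddingTable] with matching k.
#' @return numeric matrix, `|nodes|` rows by `d` columns.
#' @export
embedNodes <- function(g, table) {
  stopifnot(is(g, "KmerGraph"), is(table, "EmbeddingTable"))
  if (g@k != table@k)
    stop(sprintf("k mismatch: graph k=%d, embeddings k=%d", g@k, table@k))
  stopifnot(length(g@nodes) > 0L)
  idx <- match(g@nodes, table@vocab)
  oov <- is.na(idx)
  if (any(oov)) {
    warning(sprintf("%d k-mer(s) missing from embedding vocabulary: %s",
                    sum(oov), paste(head(g@nodes[oov], 5L), collapse = ", ")))
  }
  X <- matrix(0, nrow = length(g@nodes), ncol = ncol(table@vectors))
  X[!oov, ] <- table@vectors[idx[!oov], , drop = FALSE]
  rownames(X) <- g@nodes
  X
}

#' Write an embedding table as TSV
#'
#' @param table an [EmbeddingTable].
#' @param path output path (`kmer` column followed by the d components).
#' @return `path`, invisibly.
#' @export
writeEmbeddings <- function(table, path) {
  df <- data.frame(kmer = table@vocab, table@vectors,
                   check.names = FALSE)
  names(df) <- c("kmer", paste0("v", seq_len(ncol(table@vectors))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding table written by [writeEmbeddings()]
#'
#' @param path TSV path.
#' @param meta optional metadata list to attach.
#' @return an [EmbeddingTable].
#' @export
readEmbeddings <- function(path, meta = list()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  vec <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(vec) <- NULL
  new("EmbeddingTable", vocab = df$kmer, vectors = vec,
      k = as.integer(nchar(df$kmer[1L])), meta = meta)
}
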