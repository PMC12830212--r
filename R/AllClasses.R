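#' @import methods
NULL

#' Weighted directed De Bruijn graph over the k-mers of one transcript
#'
#' Nodes are the distinct k-mers of a single transcript in order of first
#' occurrence; a directed edge i -> j records that the k-mer at node j
#' immediately follows the k-mer at node i somewhere in the sequence, and its
#' raw weight is the number of such adjacencies (equivalently the count of
#' the spanning (k+1)-mer). Normalized weights are filled in by
#' [normalizeEdgeWeights()].
#'
#' @slot nodes character vector of distinct k-mers (first-occurrence order).
#' @slot edges integer matrix with columns `from`, `to` (1-based node
#'   indices).
#' @slot rawWeights integer vector, one count per edge, all >= 1.
#' @slot normWeights numeric vector of normalized weights (length 0 until
#'   [normalizeEdgeWeights()] has been applied).
#' @slot nodeCounts integer vector: occurrences of each node's k-mer among
#'   the transcript's (non-ambiguous) k-mer windows.
#' @slot k integer k-mer size.
#' @slot sequenceId identifier of the source transcript.
#' @export
setClass("KmerGraph",
  representation(
    nodes = "character",
    edges = "matrix",
    rawWeights = "integer",
    normWeights = "numeric",
    nodeCounts = "integer",
    k = "integer",
    sequenceId = "character"
  )
)

setValidity("KmerGraph", function(object) {
  msgs <- character()
  n <- length(object@nodes)
  e <- nrow(object@edges)
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicate node k-mers")
  if (n > 0L && !all(nchar(object@nodes) == object@k))
    msgs <- c(msgs, "node k-mers must have length k")
  if (ncol(object@edges) != 2L) msgs <- c(msgs, "edges must have 2 columns")
  if (length(object@rawWeights) != e)
    msgs <- c(msgs, "rawWeights length != edge count")
  if (e > 0L) {
    if (any(object@edges < 1L) || any(object@edges > n))
      msgs <- c(msgs, "edge endpoints out of range")
    if (any(object@rawWeights < 1L)) msgs <- c(msgs, "rawWeights must be >= 1")
    # De Bruijn overlap: suffix(from, k-1) == prefix(to, k-1)
    suf <- substr(object@nodes[object@edges[, 1L]], 2L, object@k)
    pre <- substr(object@nodes[object@edges[, 2L]], 1L, object@k - 1L)
    if (!all(suf == pre)) msgs <- c(msgs, "edge without (k-1)-overlap")
  }
  if (length(object@normWeights) > 0L) {
    if (length(object@normWeights) != e)
      msgs <- c(msgs, "normWeights length != edge count")
    else if (!all(is.finite(object@normWeights)) ||
             any(object@normWeights <= 0))
      msgs <- c(msgs, "normWeights must be finite and > 0")
  }
  if (length(object@nodeCounts) != n)
    msgs <- c(msgs, "nodeCounts length != node count")
  if (length(msgs)) msgs else TRUE
})

#' Dense k-mer embedding table learned by CBOW
#'
#' @slot vocab character vector of unique k-mers.
#' @slot vectors numeric matrix, one row per vocab entry, `d` columns.
#' @slot k integer k-mer size.
#' @slot meta list of training metadata (window, epochs, seed, d).
#' @export
setClass("EmbeddingTable",
  representation(vocab = "character", vectors = "matrix", k = "integer",
                 meta = "list")
)

setValidity("EmbeddingTable", function(object) {
  msgs <- character()
  if (anyDuplicated(object@vocab)) msgs <- c(msgs, "duplicate vocab entries")
  if (nrow(object@vectors) != length(object@vocab))
    msgs <- c(msgs, "vectors rows != vocab length")
  if (!all(nchar(object@vocab) == object@k))
    msgs <- c(msgs, "vocab entries must have length k")
  if (!all(is.finite(object@vectors)))
    msgs <- c(msgs, "vectors must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the multi-head graph attention classifier
#'
#' One GAT layer with `K` concatenated heads followed by a two-layer fully
#' connected head ending in a logistic output.
#'
#' @slot W list of K transform matrices, each d x hidden.
#' @slot a list of K attention vectors, each length 2*hidden.
#' @slot fcW1,fcB1,fcW2,fcB2 fully connected head parameters
#'   (K*hidden -> fcHidden -> 1).
#' @slot slope LeakyReLU negative slope used in the attention scores.
#' @slot edgeBias `"multiplicative"` to bias the attention softmax by the
#'   normalized De Bruijn edge weights, `"none"` for the plain GAT softmax.
#' @slot dropout dropout rate applied to the readout vector during training.
#' @export
setClass("GatParameters",
  representation(W = "list", a = "list", fcW1 = "matrix", fcB1 = "numeric",
                 fcW2 = "numeric", fcB2 = "numeric", slope = "numeric",
                 edgeBias = "character", dropout = "numeric")
)

setValidity("GatParameters", function(object) {
  msgs <- character()
  K <- length(object@W)
  if (K < 1L) msgs <- c(msgs, "at least one attention head required")
  if (length(object@a) != K) msgs <- c(msgs, "length(a) != length(W)")
  h <- if (K) ncol(object@W[[1L]]) else 0L
  if (K && !all(vapply(object@W, ncol, 0L) == h))
    msgs <- c(msgs, "heads disagree on hidden width")
  if (K && !all(vapply(object@a, length, 0L) == 2L * h))
    msgs <- c(msgs, "attention vectors must have length 2*hidden")
  finite <- all(vapply(object@W, function(m) all(is.finite(m)), TRUE)) &&
    all(vapply(object@a, function(v) all(is.finite(v)), TRUE)) &&
    all(is.finite(object@fcW1)) && all(is.finite(object@fcB1)) &&
    all(is.finite(object@fcW2)) && all(is.finite(object@fcB2))
  if (!finite) msgs <- c(msgs, "non-finite parameters")
  if (nrow(object@fcW1) != K * h)
    msgs <- c(msgs, "fcW1 rows must equal K*hidden")
  if (length(object@fcW2) != ncol(object@fcW1))
    msgs <- c(msgs, "fcW2 length must equal fcW1 cols")
  if (!object@edgeBias %in% c("multiplicative", "none"))
    msgs <- c(msgs, "edgeBias must be 'multiplicative' or 'none'")
  if (length(msgs)) msgs else TRUE
})

#' Per-edge attention coefficients of one forward pass
#'
#' Stores alpha for every directed attention edge (in-neighbor -> node,
#' plus one self edge per node) and every head. For each destination node
#' and head the coefficients sum to one.
#'
#' @slot nodes node k-mers, matching the originating [KmerGraph].
#' @slot src,dst integer endpoints of the attention edges (src = message
#'   sender / in-neighbor, dst = receiving node). Self edges have src == dst.
#' @slot alpha numeric matrix, one row per attention edge, one column per
#'   head.
#' @export
setClass("AttentionRecord",
  representation(nodes = "character", src = "integer", dst = "integer",
                 alpha = "matrix")
)

setValidity("AttentionRecord", function(object) {
  msgs <- character()
  e <- length(object@src)
  if (length(object@dst) != e || nrow(object@alpha) != e)
    msgs <- c(msgs, "src/dst/alpha lengths disagree")
  if (e > 0L) {
    if (any(object@alpha < -1e-9)) msgs <- c(msgs, "negative coefficients")
    sums <- rowsum(object@alpha, object@dst)
    if (any(abs(sums - 1) > 1e-6))
      msgs <- c(msgs, "attention rows must sum to 1 per node and head")
  }
  if (length(msgs)) msgs else TRUE
})

#' Labeled transcript collection
#'
#' @slot sequences a [Biostrings::DNAStringSet] with unique names.
#' @slot labels named integer vector (0/1), one per sequence;
#'   1 = bifunctional.
#' @slot truth optional annotation table (e.g. planted ORF coordinates from
#'   the synthetic generator); zero-row data.frame when absent.
#' @export
setClass("LabeledTranscripts",
  representation(sequences = "ANY", labels = "integer", truth = "data.frame")
)

setValidity("LabeledTranscripts", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids)) msgs <- c(msgs, "ids must be unique")
  if (length(object@labels) != length(object@sequences))
    msgs <- c(msgs, "one label per sequence required")
  if (!setequal(names(object@labels), ids) ||
      !identical(names(object@labels), ids))
    msgs <- c(msgs, "label names must match sequence ids in order")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validated GAT ensemble
#'
#' One trained [GatParameters] member per cross-validation fold, plus the
#' shared [EmbeddingTable] and the fold assignment used in training.
#'
#' @slot members list of [GatParameters], one per fold.
#' @slot embeddings the shared [EmbeddingTable] trained on the training set.
#' @slot folds data.frame with columns `id`, `label`, `fold`.
#' @slot config training configuration snapshot (see [trainConfig()]).
#' @slot history list of per-fold training diagnostics.
#' @export
setClass("FoldEnsemble",
  representation(members = "list", embeddings = "ANY", folds = "data.frame",
                 config = "list", history = "list")
)

setValidity("FoldEnsemble", function(object) {
  msgs <- character()
  nf <- object@config$folds %||% length(object@members)
  if (length(object@members) != nf)
    msgs <- c(msgs, "member count must equal configured fold count")
  if (!all(vapply(object@members, is, TRUE, "GatParameters")))
    msgs <- c(msgs, "members must be GatParameters")
  if (!all(c("id", "label", "fold") %in% names(object@folds)))
    msgs <- c(msgs, "folds needs columns id, label, fold")
  if (anyDuplicated(object@folds$id))
    msgs <- c(msgs, "each training id must sit in exactly one fold")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "KmerGraph", function(object) {
  cat(sprintf("KmerGraph '%s': k=%d, %d nodes, %d edges%s\n",
              object@sequenceId, object@k, length(object@nodes),
              nrow(object@edges),
              if (length(object@normWeights)) " (normalized)" else ""))
  if (length(object@nodes))
    cat("  nodes: ", paste(head(object@nodes, 8L), collapse = " "),
        if (length(object@nodes) > 8L) " ..." else "", "\n", sep = "")
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d k-mers (k=%d) x %d dims\n",
              length(object@vocab), object@k, ncol(object@vectors)))
})

setMethod("show", "GatParameters", function(object) {
  h <- ncol(object@W[[1L]])
  cat(sprintf(
    "GatParameters: %d heads, d=%d, hidden=%d, fc %d->%d->1, edgeBias=%s\n",
    length(object@W), nrow(object@W[[1L]]), h, nrow(object@fcW1),
    ncol(object@fcW1), object@edgeBias))
})

setMethod("show", "AttentionRecord", function(object) {
  cat(sprintf("AttentionRecord: %d nodes, %d attention edges, %d heads\n",
              length(object@nodes), length(object@src), ncol(object@alpha)))
})

setMethod("show", "LabeledTranscripts", function(object) {
  cat(sprintf("LabeledTranscripts: %d sequences (%d positive, %d negative)\n",
              length(object@sequences), sum(object@labels == 1L),
              sum(object@labels == 0L)))
})

setMethod("show", "FoldEnsemble", function(object) {
  cat(sprintf(
    "FoldEnsemble: %d fold members, k=%s, %d training sequences\n",
    length(object@members), object@config$k %||% "?", nrow(object@folds)))
})
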