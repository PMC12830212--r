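# De Bruijn graph construction and edge-weight normalization.

#' Build a weighted De Bruijn graph from k-mer tokens
#'
#' Nodes are the distinct non-skip k-mers in order of first occurrence. For
#' every adjacent pair of non-skip tokens a directed edge is drawn from the
#' earlier to the later k-mer; its raw weight is the number of such adjacent
#' occurrences, i.e. the count of the spanning (k+1)-mer in the sequence.
#' Self-loops from homopolymer runs are kept: they are legitimate
#' (k+1)-mer counts. No edge ever spans a skip marker (ambiguous window).
#'
#' @param tokens k-mer token vector from [tokenizeKmers()], or a raw
#'   sequence (character / `DNAString`) which is tokenized first.
#' @param k k-mer size.
#' @param sequenceId identifier stored on the graph.
#' @return a [KmerGraph] with raw weights set and normalized weights unset.
#' @examples
#' g <- buildKmerGraph("ATGCAT", k = 3, sequenceId = "demo")
#' edgeTable(g)
#' @export
buildKmerGraph <- function(tokens, k = 3L, sequenceId = "seq") {
  if (!is.character(tokens)) tokens <- as.character(tokens)
  if (length(tokens) == 1L && !identical(tokens, "skip") &&
      nchar(tokens) != k)
    tokens <- tokenizeKmers(tokens, k)
  keep <- tokens != "skip"
  if (!any(keep)) stop("sequence yields no edges (all windows ambiguous)")
  if (!all(nchar(tokens[keep]) == k))
    stop(sprintf("tokens are not %d-mers", k))

  nodes <- unique(tokens[keep])
  idx <- match(tokens, nodes)            # NA at skip positions
  from <- idx[-length(idx)]
  to <- idx[-1L]
  ok <- !is.na(from) & !is.na(to)        # adjacency only across non-skip pairs
  if (!any(ok)) stop("sequence yields no edges")
  from <- from[ok]; to <- to[ok]

  key <- (from - 1L) * length(nodes) + to
  first <- !duplicated(key)
  counts <- tabulate(match(key, key[first]), sum(first))
  edges <- cbind(from = from[first], to = to[first])

  new("KmerGraph",
      nodes = nodes,
      edges = edges,
      rawWeights = as.integer(counts),
      normWeights = numeric(0),
      nodeCounts = as.integer(tabulate(idx[keep], length(nodes))),
      k = as.integer(k),
      sequenceId = as.character(sequenceId))
}

#' Normalize De Bruijn edge weights
#'
#' Attenuates absolute count differences before model training. With
#' `method = "sqrt"` (default) each edge weight W_ij is divided by the
#' square root of the product of node i's total outgoing raw weight and
#' node j's total incoming raw weight:
#' \deqn{\tilde W_{ij} = W_{ij} / \sqrt{\sum_p W_{ip} \sum_q W_{qj}}.}
#' This symmetric-degree style normalization is invariant to scaling all
#' counts by a constant, and leaves every weight of a simple chain at 1.
#' `method = "product"` divides by the bare product of the two sums
#' instead, which shrinks weights quadratically with coverage; it is kept
#' as an alternative reading of the same normalization idea.
#'
#' @param g a [KmerGraph] with raw weights.
#' @param method `"sqrt"` or `"product"`.
#' @return the graph with `normWeights` filled in.
#' @export
normalizeEdgeWeights <- function(g, method = c("sqrt", "product")) {
  method <- match.arg(method)
  stopifnot(is(g, "KmerGraph"))
  w <- as.numeric(g@rawWeights)
  n <- length(g@nodes)
  out_sum <- as.vector(rowsum(w, g@edges[, 1L],
                              reorder = TRUE))
  out_ids <- sort(unique(g@edges[, 1L]))
  in_sum <- as.vector(rowsum(w, g@edges[, 2L], reorder = TRUE))
  in_ids <- sort(unique(g@edges[, 2L]))
  s_down <- numeric(n); s_down[out_ids] <- out_sum
  s_up <- numeric(n); s_up[in_ids] <- in_sum
  denom <- s_down[g@edges[, 1L]] * s_up[g@edges[, 2L]]
  if (any(denom <= 0))
    stop("internal error: edge with zero out-sum or in-sum")
  g@normWeights <- if (method == "sqrt") w / sqrt(denom) else w / denom
  validObject(g)
  g
}

#' Convert a KmerGraph to igraph
#'
#' @param g a [KmerGraph].
#' @return an [igraph::graph] with vertex attribute `kmer` and edge
#'   attributes `raw_weight`, `norm_weight`.
#' @export
kmerGraphToIgraph <- function(g) {
  stopifnot(is(g, "KmerGraph"))
  ig <- igraph::make_empty_graph(n = length(g@nodes), directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g@nodes)
  ig <- igraph::set_vertex_attr(ig, "kmer", value = g@nodes)
  ig <- igraph::add_edges(ig, t(g@edges))
  ig <- igraph::set_edge_attr(ig, "raw_weight", value = g@rawWeights)
  if (length(g@normWeights))
    ig <- igraph::set_edge_attr(ig, "norm_weight", value = g@normWeights)
  ig
}

#' Export a KmerGraph (or attention network) as GraphML
#'
#' @param g a [KmerGraph] or an igraph object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(g, path) {
  ig <- if (is(g, "KmerGraph")) kmerGraphToIgraph(g) else g
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
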