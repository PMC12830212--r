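# Attention-entropy analytics, rank shifts, attention networks, EPC
# centrality, and motif enrichment.

## Average attention coefficients over heads (and over a list of records,
## e.g. ensemble members sharing one graph), renormalized per destination
## node to sum to one.
aggregate_alpha <- function(records) {
  if (is(records, "AttentionRecord")) records <- list(records)
  stopifnot(length(records) >= 1L)
  ref <- records[[1L]]
  for (r in records[-1L])
    if (!identical(r@src, ref@src) || !identical(r@dst, ref@dst))
      stop("attention records do not share the same edge set")
  am <- rowMeans(do.call(cbind, lapply(records, function(r) r@alpha)))
  z <- as.vector(group_rowsum(am, ref@dst))
  list(src = ref@src, dst = ref@dst, nodes = ref@nodes,
       alpha = am / z[ref@dst])
}

#' Attention entropy per node
#'
#' Shannon entropy (base 2) of each node's aggregated attention
#' distribution over its neighborhood,
#' \deqn{H_i = -\sum_{j \in N(i)} \alpha_{ij} \log_2 \alpha_{ij},}
#' with 0 log 0 taken as 0. Coefficients are first averaged over heads (and
#' over ensemble members when several records are given) and renormalized.
#' High entropy marks k-mers that integrate context from many neighbors.
#'
#' @param record an [AttentionRecord], or a list of records over the same
#'   graph (e.g. one per ensemble member).
#' @param graph the originating [KmerGraph]; supplies each node's k-mer
#'   occurrence count.
#' @param label optional class label attached to the profile.
#' @return data.frame (`sequence_id`, `kmer`, `frequency`, `entropy_bits`,
#'   `label`).
#' @export
attentionEntropy <- function(record, graph, label = NA_integer_) {
  agg <- aggregate_alpha(record)
  stopifnot(identical(agg$nodes, graph@nodes))
  a <- agg$alpha
  term <- ifelse(a > 0, -a * log2(a), 0)
  H <- as.vector(group_rowsum(term, agg$dst))
  data.frame(
    sequence_id = graph@sequenceId,
    kmer = graph@nodes,
    frequency = graph@nodeCounts,
    entropy_bits = H,
    label = label,
    row.names = NULL
  )
}

#' Entropy profiles for a set of sequences under a trained ensemble
#'
#' Runs every ensemble member's attention layer on each sequence and
#' returns the member-averaged entropy profile per sequence.
#'
#' @param ensemble a [FoldEnsemble].
#' @param seqs named [Biostrings::DNAStringSet].
#' @param labels optional named 0/1 vector.
#' @return row-bound data.frame of [attentionEntropy()] profiles.
#' @export
entropyProfiles <- function(ensemble, seqs, labels = NULL) {
  cfg <- ensemble@config
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    g <- normalizeEdgeWeights(
      buildKmerGraph(tokenizeKmers(seqs[[i]], cfg$k), cfg$k, id),
      method = cfg$edge_norm)
    X <- embedNodes(g, ensemble@embeddings)
    recs <- lapply(ensemble@members,
                   function(p) gatForward(X, g, p)$attention)
    lab <- if (is.null(labels)) NA_integer_ else as.integer(labels[[id]])
    out[[i]] <- attentionEntropy(recs, g, lab)
  }
  do.call(rbind, out)
}

#' Correlation between k-mer attention entropy and frequency
#'
#' Aggregates mean entropy and mean frequency per k-mer (separately per
#' class when labels are present) and reports the Spearman rank
#' correlation. Spearman is used because k-mer frequencies are
#' heavy-tailed.
#'
#' @param profiles data.frame from [attentionEntropy()] /
#'   [entropyProfiles()].
#' @return data.frame with one row per class: `label`, `rho`, `p_value`,
#'   `n_kmers`.
#' @export
entropyFrequencyCorrelation <- function(profiles) {
  classes <- unique(profiles$label)
  res <- lapply(classes, function(cl) {
    same <- if (is.na(cl)) is.na(profiles$label)
            else !is.na(profiles$label) & profiles$label == cl
    sub <- profiles[same, , drop = FALSE]
    ent <- tapply(sub$entropy_bits, sub$kmer, mean)
    freq <- tapply(sub$frequency, sub$kmer, mean)
    if (length(ent) < 3L)
      stop("need at least 3 k-mers per class for a correlation")
    if (length(unique(ent)) == 1L || length(unique(freq)) == 1L) {
      warning("constant entropy or frequency: correlation undefined")
      return(data.frame(label = cl, rho = NA_real_, p_value = NA_real_,
                        n_kmers = length(ent)))
    }
    ct <- suppressWarnings(
      cor.test(freq, ent, method = "spearman", exact = FALSE))
    data.frame(label = cl, rho = unname(ct$estimate),
               p_value = ct$p.value, n_kmers = length(ent))
  })
  do.call(rbind, res)
}

#' Rank shift of k-mer attention entropy between classes
#'
#' Ranks k-mers by mean entropy within each class (rank 1 = highest
#' entropy; ties broken lexicographically) and reports the shift
#' `rank_neg - rank_pos`: a positive shift means the k-mer holds a
#' relatively higher attention-entropy rank in positive (bifunctional)
#' samples.
#'
#' @param posProfiles,negProfiles entropy profile data.frames for the two
#'   classes.
#' @return data.frame (`kmer`, `mean_entropy_pos`, `mean_entropy_neg`,
#'   `rank_pos`, `rank_neg`, `shift`) sorted by decreasing `|shift|`.
#' @export
rankShift <- function(posProfiles, negProfiles) {
  if (nrow(posProfiles) == 0L || nrow(negProfiles) == 0L)
    stop("both classes need at least one profile")
  mpos <- tapply(posProfiles$entropy_bits, posProfiles$kmer, mean)
  mneg <- tapply(negProfiles$entropy_bits, negProfiles$kmer, mean)
  kmers <- sort(union(names(mpos), names(mneg)))
  # a k-mer never seen in a class ranks last there (entropy -Inf)
  epos <- ifelse(kmers %in% names(mpos), mpos[kmers], -Inf)
  eneg <- ifelse(kmers %in% names(mneg), mneg[kmers], -Inf)
  rank_by <- function(e) {
    ord <- order(-e, kmers)
    r <- integer(length(e)); r[ord] <- seq_along(e)
    r
  }
  rpos <- rank_by(epos)
  rneg <- rank_by(eneg)
  out <- data.frame(
    kmer = kmers,
    mean_entropy_pos = as.vector(epos),
    mean_entropy_neg = as.vector(eneg),
    rank_pos = rpos,
    rank_neg = rneg,
    shift = rneg - rpos,
    row.names = NULL
  )
  out[order(-abs(out$shift), out$kmer), , drop = FALSE]
}

#' Attention-weight interaction network of one sequence
#'
#' Runs the attention layer of every ensemble member on the sequence's
#' De Bruijn graph and builds a directed igraph whose edge weights are the
#' head- and member-averaged attention coefficients (per-node outgoing
#' rows renormalized to sum to one). Self edges are included. Edges with
#' weight below `prune` can optionally be dropped for display.
#'
#' @param seq a single sequence (character / `DNAString`) or a length-one
#'   named `DNAStringSet`.
#' @param ensemble a [FoldEnsemble].
#' @param prune drop edges with weight < `prune` (default 0 keeps all).
#' @param id sequence identifier.
#' @return an [igraph::graph] with edge attribute `weight`.
#' @export
buildAttentionNetwork <- function(seq, ensemble, prune = 0,
                                  id = "sequence") {
  cfg <- ensemble@config
  if (is(seq, "XStringSet")) {
    if (!is.null(names(seq))) id <- names(seq)[1L]
    seq <- seq[[1L]]
  }
  g <- normalizeEdgeWeights(
    buildKmerGraph(tokenizeKmers(seq, cfg$k), cfg$k, id),
    method = cfg$edge_norm)
  X <- embedNodes(g, ensemble@embeddings)
  recs <- lapply(ensemble@members, function(p) gatForward(X, g, p)$attention)
  agg <- aggregate_alpha(recs)
  keep <- agg$alpha >= prune
  net <- igraph::make_empty_graph(n = length(g@nodes), directed = TRUE)
  net <- igraph::set_vertex_attr(net, "name", value = g@nodes)
  # attention edge j -> i carries node i's attention on in-neighbor j;
  # the network edge keeps the message direction src -> dst
  net <- igraph::add_edges(net, rbind(agg$src[keep], agg$dst[keep]))
  net <- igraph::set_edge_attr(net, "weight", value = agg$alpha[keep])
  net
}

#' Edge-percolated-component (EPC) centrality
#'
#' Monte-Carlo percolation: in each replicate every edge is retained
#' independently with probability equal to its weight (clamped to [0, 1]);
#' a node's score is the expected size of its weakly connected component
#' in the retained graph. Hubs of the attention network score highest.
#'
#' @param net an igraph with a `weight` edge attribute in [0, 1].
#' @param replicates number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return data.frame (`kmer`, `epc`) sorted by decreasing score.
#' @export
epcCentrality <- function(net, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  w <- pmin(pmax(igraph::E(net)$weight, 0), 1)
  m <- length(w)
  with_seed(seed, {
    total <- numeric(n)
    for (r in seq_len(replicates)) {
      keep <- runif(m) < w
      sub <- igraph::subgraph_from_edges(net, which(keep),
                                         delete.vertices = FALSE)
      comp <- igraph::components(sub, mode = "weak")
      total <- total + comp$csize[comp$membership]
    }
    out <- data.frame(kmer = igraph::V(net)$name %||% as.character(seq_len(n)),
                      epc = total / replicates, row.names = NULL)
    out[order(-out$epc, out$kmer), , drop = FALSE]
  })
}

#' Motif enrichment between classes
#'
#' Builds the 2x2 presence/absence contingency table (does a sequence
#' contain at least one occurrence of the motif, by class) and applies
#' Pearson's chi-squared test without continuity correction (df = 1).
#'
#' @param posSeqs,negSeqs character vectors or `DNAStringSet`s.
#' @param motif a motif over `{A,C,G,T}` (e.g. `"GCCATG"`).
#' @return list with `statistic`, `p_value`, `table` (2x2 counts), and
#'   `direction` (+1 when the motif is more prevalent in positives).
#' @export
motifEnrichment <- function(posSeqs, negSeqs, motif) {
  stopifnot(grepl("^[ACGT]+$", motif))
  pos <- as.character(posSeqs)
  neg <- as.character(negSeqs)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be non-empty")
  hit_pos <- grepl(motif, pos, fixed = TRUE)
  hit_neg <- grepl(motif, neg, fixed = TRUE)
  tab <- rbind(positive = c(present = sum(hit_pos),
                            absent = sum(!hit_pos)),
               negative = c(present = sum(hit_neg),
                            absent = sum(!hit_neg)))
  if (any(colSums(tab) == 0L))
    stop("degenerate contingency table (motif present or absent in all ",
         "sequences)")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab,
       direction = sign(mean(hit_pos) - mean(hit_neg)))
}
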