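# Attention entropy, rank shifts, EPC centrality, motif enrichment.

# Hand-built attention record over a 3-node chain graph.
record_for <- function(g, alpha_by_dst) {
  n <- length(kmerNodes(g))
  self <- g@edges[, 1] == g@edges[, 2]
  src <- c(g@edges[!self, 1], seq_len(n))
  dst <- c(g@edges[!self, 2], seq_len(n))
  alpha <- numeric(length(src))
  for (i in seq_len(n)) {
    rows <- which(dst == i)
    alpha[rows] <- alpha_by_dst[[i]][seq_along(rows)]
  }
  new("AttentionRecord", nodes = kmerNodes(g), src = as.integer(src),
      dst = as.integer(dst), alpha = cbind(alpha))
}

test_that("attention entropy matches direct Shannon evaluation", {
  g <- buildKmerGraph("ATGCA", 3, "ent")  # chain ATG -> TGC -> GCA
  # node 1: self only ([1.0] -> 0 bits); node 2: [in, self]; node 3 likewise
  rec <- record_for(g, list(1, c(0.5, 0.5), c(0.25, 0.75)))
  prof <- attentionEntropy(rec, g)
  expect_equal(prof$entropy_bits[1], 0)
  expect_equal(prof$entropy_bits[2], 1)
  expect_equal(prof$entropy_bits[3],
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(prof$frequency, c(1L, 1L, 1L))

  # uniform over 4 -> 2 bits; [0.5, 0.25, 0.25] -> 1.5 bits (checked by
  # direct evaluation of -sum(a log2 a))
  expect_equal(-sum(rep(0.25, 4) * log2(rep(0.25, 4))), 2)
  a <- c(0.5, 0.25, 0.25)
  expect_equal(-sum(a * log2(a)), 1.5)
})

test_that("entropy is bounded by log2 of the neighborhood size", {
  with_seed_test(41, {
    for (i in 1:5) {
      g <- normalizeEdgeWeights(buildKmerGraph(random_dna(300), 3, "b"))
      p <- initGatParameters(d = 8, hidden = 6, heads = 3, seed = i)
      X <- matrix(rnorm(length(kmerNodes(g)) * 8), ncol = 8)
      rec <- gatForward(X, g, p)$attention
      prof <- attentionEntropy(rec, g)
      nb_size <- table(rec@dst)
      expect_true(all(prof$entropy_bits <=
                        log2(as.numeric(nb_size)) + 1e-9))
      expect_true(all(prof$entropy_bits >= -1e-12))
    }
  })
})

test_that("entropy-frequency correlation recovers monotone structure", {
  prof <- data.frame(
    sequence_id = "s", kmer = sprintf("K%02d", 1:10),
    frequency = 1:10, entropy_bits = seq(0.1, 1, 0.1), label = 1L)
  res <- entropyFrequencyCorrelation(prof)
  expect_equal(res$rho, 1)
  prof$entropy_bits <- rev(prof$entropy_bits)
  expect_equal(entropyFrequencyCorrelation(prof)$rho, -1)

  # random pairing: |rho| small, p from the standard null
  with_seed_test(12, {
    prof64 <- data.frame(
      sequence_id = "s", kmer = sprintf("K%02d", 1:64),
      frequency = sample(1:64), entropy_bits = runif(64), label = 0L)
    r <- entropyFrequencyCorrelation(prof64)
    expect_lt(abs(r$rho), 0.35)
    expect_gt(r$p_value, 0.01)
  })

  cons <- data.frame(sequence_id = "s", kmer = c("A", "B", "C"),
                     frequency = 1:3, entropy_bits = rep(0.5, 3),
                     label = 1L)
  expect_warning(rc <- entropyFrequencyCorrelation(cons), "constant")
  expect_true(is.na(rc$rho))
})

test_that("rank shift reports rank_neg minus rank_pos with lexicographic ties", {
  mk <- function(kmers, ent, lab)
    data.frame(sequence_id = "s", kmer = kmers, frequency = 1,
               entropy_bits = ent, label = lab)
  # identical rankings -> all shifts zero
  rs0 <- rankShift(mk(c("AAA", "CCC"), c(2, 1), 1),
                   mk(c("AAA", "CCC"), c(2, 1), 0))
  expect_true(all(rs0$shift == 0))
  # reversed rankings over m k-mers -> max |shift| = m - 1
  km <- c("AAA", "CCC", "GGG", "TTT")
  rsr <- rankShift(mk(km, 4:1, 1), mk(km, 1:4, 0))
  expect_equal(max(abs(rsr$shift)), 3L)
  # pos ranks (1,2,3), neg ranks (3,1,2) -> shifts (+2,-1,-1)
  rs <- rankShift(mk(c("AAA", "CCC", "GGG"), c(3, 2, 1), 1),
                  mk(c("AAA", "CCC", "GGG"), c(1, 3, 2), 0))
  expect_equal(rs$shift[rs$kmer == "AAA"], 2L)
  expect_equal(rs$shift[rs$kmer == "CCC"], -1L)
  expect_equal(rs$shift[rs$kmer == "GGG"], -1L)
  # sorted by decreasing |shift|
  expect_equal(rs$kmer[1], "AAA")
  # ties broken lexicographically
  tied <- rankShift(mk(c("CCC", "AAA"), c(1, 1), 1),
                    mk(c("CCC", "AAA"), c(1, 1), 0))
  expect_equal(tied$rank_pos[tied$kmer == "AAA"], 1L)
})

test_that("EPC centrality matches deterministic and exhaustive expectations", {
  # all weights 1 on a weakly connected 5-node ring: every score = 5
  ring <- igraph::make_ring(5, directed = TRUE, circular = TRUE)
  igraph::E(ring)$weight <- 1
  sc <- epcCentrality(ring, replicates = 10, seed = 1)
  expect_equal(sc$epc, rep(5, 5))

  # isolated node scores 1
  iso <- igraph::make_empty_graph(2, directed = TRUE)
  iso <- igraph::set_vertex_attr(iso, "name", value = c("a", "b"))
  iso <- igraph::add_edges(iso, c(1, 1))
  igraph::E(iso)$weight <- 1
  sco <- epcCentrality(iso, replicates = 5, seed = 1)
  expect_equal(sco$epc[sco$kmer == "b"], 1)

  # Monte-Carlo matches the exhaustive expectation within 3 SE on small nets
  with_seed_test(71, {
    for (i in 1:3) {
      n <- 4L
      net <- igraph::make_empty_graph(n, directed = TRUE)
      igraph::V(net)$name <- paste0("v", seq_len(n))
      edges <- matrix(sample(n, 10, replace = TRUE), ncol = 2)
      edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
      net <- igraph::add_edges(net, t(edges))
      igraph::E(net)$weight <- runif(nrow(edges), 0.2, 0.8)
      truth <- epc_exhaustive(net)
      reps <- 1500L
      mc <- epcCentrality(net, replicates = reps, seed = i)
      mc <- mc[match(paste0("v", seq_len(n)), mc$kmer), ]
      se <- sqrt(truth$var / reps)
      expect_true(all(abs(mc$epc - truth$mean) <= 3 * se + 1e-9))
    }
  })

  expect_identical(epcCentrality(ring, 20, seed = 5),
                   epcCentrality(ring, 20, seed = 5))
})

test_that("motif enrichment builds the 2x2 table and Pearson statistic", {
  # equal presence proportions -> statistic 0
  pos <- c("GCCATGAAA", "GCCATGCCC", "AAAAAAA", "CCCCCCC")
  neg <- c("GCCATGTTT", "GCCATGGGG", "TTTTTTT", "GGGGGGG")
  r0 <- motifEnrichment(pos, neg, "GCCATG")
  expect_equal(r0$statistic, 0)

  # [[30,70],[5,95]] -> X2 = 2*(12.5^2/17.5) + 2*(12.5^2/82.5) = 21.645
  pos <- c(replicate(30, paste0(random_dna(20), "GCCATG", random_dna(20))),
           replicate(70, gsub("GCCATG", "GCCAAG",
                              random_dna(40), fixed = TRUE)))
  neg <- c(replicate(5, paste0(random_dna(20), "GCCATG", random_dna(20))),
           replicate(95, gsub("GCCATG", "GCCAAG",
                              random_dna(40), fixed = TRUE)))
  r <- motifEnrichment(pos, neg, "GCCATG")
  expect_equal(unname(r$table["positive", "present"]), 30)
  expect_equal(unname(r$table["negative", "present"]), 5)
  x2_hand <- 2 * (12.5^2 / 17.5) + 2 * (12.5^2 / 82.5)
  expect_equal(r$statistic, x2_hand, tolerance = 1e-6)
  expect_equal(r$p_value, stats::pchisq(x2_hand, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(r$direction, 1)

  # motif absent everywhere -> degenerate table
  expect_error(motifEnrichment(c("AAAA"), c("CCCC"), "GGG"), "degenerate")
  expect_error(motifEnrichment(character(0), c("CCCC"), "AAA"),
               "non-empty")
})

test_that("attention networks keep weights in [0,1] with renormalized rows", {
  ds <- toy_separable_dataset(6, seed = 91)
  cfg <- trainConfig(max_epochs = 2, folds = 2, batch_size = 8, seed = 9)
  ens <- trainEnsemble(ds, cfg)
  net <- buildAttentionNetwork(transcripts(ds)[1], ens)
  w <- igraph::E(net)$weight
  expect_true(all(w >= 0 & w <= 1))
  # incoming attention per node sums to 1 (rows are per-destination)
  for (v in seq_len(igraph::vcount(net))) {
    inc <- igraph::incident(net, v, mode = "in")
    expect_equal(sum(w[inc]), 1, tolerance = 1e-9)
  }
  # single-node sequence: one node with a self edge of weight 1
  one <- Biostrings::DNAStringSet(c(mono = "AAAAAA"))
  net1 <- buildAttentionNetwork(one, ens)
  expect_equal(igraph::vcount(net1), 1L)
  expect_equal(igraph::E(net1)$weight, 1)
})
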