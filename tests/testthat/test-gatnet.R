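# Graph attention layer, readout, classification head.

make_features <- function(g, d, seed) {
  with_seed_test(seed, matrix(rnorm(length(kmerNodes(g)) * d), ncol = d))
}

test_that("a single-node graph attends only to itself", {
  g <- normalizeEdgeWeights(buildKmerGraph("AAAA", 3, "solo"))
  expect_equal(kmerNodes(g), "AAA")
  p <- initGatParameters(d = 4, hidden = 3, heads = 1, fcHidden = 2,
                         seed = 1)
  X <- matrix(rnorm(4), 1, 4)
  fw <- gatForward(X, g, p)
  expect_equal(unname(fw$attention@alpha[, 1]), 1)
  expect_equal(unname(fw$output), unname(X %*% p@W[[1]]), tolerance = 1e-12)
})

test_that("attention rows sum to one for every node and head", {
  with_seed_test(21, {
    for (i in 1:5) {
      g <- normalizeEdgeWeights(buildKmerGraph(random_dna(200), 3, "r"))
      p <- initGatParameters(d = 8, hidden = 6, heads = 3, seed = i)
      fw <- gatForward(make_features(g, 8, i), g, p)
      sums <- rowsum(fw$attention@alpha, fw$attention@dst)
      expect_true(all(abs(sums - 1) < 1e-9))
      expect_true(all(fw$attention@alpha >= 0))
    }
  })
})

test_that("vectorized forward matches the dense loop oracle on small graphs", {
  with_seed_test(33, {
    for (i in 1:25) {
      # short sequences give graphs with few nodes
      s <- random_dna(sample(6:12, 1))
      g <- tryCatch(normalizeEdgeWeights(buildKmerGraph(s, 3, "o")),
                    error = function(e) NULL)
      if (is.null(g)) next
      K <- sample(1:2, 1)
      p <- initGatParameters(d = 5, hidden = 4, heads = K, seed = i)
      X <- make_features(g, 5, i + 100)
      fw <- gatForward(X, g, p)
      expect_equal(fw$output, dense_gat_oracle(X, g, p),
                   tolerance = 1e-5, ignore_attr = TRUE)
    }
  })
})

test_that("outputs are node-permutation equivariant", {
  with_seed_test(55, {
    s <- random_dna(150)
    g <- normalizeEdgeWeights(buildKmerGraph(s, 3, "perm"))
    n <- length(kmerNodes(g))
    p <- initGatParameters(d = 6, hidden = 5, heads = 2, seed = 2)
    X <- make_features(g, 6, 9)
    fw <- gatForward(X, g, p)
    perm <- sample(n)
    # permute node order (and re-index edges) by hand
    gp <- g
    gp@nodes <- g@nodes[perm]
    inv <- integer(n); inv[perm] <- seq_len(n)
    gp@edges <- cbind(from = inv[g@edges[, 1]], to = inv[g@edges[, 2]])
    gp@nodeCounts <- g@nodeCounts[perm]
    fwp <- gatForward(X[perm, , drop = FALSE], gp, p)
    expect_equal(fwp$output, fw$output[perm, , drop = FALSE],
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(readoutGraph(fwp$output), readoutGraph(fw$output),
                 tolerance = 1e-6)
    expect_equal(classifyGraph(readoutGraph(fwp$output), p),
                 classifyGraph(readoutGraph(fw$output), p),
                 tolerance = 1e-9)
  })
})

test_that("readout pools as requested", {
  v <- c(1, -2, 3)
  m <- rbind(v, v, v)
  expect_equal(readoutGraph(m), v, ignore_attr = TRUE)
  expect_equal(readoutGraph(m[1, , drop = FALSE]), v, ignore_attr = TRUE)
  expect_equal(readoutGraph(rbind(v, -v)), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(readoutGraph(rbind(v, -v), "sum"), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(readoutGraph(rbind(v, -v), "max"), abs(v),
               ignore_attr = TRUE)
  expect_error(readoutGraph(matrix(0, 0, 3)), "empty")
})

test_that("the classification head is a calibrated logistic stack", {
  p <- initGatParameters(d = 4, hidden = 3, heads = 2, fcHidden = 2,
                         seed = 4)
  # zero weights and biases -> logistic(0) = 0.5
  p0 <- p
  p0@fcW1[] <- 0; p0@fcB1[] <- 0; p0@fcW2[] <- 0; p0@fcB2 <- 0
  expect_equal(classifyGraph(rnorm(6), p0), 0.5)
  # a huge positive logit saturates
  p1 <- p0
  p1@fcB2 <- 50
  expect_gte(classifyGraph(rnorm(6), p1), 0.999)
  # range contract
  with_seed_test(2, {
    for (i in 1:10) {
      pr <- classifyGraph(rnorm(6, sd = 10), p)
      expect_true(pr > 0 && pr < 1)
    }
  })
  expect_error(classifyGraph(rnorm(5), p), "width")
})

test_that("the batched training forward equals the per-graph path", {
  with_seed_test(77, {
    seqs <- Biostrings::DNAStringSet(stats::setNames(
      vapply(1:6, function(i) random_dna(sample(80:200, 1)), ""),
      paste0("s", 1:6)))
    corp <- lapply(seq_along(seqs), function(i)
      tokenizeKmers(seqs[[i]], 3))
    et <- trainEmbeddings(corp, d = 12, epochs = 2, seed = 5)
    p <- initGatParameters(d = 12, hidden = 8, heads = 3, seed = 6)
    prep <- cncgat:::prepare_graph_items(seqs, 3, et)
    Vpad <- rbind(unname(embeddingMatrix(et)), 0)
    b <- cncgat:::assemble_batch(prep$items, NULL, nrow(Vpad))
    fw <- cncgat:::forward_batch(p, Vpad, b, training = FALSE)
    for (i in seq_along(seqs)) {
      single <- predictGraph(prep$items[[i]]$graph, et, p)
      expect_equal(fw$phat[i], single$probability, tolerance = 1e-10)
    }
  })
})

test_that("non-finite inputs are rejected", {
  g <- normalizeEdgeWeights(buildKmerGraph("ATGCATG", 3, "bad"))
  p <- initGatParameters(d = 4, hidden = 3, heads = 1, seed = 1)
  X <- make_features(g, 4, 3)
  X[1, 1] <- NaN
  expect_error(gatForward(X, g, p), "finite")
})
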