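# Fold assignment, metrics, early stopping, ensemble prediction.

test_that("makeFolds stratifies, partitions, and is seed-deterministic", {
  with_seed_test(1, {
    seqs <- Biostrings::DNAStringSet(stats::setNames(
      vapply(1:100, function(i) random_dna(60), ""),
      sprintf("s%03d", 1:100)))
  })
  labs <- stats::setNames(rep(c(1L, 0L), each = 50), names(seqs))
  ds <- LabeledTranscripts(seqs, labs)
  f <- makeFolds(ds, 5, seed = 7)
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_equal(unname(table(f$fold)), rep(20L, 5), ignore_attr = TRUE)
  per_fold_pos <- tapply(f$label, f$fold, sum)
  expect_true(all(per_fold_pos == 10L))
  expect_setequal(f$id, names(labs))
  expect_identical(f, makeFolds(ds, 5, seed = 7))
  expect_false(identical(f$fold, makeFolds(ds, 5, seed = 8)$fold))
  small <- LabeledTranscripts(seqs[c(1:3, 51:53)], labs[c(1:3, 51:53)])
  expect_error(makeFolds(small, 5), "at least 5")
})

test_that("metric formulas reproduce hand-checkable identities", {
  m <- metricsFromCounts(TP = 25, TN = 25, FP = 25, FN = 25)
  expect_equal(m$ACC, 0.5)
  expect_equal(m$MCC, 0)

  # perfect separation of a balanced set
  labs <- rep(c(1, 0), each = 20)
  probs <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  m2 <- computeMetrics(labs, probs)
  expect_equal(m2$ACC, 1); expect_equal(m2$SN, 1); expect_equal(m2$SP, 1)
  expect_equal(m2$MCC, 1); expect_equal(m2$AUC, 1)

  # balanced classes: ACC == (SN + SP) / 2 exactly
  with_seed_test(5, {
    probs <- runif(40)
    m3 <- computeMetrics(labs, probs)
    expect_equal(m3$ACC, (m3$SN + m3$SP) / 2)
    # inverting predicted labels flips the MCC sign
    m4 <- computeMetrics(1 - labs, probs)
    expect_equal(m4$MCC, -m3$MCC)
    # AUC(p) = 1 - AUC(1-p)
    expect_equal(computeMetrics(labs, 1 - probs)$AUC, 1 - m3$AUC)
  })

  expect_warning(ms <- computeMetrics(rep(1, 5), runif(5)), "single-class")
  expect_true(is.na(ms$MCC) && is.na(ms$AUC))
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  with_seed_test(9, {
    for (i in 1:5) {
      labs <- rbinom(60, 1, 0.5)
      if (length(unique(labs)) < 2) next
      probs <- round(runif(60), 2)  # force ties
      ref <- as.numeric(pROC::auc(pROC::roc(labs, probs, quiet = TRUE,
                                            direction = "<")))
      expect_equal(aucMidrank(labs, probs), ref, tolerance = 1e-12)
    }
  })
})

test_that("ensemble prediction averages members and applies the threshold", {
  ds <- toy_separable_dataset(12, seed = 31)
  cfg <- trainConfig(max_epochs = 3, folds = 3, batch_size = 8, seed = 3)
  ens <- trainEnsemble(ds, cfg)
  pred <- predictEnsemble(ens, transcripts(ds))
  expect_equal(nrow(pred), 24L)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))

  # the ensemble probability is the arithmetic mean of member probabilities
  one <- transcripts(ds)[1]
  g <- normalizeEdgeWeights(buildKmerGraph(tokenizeKmers(one[[1]], 3), 3,
                                           names(one)))
  member_p <- vapply(ensembleMembers(ens), function(p)
    predictGraph(g, ens@embeddings, p)$probability, 0)
  expect_equal(pred$probability[pred$id == names(one)], mean(member_p),
               tolerance = 1e-10)

  # threshold semantics: ties classify positive, 0 threshold labels all 1
  p0 <- predictEnsemble(ens, transcripts(ds), threshold = 1e-9)
  expect_true(all(p0$label == 1L))
  pt <- predictEnsemble(ens, transcripts(ds),
                        threshold = pred$probability[1])
  expect_equal(pt$label[1], 1L)

  # raising the threshold can only lower the positive count
  p9 <- predictEnsemble(ens, transcripts(ds), threshold = 0.9)
  expect_lte(sum(p9$label), sum(predictEnsemble(ens, transcripts(ds),
                                                threshold = 0.5)$label))

  # unconvertible sequences surface as NA with a reason
  bad <- Biostrings::DNAStringSet(c(short = "ACG", ok = random_dna(100)))
  pb <- predictEnsemble(ens, bad)
  expect_true(is.na(pb$probability[pb$id == "short"]))
  expect_match(pb$note[pb$id == "short"], "short|edges")
  expect_false(is.na(pb$probability[pb$id == "ok"]))

  expect_error(predictEnsemble(ens, Biostrings::DNAStringSet()), "empty")
})

test_that("early stopping returns the best-validation-epoch parameters", {
  ds <- toy_separable_dataset(10, seed = 17)
  ids <- names(transcripts(ds))
  tr_ids <- ids[c(1:7, 11:17)]
  va_ids <- setdiff(ids, tr_ids)
  corp <- lapply(tr_ids, function(i)
    tokenizeKmers(transcripts(ds)[[i]], 3))
  emb <- trainEmbeddings(corp, d = 16, epochs = 2, seed = 2)
  tr <- LabeledTranscripts(transcripts(ds)[tr_ids], classLabels(ds)[tr_ids])
  va <- LabeledTranscripts(transcripts(ds)[va_ids], classLabels(ds)[va_ids])

  cfg <- trainConfig(max_epochs = 40, patience = 3, batch_size = 8,
                     d = 16L, hidden = 8L, fc_hidden = 8L)
  fit <- trainFold(tr, va, cfg, emb, seed = 4)
  expect_equal(fit$bestEpoch, which.min(fit$history$val_loss))
  expect_lte(nrow(fit$history), 40L)
  if (nrow(fit$history) < 40L)  # stopped early: patience exhausted at the end
    expect_equal(nrow(fit$history) - fit$bestEpoch, 3L)

  cfg1 <- trainConfig(max_epochs = 1, batch_size = 8, d = 16L,
                      hidden = 8L, fc_hidden = 8L)
  fit1 <- trainFold(tr, va, cfg1, emb, seed = 4)
  expect_equal(nrow(fit1$history), 1L)

  expect_error(trainFold(tr, LabeledTranscripts(
    transcripts(ds)[tr_ids[1]], classLabels(ds)[tr_ids[1]]), cfg, emb),
    "overlap")
})

test_that("a linearly separable toy set is learned quickly", {
  hits <- 0L
  for (s in 1:3) {
    ds <- toy_separable_dataset(20, seed = 100 + s)
    cfg <- trainConfig(max_epochs = 50, folds = 2, batch_size = 16,
                       seed = s)
    ens <- trainEnsemble(ds, cfg)
    pred <- predictEnsemble(ens, transcripts(ds))
    acc <- mean((pred$probability >= 0.5) == (classLabels(ds) == 1L))
    if (acc >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("bundle save/load round-trips predictions exactly", {
  ds <- toy_separable_dataset(8, seed = 61)
  cfg <- trainConfig(max_epochs = 2, folds = 2, batch_size = 8, seed = 5)
  ens <- trainEnsemble(ds, cfg)
  dir <- tempfile("bundle")
  saveModelBundle(ens, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "embeddings.tsv")))
  expect_true(file.exists(file.path(dir, "fold2", "manifest.json")))
  back <- loadModelBundle(dir)
  p1 <- predictEnsemble(ens, transcripts(ds))
  p2 <- predictEnsemble(back, transcripts(ds))
  expect_equal(p1$probability, p2$probability, tolerance = 1e-9)
})
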