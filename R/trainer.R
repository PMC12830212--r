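# Cross-validated ensemble training, prediction, and evaluation metrics.

#' Training configuration
#'
#' Returns the default training configuration as a named list; any field
#' can be overridden. Defaults: k-mer size 3, 64-dimensional CBOW
#' embeddings, 64 hidden neurons per head, 3 attention heads, Adam with
#' learning rate 1e-4, batch size 64, up to 200 epochs with early stopping
#' (patience 10 on validation loss), 5 folds, classification threshold 0.5,
#' and a 1:1 negative:positive training ratio.
#'
#' @param ... overrides, e.g. `trainConfig(k = 4, max_epochs = 50)`.
#' @return named list of configuration values.
#' @export
trainConfig <- function(...) {
  cfg <- list(
    k = 3L, d = 64L, hidden = 64L, heads = 3L, fc_hidden = 64L,
    lr = 1e-4, batch_size = 64L, max_epochs = 200L, patience = 10L,
    folds = 5L, seed = 1L, threshold = 0.5, neg_pos_ratio = 1.0,
    window = 5L, embed_epochs = 10L, dropout = 0.1, slope = 0.2,
    edge_bias = "multiplicative", edge_norm = "sqrt", readout = "mean"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  stopifnot(cfg$folds >= 2L, cfg$threshold > 0, cfg$threshold < 1,
            cfg$lr > 0)
  cfg
}

#' Stratified fold assignment
#'
#' Partitions a labeled dataset into `folds` validation folds with class
#' proportions per fold within one sample of the global ratio.
#'
#' @param dataset a [LabeledTranscripts] object.
#' @param folds number of folds.
#' @param seed RNG seed; the same seed reproduces the same assignment.
#' @return data.frame with columns `id`, `label`, `fold`.
#' @export
makeFolds <- function(dataset, folds = 5L, seed = 1L) {
  labs <- classLabels(dataset)
  if (min(table(labs)) < folds)
    stop(sprintf("need at least %d samples of each class", folds))
  with_seed(seed, {
    assign_class <- function(ids) {
      ids <- sample(ids)
      split_fold <- rep_len(seq_len(folds), length(ids))
      setNames(split_fold, ids)
    }
    f <- c(assign_class(names(labs)[labs == 1L]),
           assign_class(names(labs)[labs == 0L]))
    ids <- names(labs)
    data.frame(id = ids, label = as.integer(labs),
               fold = as.integer(f[ids]), row.names = NULL)
  })
}

#' Train one cross-validation fold member
#'
#' Minimizes binary cross-entropy on the logistic output with Adam, and
#' applies early stopping: when the validation loss fails to improve for
#' `patience` consecutive epochs, training stops and the parameters from
#' the best validation epoch are returned.
#'
#' @param train,val disjoint [LabeledTranscripts] splits.
#' @param config list from [trainConfig()].
#' @param embeddings an [EmbeddingTable] trained on training-split
#'   sequences only.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list with `params` ([GatParameters] from the best epoch),
#'   `history` (per-epoch losses) and `bestEpoch`.
#' @export
trainFold <- function(train, val, config, embeddings, seed = 1L) {
  if (length(intersect(names(transcripts(train)), names(transcripts(val)))))
    stop("train and validation splits overlap")
  if (!identical(config$readout, "mean"))
    stop("batched training supports the mean readout only")
  tr <- prepare_graph_items(transcripts(train), config$k, embeddings)
  va <- prepare_graph_items(transcripts(val), config$k, embeddings)
  train_items <- tr$items
  y <- as.numeric(classLabels(train))
  Vpad <- rbind(embeddings@vectors, 0)
  nv <- nrow(Vpad)
  val_batch <- assemble_batch(va$items, as.numeric(classLabels(val)), nv)

  with_seed(seed, {
    params <- initGatParameters(
      d = ncol(embeddings@vectors), hidden = config$hidden,
      heads = config$heads, fcHidden = config$fc_hidden,
      slope = config$slope, edgeBias = config$edge_bias,
      dropout = config$dropout, seed = sample.int(2^30, 1L))
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    n <- length(train_items)
    # minibatch composition is fixed once per fold (grouping structures are
    # precomputed); the visiting order is reshuffled every epoch
    ord0 <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    batches <- lapply(seq_len(nb), function(bi) {
      take <- ord0[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, n)]
      assemble_batch(train_items[take], y[take], nv)
    })
    for (epoch in seq_len(config$max_epochs)) {
      tl <- 0
      for (bi in sample.int(nb)) {
        b <- batches[[bi]]
        fw <- forward_batch(params, Vpad, b, training = TRUE)
        loss <- bce_loss(fw$z2, b$y)
        if (!is.finite(loss)) stop("training diverged (non-finite loss)")
        tl <- tl + loss * b$G
        grads <- backward_batch(params, Vpad, b, fw)
        up <- adam_step(params, grads, state, config$lr)
        params <- up$params
        state <- up$state
      }
      vfw <- forward_batch(params, Vpad, val_batch, training = FALSE)
      vloss <- bce_loss(vfw$z2, val_batch$y)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                     val_loss = vloss))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    cnc_log("DEBUG", "fold stopped at epoch %d (best %d, val loss %.4f)",
            nrow(hist), best$epoch, best$loss)
    list(params = best$params, history = hist, bestEpoch = best$epoch)
  })
}

#' Train the full cross-validated ensemble
#'
#' Optionally balances classes by downsampling negatives, trains the CBOW
#' embedding table on the (balanced) training corpus, assigns stratified
#' folds, and trains one GAT member per fold. Test sequences must never be
#' part of `dataset`: the embedding corpus and every fold split are drawn
#' from it only.
#'
#' @param dataset a [LabeledTranscripts] training set.
#' @param config list from [trainConfig()].
#' @return a [FoldEnsemble].
#' @export
trainEnsemble <- function(dataset, config = trainConfig()) {
  labs <- classLabels(dataset)
  seqs <- transcripts(dataset)
  pos <- names(labs)[labs == 1L]
  neg <- names(labs)[labs == 0L]
  n_neg <- min(length(neg), ceiling(config$neg_pos_ratio * length(pos)))
  if (n_neg < length(neg)) {
    neg <- with_seed(derive_seed(config$seed, 1L), sample(neg, n_neg))
    keep <- c(pos, neg)
    seqs <- seqs[keep]
    labs <- labs[keep]
    dataset <- LabeledTranscripts(seqs, labs, truthTable(dataset))
    cnc_log("INFO", "downsampled negatives to %d (ratio %.2f)", n_neg,
            config$neg_pos_ratio)
  }
  cnc_log("INFO", "training embeddings on %d sequences", length(seqs))
  corpus <- lapply(seq_along(seqs),
                   function(i) tokenizeKmers(seqs[[i]], config$k))
  emb <- trainEmbeddings(corpus, d = config$d, window = config$window,
                         epochs = config$embed_epochs,
                         seed = derive_seed(config$seed, 2L))
  folds <- makeFolds(dataset, config$folds, derive_seed(config$seed, 3L))
  members <- vector("list", config$folds)
  history <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr_ids <- folds$id[folds$fold != f]
    va_ids <- folds$id[folds$fold == f]
    tr <- LabeledTranscripts(seqs[tr_ids], labs[tr_ids])
    va <- LabeledTranscripts(seqs[va_ids], labs[va_ids])
    cnc_log("INFO", "training fold %d/%d (%d train / %d val)", f,
            config$folds, length(tr_ids), length(va_ids))
    fit <- trainFold(tr, va, config, emb,
                     seed = derive_seed(config$seed, 10L + f))
    members[[f]] <- fit$params
    history[[f]] <- fit$history
  }
  new("FoldEnsemble", members = members, embeddings = emb, folds = folds,
      config = config, history = history)
}

#' Predict bifunctional potential with a trained ensemble
#'
#' The reported probability is the arithmetic mean of the fold members'
#' probabilities; the label is 1 when the probability is at least
#' `threshold`. Sequences that cannot be converted to a graph (too short,
#' or fully ambiguous) are reported as NA with a reason rather than
#' dropped.
#'
#' @param ensemble a [FoldEnsemble].
#' @param seqs a named [Biostrings::DNAStringSet] (or [LabeledTranscripts]).
#' @param threshold classification cutoff in (0, 1).
#' @return data.frame with columns `id`, `probability`, `label`, `note`.
#' @export
predictEnsemble <- function(ensemble, seqs,
                            threshold = trainConfigOf(ensemble)$threshold) {
  if (is(seqs, "LabeledTranscripts")) seqs <- transcripts(seqs)
  if (length(seqs) == 0L) stop("empty input")
  cfg <- ensemble@config
  prep <- prepare_graph_items(seqs, cfg$k, ensemble@embeddings,
                              onError = "drop")
  ok <- !vapply(prep$items, is.null, TRUE)
  probs <- rep(NA_real_, length(seqs))
  if (any(ok)) {
    Vpad <- rbind(ensemble@embeddings@vectors, 0)
    b <- assemble_batch(prep$items[ok], NULL, nrow(Vpad))
    member_probs <- vapply(ensemble@members, function(p)
      forward_batch(p, Vpad, b, training = FALSE)$phat,
      numeric(sum(ok)))
    probs[ok] <- rowMeans(matrix(member_probs, nrow = sum(ok)))
  }
  note <- rep("", length(seqs))
  note[!ok] <- unname(prep$reasons[names(seqs)[!ok]])
  data.frame(
    id = names(seqs),
    probability = probs,
    label = ifelse(is.na(probs), NA_integer_,
                   as.integer(probs >= threshold)),
    note = note,
    row.names = NULL
  )
}

#' Rank-based AUC (midrank Mann-Whitney)
#'
#' @param labels 0/1 vector.
#' @param probabilities numeric scores.
#' @return the area under the ROC curve.
#' @export
aucMidrank <- function(labels, probabilities) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and classification metrics
#'
#' Thresholds the probabilities, counts TP/TN/FP/FN, and computes
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN)}, \deqn{SN = TP/(TP+FN)},
#' \deqn{SP = TN/(TN+FP)},
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' plus the rank-based AUC. With a single observed class, AUC and MCC are
#' NA with a warning.
#'
#' @param labels 0/1 truth vector.
#' @param probabilities predicted probabilities (same length).
#' @param threshold cutoff; predictions `>= threshold` are positive.
#' @return named list: TP, TN, FP, FN, ACC, SN, SP, MCC, AUC.
#' @export
computeMetrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), all(is.finite(probabilities)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- (tp + tn) / length(labels)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  single_class <- length(unique(labels)) < 2L
  if (single_class) {
    warning("single-class input: MCC and AUC are undefined")
    mcc <- NA_real_
    auc <- NA_real_
  } else {
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
    auc <- aucMidrank(labels, probabilities)
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn, ACC = acc, SN = sn, SP = sp,
       MCC = mcc, AUC = auc)
}

#' Metrics directly from confusion counts
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @return named list with ACC, SN, SP, MCC.
#' @export
metricsFromCounts <- function(TP, TN, FP, FN) {
  acc <- (TP + TN) / (TP + FP + TN + FN)
  sn <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom > 0) (TP * TN - FP * FN) / denom else 0
  list(TP = TP, TN = TN, FP = FP, FN = FN, ACC = acc, SN = sn, SP = sp,
       MCC = mcc)
}
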