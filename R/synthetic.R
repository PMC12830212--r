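# Synthetic transcript generator with planted translation signals.
#
# Positives carry one planted open reading frame: a Kozak-like context
# whose terminal ATG is the start codon, a run of stop-free sense codons,
# and a single stop. Negatives share the same i.i.d. background but have
# their in-frame stop-codon density boosted and any long spurious ORF
# disrupted. This plants exactly the signal structure the classifier and
# the interpretability suite are expected to detect (start/Kozak motifs in
# positives, stop-codon enrichment in negatives).

STOP_CODONS <- c("TAA", "TGA", "TAG")

#' Synthetic dataset configuration
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range transcript length range in nt.
#' @param gc_content background GC fraction.
#' @param kozak_motif planted start context; must end in ATG.
#' @param orf_min_codons minimum number of stop-free sense codons in a
#'   planted ORF; negatives are scrubbed of ORFs longer than half this.
#' @param neg_stop_boost multiplier on the in-frame stop-codon density of
#'   negatives relative to the background expectation.
#' @param seed RNG seed.
#' @return named list of validated settings.
#' @export
syntheticConfig <- function(n_pos = 100L, n_neg = 100L,
                            length_range = c(200L, 1500L),
                            gc_content = 0.45, kozak_motif = "GCCATG",
                            orf_min_codons = 30L, neg_stop_boost = 2.0,
                            seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L],
            gc_content > 0, gc_content < 1,
            grepl("^[ACGT]*ATG$", kozak_motif),
            orf_min_codons >= 1L, neg_stop_boost >= 1)
  min_needed <- nchar(kozak_motif) + 3L * (orf_min_codons + 1L)
  if (length_range[1L] < min_needed)
    stop(sprintf(
      "minimum length %d too short for a planted ORF (needs >= %d nt)",
      length_range[1L], min_needed))
  list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
       length_range = as.integer(length_range), gc_content = gc_content,
       kozak_motif = kozak_motif, orf_min_codons = as.integer(orf_min_codons),
       neg_stop_boost = neg_stop_boost, seed = as.integer(seed))
}

## i.i.d. background base probabilities for a GC fraction.
background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_background <- function(L, probs) {
  paste(sample(names(probs), L, replace = TRUE, prob = probs),
        collapse = "")
}

## All 61 sense codons with probabilities induced by the background model.
sense_codon_probs <- function(probs) {
  codons <- as.vector(outer(outer(names(probs), names(probs), paste0),
                            names(probs), paste0))
  p <- as.vector(outer(outer(probs, probs), probs))
  keep <- !codons %in% STOP_CODONS
  stats::setNames(p[keep] / sum(p[keep]), codons[keep])
}

## Expected per-codon stop probability under the background model.
stop_codon_prob <- function(probs) {
  sum(vapply(STOP_CODONS, function(cd)
    prod(probs[strsplit(cd, "")[[1L]]]), 0))
}

## Locations (start, end, frame, codons) of all forward-strand ORFs of at
## least `min_codons` sense codons. Used to scrub negatives.
find_long_orfs <- function(seq, min_codons) {
  L <- nchar(seq)
  hits <- list()
  codons_at <- function(starts)
    substring(seq, starts, starts + 2L)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(hits)
  for (s in starts) {
    pos <- s + 3L
    ncod <- 0L
    while (pos + 2L <= L) {
      cd <- substr(seq, pos, pos + 2L)
      if (cd %in% STOP_CODONS) break
      ncod <- ncod + 1L
      pos <- pos + 3L
    }
    if (ncod >= min_codons)
      hits[[length(hits) + 1L]] <-
        list(start = s, sense_codons = ncod)
  }
  hits
}

#' Generate a labeled synthetic transcript dataset
#'
#' Positives are i.i.d. background sequences with one planted ORF (Kozak
#' context, at least `orf_min_codons` stop-free sense codons, one stop);
#' negatives are background with in-frame stop density multiplied by
#' `neg_stop_boost` (applied in all three frames via codon replacement in
#' frame 0 plus ORF disruption) and no ORF longer than
#' `orf_min_codons / 2`. Fully reproducible under the config seed.
#'
#' @param config list from [syntheticConfig()].
#' @return a [LabeledTranscripts]; its truth table records each positive's
#'   planted ORF coordinates (1-based, inclusive, ATG start through stop).
#' @export
generateDataset <- function(config = syntheticConfig()) {
  probs <- background_probs(config$gc_content)
  sense <- sense_codon_probs(probs)
  p_stop <- stop_codon_prob(probs)
  motif <- config$kozak_motif
  with_seed(config$seed, {
    seqs <- character(config$n_pos + config$n_neg)
    ids <- c(sprintf("pos_%04d", seq_len(config$n_pos)),
             sprintf("neg_%04d", seq_len(config$n_neg)))
    labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
    orf_start <- rep(NA_integer_, length(ids))
    orf_end <- rep(NA_integer_, length(ids))

    for (i in seq_len(config$n_pos)) {
      L <- sample(config$length_range[1L]:config$length_range[2L], 1L)
      bg <- random_background(L, probs)
      # cassette: kozak prefix + ATG + >= orf_min_codons sense codons + stop
      max_extra <- max(0L, (L - nchar(motif) - 3L) %/% 3L -
                         config$orf_min_codons)
      ncod <- config$orf_min_codons +
        sample.int(min(max_extra, config$orf_min_codons) + 1L, 1L) - 1L
      cassette <- paste0(
        motif,
        paste(sample(names(sense), ncod, replace = TRUE, prob = sense),
              collapse = ""),
        sample(STOP_CODONS, 1L))
      at <- sample.int(L - nchar(cassette) + 1L, 1L)
      seq <- paste0(substr(bg, 1L, at - 1L), cassette,
                    substr(bg, at + nchar(cassette), L))
      seqs[i] <- seq
      orf_start[i] <- at + nchar(motif) - 3L        # the ATG
      orf_end[i] <- at + nchar(cassette) - 1L        # last base of the stop
    }

    max_orf <- max(1L, config$orf_min_codons %/% 2L)
    extra <- (config$neg_stop_boost - 1) * p_stop / (1 - p_stop)
    for (i in seq_len(config$n_neg)) {
      L <- sample(config$length_range[1L]:config$length_range[2L], 1L)
      seq <- random_background(L, probs)
      # boost in-frame (frame 0) stop density by codon replacement
      ncod <- L %/% 3L
      flip <- which(runif(ncod) < extra)
      if (length(flip)) {
        repl <- sample(STOP_CODONS, length(flip), replace = TRUE)
        chars <- strsplit(seq, "")[[1L]]
        for (jj in seq_along(flip)) {
          at <- (flip[jj] - 1L) * 3L + 1L
          chars[at:(at + 2L)] <- strsplit(repl[jj], "")[[1L]]
        }
        seq <- paste(chars, collapse = "")
      }
      # disrupt any remaining ORF longer than max_orf sense codons by
      # ablating its start codon (ATG -> stop). Replacing the ATG itself
      # cannot mint a new ATG at the junctions, so every pass strictly
      # lowers the ATG count and the scrub terminates.
      repeat {
        long <- find_long_orfs(seq, max_orf + 1L)
        if (!length(long)) break
        o <- long[[1L]]
        stop_cd <- sample(c("TAA", "TAG"), 1L)
        seq <- paste0(substr(seq, 1L, o$start - 1L), stop_cd,
                      substr(seq, o$start + 3L, nchar(seq)))
      }
      seqs[config$n_pos + i] <- seq
    }

    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- ids
    truth <- data.frame(id = ids, label = labels, orf_start = orf_start,
                        orf_end = orf_end, row.names = NULL)
    LabeledTranscripts(sset, setNames(labels, ids), truth)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `positives.fasta`, `negatives.fasta` and `truth.tsv`
#' (`id`, `label`, `orf_start`, `orf_end`) into a directory.
#'
#' @param dataset a [LabeledTranscripts].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- classLabels(dataset)
  seqs <- transcripts(dataset)
  writeFasta(seqs[labs == 1L], file.path(dir, "positives.fasta"))
  writeFasta(seqs[labs == 0L], file.path(dir, "negatives.fasta"))
  write.table(truthTable(dataset), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
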