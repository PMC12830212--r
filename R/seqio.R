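# Sequence input/output and k-mer tokenization.

#' Normalize a raw nucleotide string
#'
#' Uppercases, maps RNA U to T, and validates the alphabet. Ambiguous `N`
#' bases are retained here and handled at tokenization, where any window
#' containing `N` becomes a skip marker rather than an invented k-mer.
#'
#' @param raw a single non-empty character string.
#' @return the normalized string over `{A,C,G,T,N}`.
#' @examples
#' normalizeSequence("augc")  # "ATGC"
#' @export
normalizeSequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("empty sequence")
  up <- chartr("u", "U", toupper(raw))
  up <- chartr("U", "T", up)
  bad <- regexpr("[^ACGTN]", up)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(raw, bad, bad), bad))
  }
  up
}

#' Read transcript sequences from a FASTA file
#'
#' Sequences are read permissively (any letters), then normalized with
#' [normalizeSequence()]: case-folded, U mapped to T, alphabet restricted to
#' `{A,C,G,T,N}`. Ids are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by sequence id, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning(sprintf("no sequences in %s", path))
    return(Biostrings::DNAStringSet())
  }
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  seqs <- vapply(as.character(raw), normalizeSequence, "", USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Returns the `L - k + 1` windows of width `k` in 5' to 3' order. Windows
#' containing `N` are replaced by the sentinel `"skip"` so that positional
#' adjacency is never fabricated across ambiguous bases: graph construction
#' refuses to draw an edge into or out of a skip marker.
#'
#' @param seq a character string, [Biostrings::DNAString], or a length-one
#'   [Biostrings::DNAStringSet].
#' @param k k-mer size, >= 2.
#' @return character vector of k-mers (with `"skip"` sentinels).
#' @examples
#' tokenizeKmers("ATGCA", 3)  # "ATG" "TGC" "GCA"
#' @export
tokenizeKmers <- function(seq, k = 3L) {
  stopifnot(k >= 2L)
  s <- as.character(seq)
  if (length(s) != 1L) stop("tokenizeKmers expects a single sequence")
  L <- nchar(s)
  if (L < k) stop(sprintf("sequence length %d shorter than k=%d", L, k))
  starts <- seq_len(L - k + 1L)
  toks <- substring(s, starts, starts + k - 1L)
  toks[grepl("N", toks, fixed = TRUE)] <- "skip"
  toks
}

#' Read a two-column id/label TSV
#'
#' Accepts an optional header row; labels must be 0/1.
#'
#' @param path path to a TSV with columns `id` and `label`.
#' @return named integer vector of labels.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("id", first, ignore.case = TRUE) &&
    !grepl("\t[01]\\s*$", first)
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label TSV needs two columns: id, label")
  ids <- as.character(tab[[1L]])
  labs <- suppressWarnings(as.integer(tab[[2L]]))
  if (anyNA(labs) || !all(labs %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  if (anyDuplicated(ids)) stop("duplicate ids in label file")
  setNames(labs, ids)
}

#' Construct a labeled transcript set
#'
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param labels named 0/1 vector covering exactly the sequence ids.
#' @param truth optional annotation data.frame.
#' @return a [LabeledTranscripts] object.
#' @export
LabeledTranscripts <- function(sequences, labels,
                               truth = data.frame()) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop(sprintf("no label for id(s): %s",
                 paste(head(missing, 5L), collapse = ", ")))
  extra <- setdiff(names(labels), ids)
  if (length(extra))
    stop(sprintf("label(s) without sequence: %s",
                 paste(head(extra, 5L), collapse = ", ")))
  new("LabeledTranscripts", sequences = sequences,
      labels = as.integer(labels[ids]) |> setNames(ids), truth = truth)
}
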