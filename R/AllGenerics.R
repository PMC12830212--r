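# Accessor generics for the package's S4 containers.

#' @rdname KmerGraph-class
#' @param object,x an object.
#' @export
setGeneric("kmerNodes", function(object) standardGeneric("kmerNodes"))

#' @rdname KmerGraph-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname KmerGraph-class
#' @export
setGeneric("rawWeights", function(object) standardGeneric("rawWeights"))

#' @rdname KmerGraph-class
#' @export
setGeneric("normWeights", function(object) standardGeneric("normWeights"))

#' @rdname KmerGraph-class
#' @export
setGeneric("kmerSize", function(object) standardGeneric("kmerSize"))

#' @rdname KmerGraph-class
#' @export
setGeneric("sequenceId", function(object) standardGeneric("sequenceId"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("vocabulary", function(object) standardGeneric("vocabulary"))

#' @rdname EmbeddingTable-class
#' @export
setGeneric("embeddingMatrix",
           function(object) standardGeneric("embeddingMatrix"))

#' @rdname LabeledTranscripts-class
#' @export
setGeneric("transcripts", function(object) standardGeneric("transcripts"))

#' @rdname LabeledTranscripts-class
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname LabeledTranscripts-class
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname FoldEnsemble-class
#' @export
setGeneric("ensembleMembers",
           function(object) standardGeneric("ensembleMembers"))

#' @rdname FoldEnsemble-class
#' @export
setGeneric("foldAssignments",
           function(object) standardGeneric("foldAssignments"))

#' @rdname FoldEnsemble-class
#' @export
setGeneric("trainConfigOf", function(object) standardGeneric("trainConfigOf"))

#' @rdname AttentionRecord-class
#' @export
setGeneric("attentionCoefficients",
           function(object) standardGeneric("attentionCoefficients"))

## ---- methods ------------------------------------------------------------

#' @rdname KmerGraph-class
setMethod("kmerNodes", "KmerGraph", function(object) object@nodes)

#' @rdname KmerGraph-class
setMethod("edgeTable", "KmerGraph", function(object) {
  data.frame(
    from = object@nodes[object@edges[, 1L]],
    to = object@nodes[object@edges[, 2L]],
    raw_weight = object@rawWeights,
    norm_weight = if (length(object@normWeights)) object@normWeights
                  else NA_real_
  )
})

#' @rdname KmerGraph-class
setMethod("rawWeights", "KmerGraph", function(object) object@rawWeights)

#' @rdname KmerGraph-class
setMethod("normWeights", "KmerGraph", function(object) object@normWeights)

#' @rdname KmerGraph-class
setMethod("kmerSize", "KmerGraph", function(object) object@k)

#' @rdname KmerGraph-class
setMethod("sequenceId", "KmerGraph", function(object) object@sequenceId)

#' @rdname EmbeddingTable-class
setMethod("vocabulary", "EmbeddingTable", function(object) object@vocab)

#' @rdname EmbeddingTable-class
setMethod("embeddingMatrix", "EmbeddingTable", function(object) {
  m <- object@vectors
  rownames(m) <- object@vocab
  m
})

#' @rdname EmbeddingTable-class
setMethod("kmerSize", "EmbeddingTable", function(object) object@k)

#' @rdname LabeledTranscripts-class
setMethod("transcripts", "LabeledTranscripts",
          function(object) object@sequences)

#' @rdname LabeledTranscripts-class
setMethod("classLabels", "LabeledTranscripts", function(object) object@labels)

#' @rdname LabeledTranscripts-class
setMethod("truthTable", "LabeledTranscripts", function(object) object@truth)

#' @rdname LabeledTranscripts-class
setMethod("length", "LabeledTranscripts",
          function(x) length(x@sequences))

#' @rdname FoldEnsemble-class
setMethod("ensembleMembers", "FoldEnsemble", function(object) object@members)

#' @rdname FoldEnsemble-class
setMethod("foldAssignments", "FoldEnsemble", function(object) object@folds)

#' @rdname FoldEnsemble-class
setMethod("trainConfigOf", "FoldEnsemble", function(object) object@config)

#' @rdname AttentionRecord-class
setMethod("attentionCoefficients", "AttentionRecord", function(object) {
  data.frame(
    src = object@nodes[object@src],
    dst = object@nodes[object@dst],
    object@alpha
  )
})
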