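#' @rdname TranscriptModel-class
#' @param object,x a \code{TranscriptModel}.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsStartTx", function(x) standardGeneric("cdsStartTx"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsEndTx", function(x) standardGeneric("cdsEndTx"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("splicedSeq", function(x) standardGeneric("splicedSeq"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("utr3Seq", function(x) standardGeneric("utr3Seq"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
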