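#' Construct a TranscriptModel
#'
#' Low-level constructor; most users will call [loadFixture()], [loadGtf()]
#' or [makeTranscript()] instead. All invariants are checked: positive exon
#' lengths, sequence length equal to the exon-length sum, a CDS span that is
#' divisible by 3 (the span includes the stop codon) and begins with ATG
#' unless `permissiveStart` is set.
#'
#' @param transcriptId transcript identifier.
#' @param exonLengths integer vector of exon lengths, 5' to 3'.
#' @param cdsStartTx,cdsEndTx CDS span in spliced-mRNA coordinates (1-based,
#'   inclusive, stop codon included).
#' @param splicedSeq sense-strand mRNA sequence (character or `DNAString`).
#' @param txStrand `"+"` or `"-"` (informational; the sequence is always
#'   sense-strand).
#' @param exonRanges optional `GRanges` of exons in genomic coordinates.
#' @param permissiveStart waive the ATG start-codon check.
#' @return a validated [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(transcriptId, exonLengths, cdsStartTx, cdsEndTx,
                            splicedSeq, txStrand = "+", exonRanges = NULL,
                            permissiveStart = FALSE) {
  if (is.character(splicedSeq)) splicedSeq <- Biostrings::DNAString(splicedSeq)
  new("TranscriptModel",
      transcriptId = as.character(transcriptId),
      txStrand = txStrand,
      exonLengths = as.integer(exonLengths),
      exonRanges = exonRanges,
      cdsStartTx = as.integer(cdsStartTx),
      cdsEndTx = as.integer(cdsEndTx),
      splicedSeq = splicedSeq,
      permissiveStart = isTRUE(permissiveStart))
}

#' @rdname TranscriptModel-class
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)

#' @rdname TranscriptModel-class
#' @export
setMethod("exonLengths", "TranscriptModel", function(x) x@exonLengths)

#' @rdname TranscriptModel-class
#' @export
setMethod("nExons", "TranscriptModel", function(x) length(x@exonLengths))

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsStartTx", "TranscriptModel", function(x) x@cdsStartTx)

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsEndTx", "TranscriptModel", function(x) x@cdsEndTx)

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsLength", "TranscriptModel", function(x) x@cdsEndTx - x@cdsStartTx + 1L)

#' @rdname TranscriptModel-class
#' @export
setMethod("splicedSeq", "TranscriptModel", function(x) x@splicedSeq)

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsSeq", "TranscriptModel", function(x)
  as.character(Biostrings::subseq(x@splicedSeq, x@cdsStartTx, x@cdsEndTx)))

#' @rdname TranscriptModel-class
#' @export
setMethod("utr3Seq", "TranscriptModel", function(x) {
  txLen <- length(x@splicedSeq)
  if (x@cdsEndTx >= txLen) return("")
  as.character(Biostrings::subseq(x@splicedSeq, x@cdsEndTx + 1L, txLen))
})

#' @rdname TranscriptModel-class
#' @export
setMethod("txStrand", "TranscriptModel", function(x) x@txStrand)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel '%s' (%s strand)\n", object@transcriptId,
              object@txStrand))
  cat(sprintf("  %d exons, spliced length %d nt\n",
              length(object@exonLengths), sum(object@exonLengths)))
  cat(sprintf("  CDS %d..%d (%d nt incl. stop; %d codons, %d aa)\n",
              object@cdsStartTx, object@cdsEndTx, cdsLength(object),
              cdsLength(object) %/% 3L, cdsLength(object) %/% 3L - 1L))
  if (!is.null(object@exonRanges))
    cat(sprintf("  genomic: %s:%d-%d\n",
                as.character(GenomicRanges::seqnames(object@exonRanges)[1]),
                min(GenomicRanges::start(object@exonRanges)),
                max(GenomicRanges::end(object@exonRanges))))
})

#' Load a transcript from the self-contained JSON fixture dialect
#'
#' The fixture dialect carries everything downstream computation needs —
#' exon lengths, CDS span and the spliced sequence — so no genome or
#' annotation download is ever required:
#' \preformatted{{"transcript_id": str, "exon_lengths": [int, ...],
#'  "cds_start_tx": int, "cds_end_tx": int, "spliced_seq": str}}
#'
#' @param path path to a fixture JSON file.
#' @return a validated [TranscriptModel-class].
#' @seealso [writeFixtureJson()], [makeTranscript()]
#' @examples
#' p <- system.file("extdata", "btk_like_tx.json", package = "stopfate")
#' loadFixture(p)
#' @export
loadFixture <- function(path) {
  if (!file.exists(path))
    sfStop("stopfate_not_found", "fixture file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) sfStop("stopfate_parse_error",
                    "malformed fixture JSON in %s: %s", path, conditionMessage(e)))
  required <- c("transcript_id", "exon_lengths", "cds_start_tx",
                "cds_end_tx", "spliced_seq")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    sfStop("stopfate_parse_error", "fixture %s missing field '%s'",
           path, missing[1])
  for (fld in c("cds_start_tx", "cds_end_tx"))
    if (!is.numeric(obj[[fld]]) || length(obj[[fld]]) != 1L)
      sfStop("stopfate_parse_error", "fixture field '%s' must be a single integer", fld)
  if (!is.numeric(obj$exon_lengths) || length(obj$exon_lengths) < 1L)
    sfStop("stopfate_parse_error", "fixture field 'exon_lengths' must be a non-empty integer array")
  if (!is.character(obj$spliced_seq) || length(obj$spliced_seq) != 1L)
    sfStop("stopfate_parse_error", "fixture field 'spliced_seq' must be a single string")
  tryCatch(
    TranscriptModel(transcriptId = obj$transcript_id,
                    exonLengths = obj$exon_lengths,
                    cdsStartTx = obj$cds_start_tx,
                    cdsEndTx = obj$cds_end_tx,
                    splicedSeq = obj$spliced_seq,
                    permissiveStart = isTRUE(obj$permissive_start)),
    error = function(e) sfStop("stopfate_validation_error",
      "fixture %s failed validation: %s", path, conditionMessage(e)))
}

#' Write a transcript in the fixture JSON dialect
#'
#' @param model a [TranscriptModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFixtureJson <- function(model, path) {
  stopifnot(is(model, "TranscriptModel"))
  obj <- list(
    transcript_id = model@transcriptId,
    exon_lengths = model@exonLengths,
    cds_start_tx = model@cdsStartTx,
    cds_end_tx = model@cdsEndTx,
    spliced_seq = as.character(model@splicedSeq)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map a CDS nucleotide position to its codon index
#'
#' Position 1..3 is codon 1 (the initiator), 4..6 codon 2, and so on:
#' `ceiling(cdsPos / 3)`. CDS nucleotide 72 (third base of codon 24) maps to
#' codon 24; nucleotide 595 maps to codon 199.
#'
#' @param cdsPos 1-based CDS nucleotide position(s).
#' @return integer codon index (vectorized).
#' @export
cdsPosToCodon <- function(cdsPos) {
  if (any(is.na(cdsPos)) || any(cdsPos < 1))
    sfStop("stopfate_domain_error", "cdsPos must be >= 1")
  as.integer(ceiling(cdsPos / 3))
}

#' Locate a CDS position on the exon scaffold
#'
#' Converts a CDS position to spliced-mRNA coordinates
#' (`mrnaPos = cdsStartTx + cdsPos - 1`) and reports which exon holds it,
#' the offset within that exon, the exon length, and the distance to the 3'
#' end of the penultimate exon — the measurement the 50 nt escape rule is
#' evaluated on. The distance counts the last nucleotide of the penultimate
#' exon as 1 and is negative for positions in the last exon.
#'
#' @param model a [TranscriptModel-class].
#' @param cdsPos 1-based CDS position, `1 <= cdsPos <= cdsLength(model)`.
#' @return an `ExonLocation`: a list with elements `exonRank`,
#'   `offsetInExon`, `distToLastJunction` (`NA` for single-exon
#'   transcripts), `exonLength`, `lastExon`, `singleExon`.
#' @examples
#' tx <- makeTranscript(c(100L, 100L, 100L), 1L, 270L, seed = 1)
#' locateCdsPos(tx, 150L)  # exon 2, 51 nt from the last junction
#' @export
locateCdsPos <- function(model, cdsPos) {
  stopifnot(is(model, "TranscriptModel"))
  cdsPos <- as.integer(cdsPos)
  if (length(cdsPos) != 1L || is.na(cdsPos) || cdsPos < 1L ||
      cdsPos > cdsLength(model))
    sfStop("stopfate_domain_error",
           "cdsPos %s outside CDS 1..%d of %s", as.character(cdsPos),
           cdsLength(model), model@transcriptId)
  mrnaPos <- model@cdsStartTx + cdsPos - 1L
  cum <- cumsum(model@exonLengths)
  rank <- which(mrnaPos <= cum)[1L]
  n <- length(cum)
  before <- if (rank == 1L) 0L else cum[rank - 1L]
  loc <- list(
    exonRank = rank,
    offsetInExon = mrnaPos - before,
    distToLastJunction = if (n >= 2L) cum[n - 1L] - mrnaPos + 1L else NA_integer_,
    exonLength = model@exonLengths[rank],
    lastExon = rank == n,
    singleExon = n == 1L
  )
  class(loc) <- "ExonLocation"
  loc
}

#' @export
print.ExonLocation <- function(x, ...) {
  cat(sprintf("ExonLocation: exon %d (length %d nt), offset %d, dist to last junction %s\n",
              x$exonRank, x$exonLength, x$offsetInExon,
              as.character(x$distToLastJunction)))
  invisible(x)
}

# Inverse of locateCdsPos for the round-trip property: (rank, offset) -> cdsPos.
exonOffsetToCdsPos <- function(model, exonRank, offsetInExon) {
  cum <- c(0L, cumsum(model@exonLengths))
  mrnaPos <- cum[exonRank] + offsetInExon
  mrnaPos - model@cdsStartTx + 1L
}
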