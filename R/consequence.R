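# Normalize any supported edit to (delStart, delEnd, ins) in CDS
# coordinates: mutated = ref[1..delStart-1] + ins + ref[delEnd+1..].
# delEnd == delStart - 1 encodes an empty deleted span (pure insertion).
normalizeEdit <- function(model, v) {
  cdsLen <- cdsLength(model)
  cds <- cdsSeq(model)
  if (v@start < 1L || v@end > cdsLen)
    sfStop("stopfate_unsupported_region",
           "variant span %d..%d outside CDS 1..%d of %s",
           v@start, v@end, cdsLen, model@transcriptId)
  checkRef <- function(span1, span2, given, what) {
    found <- substring(cds, span1, span2)
    if (nzchar(given) && !identical(given, found))
      sfStop("stopfate_refcheck_error",
             "%s reference mismatch at c.%d_%d: expected %s, transcript has %s",
             what, span1, span2, given, found)
    found
  }
  switch(v@kind,
    substitution = {
      checkRef(v@start, v@end, v@refSeq, "substitution")
      list(delStart = v@start, delEnd = v@end, ins = v@altSeq)
    },
    deletion = {
      checkRef(v@start, v@end, v@refSeq, "deletion")
      list(delStart = v@start, delEnd = v@end, ins = "")
    },
    delins = {
      checkRef(v@start, v@end, v@refSeq, "delins")
      list(delStart = v@start, delEnd = v@end, ins = v@altSeq)
    },
    duplication = {
      dup <- checkRef(v@start, v@end, v@refSeq, "duplication")
      list(delStart = v@end + 1L, delEnd = v@end, ins = dup)
    },
    insertion = {
      list(delStart = v@start + 1L, delEnd = v@start, ins = v@altSeq)
    },
    sfStop("stopfate_validation_error", "unknown variant kind '%s'", v@kind)
  )
}

#' Apply a coding variant to the reference CDS
#'
#' Pure string edit: the variant's span must lie within the CDS and any
#' reference bases it carries must match the transcript (mismatch raises a
#' `stopfate_refcheck_error` reporting expected vs found). The mutated
#' sequence length equals the reference CDS length plus the net length
#' change of the edit.
#'
#' @param model a [TranscriptModel-class].
#' @param v a [CodingVariant-class].
#' @return the mutated CDS as a character string.
#' @export
applyVariant <- function(model, v) {
  stopifnot(is(model, "TranscriptModel"), is(v, "CodingVariant"))
  ed <- normalizeEdit(model, v)
  cds <- cdsSeq(model)
  paste0(substring(cds, 1L, ed$delStart - 1L), ed$ins,
         substring(cds, ed$delEnd + 1L, nchar(cds)))
}

# Map a mutated-sequence position back to reference-CDS coordinates.
# Positions 5' of the edit are shared; positions inside the inserted block
# are clamped to the edit start; positions 3' of it are shifted by -net.
mapMutToRef <- function(p, delStart, insLen, net) {
  if (p < delStart) return(list(pos = p, inserted = FALSE))
  if (p < delStart + insLen) return(list(pos = delStart, inserted = TRUE))
  list(pos = p - net, inserted = FALSE)
}

#' Translate reference and mutated CDS and scan for a premature stop
#'
#' Codon-by-codon comparison from codon 1. An edit whose net length change
#' is not divisible by 3 shifts the reading frame and the scan walks the
#' shifted frame — continuing past the reference stop into the 3' UTR,
#' which a shifted frame ignores — until the first in-frame stop codon or
#' the 3' end of the transcript. A stop strictly upstream of the reference
#' stop yields `nonsense` (frame preserved) or `frameshift_with_ptc`
#' (frame shifted); a shifted frame reaching the 3' end without a stop
#' yields `frameshift_no_ptc`.
#'
#' PTC position convention: `ptcCdsPos` is the first nucleotide of the new
#' stop codon in reference-CDS coordinates; for frameshifts the
#' mutated-mRNA position is mapped back through the edit (positions 5' of
#' the edit are shared, positions inside the inserted block clamp to the
#' edit start, positions 3' of it shift by the net length change).
#'
#' Any codon containing N aborts the scan with a `stopfate_scan_aborted`
#' condition: the translation outcome would be a guess.
#'
#' @param refCds reference CDS sequence (including the stop codon).
#' @param mutCds mutated CDS from [applyVariant()].
#' @param v the [CodingVariant-class] that produced `mutCds` (needed to map
#'   frameshift PTC positions back to reference coordinates).
#' @param utr3 3' UTR sequence appended for the shifted-frame scan
#'   (default none).
#' @return an [MrnaConsequence-class].
#' @seealso [variantConsequence()] for the model-level convenience wrapper.
#' @export
translateAndScan <- function(refCds, mutCds, v, utr3 = "") {
  stopifnot(nzchar(refCds), nzchar(mutCds), is(v, "CodingVariant"))
  if (nchar(refCds) %% 3L != 0L)
    sfStop("stopfate_validation_error", "reference CDS length not divisible by 3")

  net <- nchar(mutCds) - nchar(refCds)
  frameOffset <- ((net %% 3L) + 3L) %% 3L
  insLen <- switch(v@kind,
    substitution = 1L,
    deletion = 0L,
    insertion = nchar(v@altSeq),
    duplication = v@end - v@start + 1L,
    delins = nchar(v@altSeq))
  delStart <- switch(v@kind,
    substitution = v@start,
    deletion = v@start,
    delins = v@start,
    duplication = v@end + 1L,
    insertion = v@start + 1L)

  refCodons <- codonSplit(refCds)
  refAa <- translateCodons(refCodons)
  if (anyNA(refAa))
    sfStop("stopfate_scan_aborted",
           "reference codon %d contains an ambiguous base (N); PTC scan aborted",
           which(is.na(refAa))[1])
  nRefCodons <- length(refCodons)
  if (any(refAa[-nRefCodons] == "*"))
    sfStop("stopfate_validation_error",
           "reference CDS contains an internal stop at codon %d",
           which(refAa[-nRefCodons] == "*")[1])
  if (refAa[nRefCodons] != "*")
    sfStop("stopfate_validation_error", "reference CDS does not end in a stop codon")

  mutExt <- paste0(mutCds, utr3)
  mutCodons <- codonSplit(mutExt)
  mutAa <- translateCodons(mutCodons)
  refStopInMut <- nRefCodons + net %/% 3L  # only meaningful when frame preserved

  # limit the N check to codons the scan can actually reach
  firstStopMut <- which(mutAa == "*")[1]
  scanEnd <- if (!is.na(firstStopMut)) firstStopMut else length(mutAa)
  if (anyNA(mutAa[seq_len(min(scanEnd, length(mutAa)))]))
    sfStop("stopfate_scan_aborted",
           "mutated codon %d contains an ambiguous base (N); PTC scan aborted",
           which(is.na(mutAa))[1])

  cons <- function(class, ..., caveats = character(0)) {
    new("MrnaConsequence", consequenceClass = class,
        netLengthChange = as.integer(net), frameOffset = frameOffset,
        refProtein = paste(refAa[-nRefCodons], collapse = ""),
        caveats = caveats, ...)
  }

  if (identical(refCds, mutCds)) return(cons("no_change"))

  # first codon whose translation differs from the reference frame
  cmpLen <- min(length(refAa), length(mutAa))
  diffIdx <- which(refAa[seq_len(cmpLen)] != mutAa[seq_len(cmpLen)])
  firstAffected <- if (length(diffIdx)) diffIdx[1] else NA_integer_

  mutProt <- if (!is.na(firstStopMut))
    paste(mutAa[seq_len(firstStopMut - 1L)], collapse = "") else
    paste(mutAa, collapse = "")

  if (frameOffset == 0L) {
    if (!is.na(firstStopMut) && firstStopMut < refStopInMut) {
      # premature in-frame stop: stop-gained
      ptcMutPos <- 3L * firstStopMut - 2L
      mp <- mapMutToRef(ptcMutPos, delStart, insLen, net)
      fa <- if (is.na(firstAffected)) firstStopMut else min(firstAffected, firstStopMut)
      return(cons("nonsense",
        ptcCdsPos = as.integer(mp$pos), ptcCodon = cdsPosToCodon(mp$pos),
        firstAffectedCodon = as.integer(fa),
        terOffset = as.integer(firstStopMut - fa + 1L),
        refResidue = refAa[fa], newResidue = mutAa[fa],
        mutProtein = mutProt,
        caveats = if (mp$inserted)
          "PTC first nucleotide lies within inserted sequence; reference-coordinate position clamped to the edit site"
        else character(0)))
    }
    if (is.na(firstStopMut) || firstStopMut > refStopInMut) {
      return(cons("stop_lost",
        firstAffectedCodon = firstAffected,
        refResidue = if (!is.na(firstAffected)) refAa[firstAffected] else NA_character_,
        newResidue = if (!is.na(firstAffected)) mutAa[firstAffected] else NA_character_,
        mutProtein = mutProt,
        caveats = "reference stop codon lost; passed through without NMD evaluation"))
    }
    # stop where expected
    refProt <- paste(refAa[-nRefCodons], collapse = "")
    if (identical(mutProt, refProt))
      return(cons("synonymous", mutProtein = mutProt))
    if (identical(v@kind, "substitution"))
      return(cons("missense",
        firstAffectedCodon = firstAffected,
        refResidue = refAa[firstAffected], newResidue = mutAa[firstAffected],
        mutProtein = mutProt))
    return(cons("inframe_indel",
      firstAffectedCodon = firstAffected,
      refResidue = if (!is.na(firstAffected)) refAa[firstAffected] else NA_character_,
      newResidue = if (!is.na(firstAffected)) mutAa[firstAffected] else NA_character_,
      mutProtein = mutProt))
  }

  # shifted reading frame
  fa <- if (is.na(firstAffected)) cdsPosToCodon(delStart) else firstAffected
  if (!is.na(firstStopMut)) {
    ptcMutPos <- 3L * firstStopMut - 2L
    mp <- mapMutToRef(ptcMutPos, delStart, insLen, net)
    if (mp$pos <= nchar(refCds) - 3L) {
      return(cons("frameshift_with_ptc",
        ptcCdsPos = as.integer(mp$pos), ptcCodon = cdsPosToCodon(mp$pos),
        firstAffectedCodon = as.integer(fa),
        terOffset = as.integer(firstStopMut - fa + 1L),
        refResidue = refAa[min(fa, nRefCodons)], newResidue = mutAa[fa],
        mutProtein = mutProt,
        caveats = if (mp$inserted)
          "PTC first nucleotide lies within inserted sequence; reference-coordinate position clamped to the edit site"
        else character(0)))
    }
    return(cons("frameshift_no_ptc",
      firstAffectedCodon = as.integer(fa),
      terOffset = as.integer(firstStopMut - fa + 1L),
      refResidue = refAa[min(fa, nRefCodons)], newResidue = mutAa[fa],
      mutProtein = mutProt,
      caveats = "shifted frame terminates at or downstream of the reference stop; not a premature termination"))
  }
  cons("frameshift_no_ptc",
    firstAffectedCodon = as.integer(fa),
    refResidue = refAa[min(fa, nRefCodons)], newResidue = mutAa[fa],
    mutProtein = mutProt,
    caveats = "shifted frame reaches the transcript 3' end without a stop codon")
}

#' Compute the mRNA consequence of a variant on a transcript
#'
#' Convenience wrapper: [applyVariant()] then [translateAndScan()] with the
#' transcript's 3' UTR available to the shifted-frame scan.
#'
#' @param model a [TranscriptModel-class].
#' @param v a [CodingVariant-class].
#' @return an [MrnaConsequence-class].
#' @examples
#' tx <- loadFixture(system.file("extdata", "dmd_like_tx.json",
#'                               package = "stopfate"))
#' variantConsequence(tx, parseHgvsC("c.72G>A"))
#' @export
variantConsequence <- function(model, v) {
  mut <- applyVariant(model, v)
  translateAndScan(cdsSeq(model), mut, v, utr3 = utr3Seq(model))
}

setMethod("show", "MrnaConsequence", function(object) {
  cat(sprintf("MrnaConsequence: %s (net %+d nt, frame offset %d)\n",
              object@consequenceClass, object@netLengthChange,
              object@frameOffset))
  if (!is.na(object@ptcCdsPos))
    cat(sprintf("  PTC at CDS nt %d (codon %d)\n", object@ptcCdsPos,
                object@ptcCodon))
  if (!is.na(object@firstAffectedCodon))
    cat(sprintf("  first affected codon %d (%s -> %s)%s\n",
                object@firstAffectedCodon, object@refResidue,
                object@newResidue,
                if (!is.na(object@terOffset))
                  sprintf(", ter offset %d", object@terOffset) else ""))
  for (cv in object@caveats) cat("  caveat:", cv, "\n")
})

#' Tag the predicted loss-of-function variant type
#'
#' A plof tag is assigned from the variant type alone — premature stop
#' (stop_gained), frame-shifting edit (frameshift), or a change to one of
#' the two essential splice-site nucleotides flanking an exon
#' (essential_splice) — never from the NMD outcome, and it is a label of
#' variant type, not a demonstrated functional effect. A fixed caveat
#' stating exactly that accompanies every tag.
#'
#' @param x an [MrnaConsequence-class], or the string
#'   `"essential_splice"` for intronic ±1/±2 changes arriving through the
#'   VCF path.
#' @return a list with elements `tag` and `caveat`.
#' @export
plofTag <- function(x) {
  caveat <- paste("plof is a prediction of variant type, not of functional",
                  "effect; loss of function requires experimental evidence")
  if (identical(x, "essential_splice"))
    return(list(tag = "essential_splice", caveat = caveat))
  stopifnot(is(x, "MrnaConsequence"))
  tag <- if (identical(x@consequenceClass, "nonsense")) "stop_gained"
    else if (x@frameOffset != 0L) "frameshift"
    else "none"
  list(tag = tag, caveat = caveat)
}
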