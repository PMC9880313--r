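#' @import methods
#' @importFrom Biostrings DNAString
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' TranscriptModel: a protein-coding transcript in spliced coordinates
#'
#' Holds the exon scaffold (ordered 5'\eqn{\to}3'), the CDS span in spliced
#' mRNA coordinates (1-based, inclusive, including the stop codon), and the
#' sense-strand spliced sequence. All downstream computation — consequence
#' calling, PTC location, NMD classification — happens in these transcript
#' coordinates; genomic coordinates, when present (GTF/GFF3 ingestion), are
#' converted on entry and retained only for VCF input mapping.
#'
#' @slot transcriptId single transcript identifier.
#' @slot txStrand \code{"+"} or \code{"-"}; fixture-mode transcripts are
#'   always \code{"+"}.
#' @slot exonLengths integer vector of exon lengths in nt, in transcript
#'   5'\eqn{\to}3' order (rank = position in this vector).
#' @slot exonRanges \code{GRanges} of the exons in genomic coordinates, in
#'   transcript rank order, or \code{NULL} in fixture-only mode.
#' @slot cdsStartTx,cdsEndTx 1-based inclusive CDS span in spliced-mRNA
#'   coordinates; the span includes the stop codon, so its length is
#'   divisible by 3 and codes protein length \code{cdsLength/3 - 1}.
#' @slot splicedSeq \code{DNAString}, length \code{sum(exonLengths)}.
#' @slot permissiveStart if \code{TRUE}, the requirement that the CDS begin
#'   with ATG is waived (non-AUG initiation).
#'
#' @examples
#' tx <- makeTranscript(c(100L, 100L, 100L), cdsStartTx = 1L,
#'                      cdsLengthNt = 270L, seed = 1)
#' tx
#' cdsLength(tx)
#' @export
setClass("TranscriptModel",
  slots = c(
    transcriptId = "character",
    txStrand = "character",
    exonLengths = "integer",
    exonRanges = "GRangesOrNULL",
    cdsStartTx = "integer",
    cdsEndTx = "integer",
    splicedSeq = "DNAString",
    permissiveStart = "logical"
  ),
  prototype = list(txStrand = "+", exonRanges = NULL, permissiveStart = FALSE)
)

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  id <- if (length(object@transcriptId)) object@transcriptId else "<unnamed>"
  if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
    msgs <- c(msgs, "transcriptId must be a single non-empty string")
  if (!object@txStrand %in% c("+", "-"))
    msgs <- c(msgs, sprintf("[%s] txStrand must be '+' or '-'", id))
  if (length(object@exonLengths) < 1L || any(object@exonLengths < 1L))
    msgs <- c(msgs, sprintf("[%s] exon lengths must be positive", id))
  txLen <- sum(object@exonLengths)
  if (length(object@splicedSeq) != txLen)
    msgs <- c(msgs, sprintf(
      "[%s] splicedSeq length (%d) != sum of exon lengths (%d)",
      id, length(object@splicedSeq), txLen))
  cs <- object@cdsStartTx; ce <- object@cdsEndTx
  if (length(cs) != 1L || length(ce) != 1L || is.na(cs) || is.na(ce)) {
    msgs <- c(msgs, sprintf("[%s] cdsStartTx/cdsEndTx must be single integers", id))
  } else {
    if (!(cs >= 1L && cs < ce && ce <= txLen))
      msgs <- c(msgs, sprintf(
        "[%s] CDS span %d..%d invalid for transcript length %d", id, cs, ce, txLen))
    cdsLen <- ce - cs + 1L
    if (cdsLen %% 3L != 0L)
      msgs <- c(msgs, sprintf("[%s] CDS length %d not divisible by 3", id, cdsLen))
    if (!isTRUE(object@permissiveStart) && cs >= 1L && ce <= length(object@splicedSeq) &&
        cs + 2L <= length(object@splicedSeq)) {
      startCodon <- as.character(Biostrings::subseq(object@splicedSeq, cs, cs + 2L))
      if (!identical(startCodon, "ATG"))
        msgs <- c(msgs, sprintf("[%s] CDS does not begin with ATG (found %s)", id, startCodon))
    }
  }
  if (!is.null(object@exonRanges)) {
    if (length(object@exonRanges) != length(object@exonLengths))
      msgs <- c(msgs, sprintf("[%s] exonRanges length != number of exons", id))
    else if (!all(GenomicRanges::width(object@exonRanges) == object@exonLengths))
      msgs <- c(msgs, sprintf("[%s] exonRanges widths disagree with exonLengths", id))
  }
  if (length(msgs)) msgs else TRUE
})

#' CodingVariant: a parsed HGVS c.-level edit
#'
#' @slot kind one of \code{substitution}, \code{deletion}, \code{insertion},
#'   \code{duplication}, \code{delins}.
#' @slot start,end 1-based CDS nucleotide span (start == end for single-nt
#'   edits; insertions use the flanking pair with end == start + 1).
#' @slot refSeq affected reference bases as given in the input (may be empty:
#'   ref-less del/dup forms; validated against the transcript at apply time,
#'   not parse time).
#' @slot altSeq inserted bases (empty for deletion).
#' @slot raw the original input string.
#' @slot refPrefix optional reference prefix split off the input
#'   (\code{"NM_...:"}, \code{"LRG_...t1:"}), \code{NA} when absent.
#' @export
setClass("CodingVariant",
  slots = c(
    kind = "character",
    start = "integer",
    end = "integer",
    refSeq = "character",
    altSeq = "character",
    raw = "character",
    refPrefix = "character"
  ),
  prototype = list(refSeq = "", altSeq = "", raw = "", refPrefix = NA_character_)
)

setValidity("CodingVariant", function(object) {
  msgs <- character(0)
  kinds <- c("substitution", "deletion", "insertion", "duplication", "delins")
  if (!object@kind %in% kinds)
    msgs <- c(msgs, sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  if (is.na(object@start) || is.na(object@end) || object@start < 1L)
    msgs <- c(msgs, "start/end must be positive integers")
  else if (object@start > object@end)
    msgs <- c(msgs, "start must be <= end")
  badAlpha <- function(s) nzchar(s) && grepl("[^ACGT]", s)
  if (badAlpha(object@refSeq) || badAlpha(object@altSeq))
    msgs <- c(msgs, "ref/alt alphabet restricted to A,C,G,T")
  if (identical(object@kind, "substitution") &&
      (nchar(object@refSeq) != 1L || nchar(object@altSeq) != 1L))
    msgs <- c(msgs, "substitution requires single-base ref and alt")
  if (identical(object@kind, "insertion") && object@end != object@start + 1L)
    msgs <- c(msgs, "insertion must use flanking positions start, start+1")
  if (length(msgs)) msgs else TRUE
})

#' NmdRuleConfig: thresholds of the NMD escape/attenuation rules
#'
#' @slot penultimateWindowNt size of the escape window at the 3' end of the
#'   penultimate exon (default 50 nt; the "50 nt rule").
#' @slot startProximalNt distance from the start codon within which a PTC may
#'   evade degradation (default 150 nt).
#' @slot longExonNt exon length above which NMD efficiency is reduced
#'   (default 400 bp).
#' @export
setClass("NmdRuleConfig",
  slots = c(
    penultimateWindowNt = "integer",
    startProximalNt = "integer",
    longExonNt = "integer"
  ),
  prototype = list(
    penultimateWindowNt = 50L,
    startProximalNt = 150L,
    longExonNt = 400L
  )
)

setValidity("NmdRuleConfig", function(object) {
  v <- c(object@penultimateWindowNt, object@startProximalNt, object@longExonNt)
  if (length(v) != 3L || anyNA(v) || any(v < 0L))
    return("all thresholds must be non-negative integers")
  TRUE
})

#' MrnaConsequence: mRNA-level outcome of applying a variant to a CDS
#'
#' @slot consequenceClass one of \code{nonsense}, \code{frameshift_with_ptc},
#'   \code{frameshift_no_ptc}, \code{inframe_indel}, \code{missense},
#'   \code{synonymous}, \code{stop_lost}, \code{no_change}.
#' @slot netLengthChange signed nt change of the coding sequence.
#' @slot frameOffset \code{netLengthChange mod 3}; 0 iff the edit preserves
#'   the reading frame.
#' @slot ptcCdsPos 1-based reference-CDS position of the first nucleotide of
#'   the new stop codon (frameshift PTCs are mapped back through the edit),
#'   or \code{NA}.
#' @slot ptcCodon codon index of the PTC, or \code{NA}.
#' @slot firstAffectedCodon codon index of the first residue differing from
#'   the reference protein, or \code{NA}.
#' @slot terOffset for PTC-creating edits, position of the stop in the new
#'   frame counting the first changed residue as 1 (the \code{fs*N} number).
#' @slot refResidue,newResidue 1-letter residues at the first affected codon
#'   (reference and mutated), or \code{NA}.
#' @slot refProtein,mutProtein translated proteins (1-letter, stop excluded)
#'   used for protein-level HGVS emission.
#' @slot caveats free-text caveats accumulated during the scan.
#' @export
setClass("MrnaConsequence",
  slots = c(
    consequenceClass = "character",
    netLengthChange = "integer",
    frameOffset = "integer",
    ptcCdsPos = "integer",
    ptcCodon = "integer",
    firstAffectedCodon = "integer",
    terOffset = "integer",
    refResidue = "character",
    newResidue = "character",
    refProtein = "character",
    mutProtein = "character",
    caveats = "character"
  ),
  prototype = list(
    ptcCdsPos = NA_integer_, ptcCodon = NA_integer_,
    firstAffectedCodon = NA_integer_, terOffset = NA_integer_,
    refResidue = NA_character_, newResidue = NA_character_,
    refProtein = "", mutProtein = "", caveats = character(0)
  )
)

setValidity("MrnaConsequence", function(object) {
  msgs <- character(0)
  classes <- c("nonsense", "frameshift_with_ptc", "frameshift_no_ptc",
               "inframe_indel", "missense", "synonymous", "stop_lost",
               "no_change")
  if (!object@consequenceClass %in% classes)
    msgs <- c(msgs, "unknown consequenceClass")
  if (!is.na(object@frameOffset) &&
      object@frameOffset != ((object@netLengthChange %% 3L) + 3L) %% 3L)
    msgs <- c(msgs, "frameOffset must equal netLengthChange mod 3")
  if (object@consequenceClass %in% c("nonsense", "frameshift_with_ptc") &&
      (is.na(object@ptcCdsPos) || is.na(object@ptcCodon)))
    msgs <- c(msgs, "PTC classes require ptcCdsPos and ptcCodon")
  if (length(msgs)) msgs else TRUE
})

#' NmdVerdict: predicted fate of a PTC-bearing transcript
#'
#' @slot fate \code{TRIGGER} (efficient NMD, transcript degraded),
#'   \code{INTERMEDIATE} (attenuated NMD, residual expression possible) or
#'   \code{ESCAPE} (transcript survives; truncated protein predicted).
#' @slot rulesFired ordered subset of \code{last_exon},
#'   \code{penultimate_50nt}, \code{single_exon}, \code{start_proximal},
#'   \code{long_exon}; \code{"none"} for TRIGGER.
#' @slot measurements named list: \code{ptcExonRank}, \code{ptcExonLength},
#'   \code{distToLastJunction}, \code{cdsPosOfPtc}.
#' @slot confidenceNote free-text qualification of the verdict.
#' @export
setClass("NmdVerdict",
  slots = c(
    fate = "character",
    rulesFired = "character",
    measurements = "list",
    confidenceNote = "character"
  ),
  prototype = list(confidenceNote = "")
)

setValidity("NmdVerdict", function(object) {
  msgs <- character(0)
  if (!object@fate %in% c("TRIGGER", "INTERMEDIATE", "ESCAPE"))
    msgs <- c(msgs, "fate must be TRIGGER, INTERMEDIATE or ESCAPE")
  escapeRules <- c("last_exon", "penultimate_50nt", "single_exon")
  if (identical(object@fate, "ESCAPE") &&
      !any(object@rulesFired %in% escapeRules))
    msgs <- c(msgs, "ESCAPE requires an escape rule among rulesFired")
  if (identical(object@fate, "TRIGGER") &&
      !identical(object@rulesFired, "none"))
    msgs <- c(msgs, "TRIGGER requires rulesFired == 'none'")
  if (identical(object@fate, "INTERMEDIATE") &&
      !any(object@rulesFired %in% c("start_proximal", "long_exon")))
    msgs <- c(msgs, "INTERMEDIATE requires start_proximal or long_exon")
  if (length(msgs)) msgs else TRUE
})

#' ProteinAnnotation: structured content of an HGVS p. string
#'
#' @slot form one of \code{no_protein_predicted}, \code{substitution_ter},
#'   \code{frameshift_ter}, \code{full_deletion}, \code{unchanged},
#'   \code{other} (payload-carrying forms such as missense / in-frame
#'   indels).
#' @slot firstAffectedCodon residue number of the first affected codon.
#' @slot refResidue,newResidue 1-letter residues.
#' @slot terOffset stop position in the new frame (first changed residue
#'   = 1); \code{NA} means unknown (\code{fs*?}).
#' @slot predicted when \code{TRUE} the emitted payload is wrapped in
#'   parentheses (theoretical construction, no experimental evidence).
#' @slot payload preformatted 3-letter payload for \code{form == "other"}.
#' @export
setClass("ProteinAnnotation",
  slots = c(
    form = "character",
    firstAffectedCodon = "integer",
    refResidue = "character",
    newResidue = "character",
    terOffset = "integer",
    predicted = "logical",
    payload = "character"
  ),
  prototype = list(
    firstAffectedCodon = NA_integer_, refResidue = NA_character_,
    newResidue = NA_character_, terOffset = NA_integer_,
    predicted = TRUE, payload = NA_character_
  )
)

setValidity("ProteinAnnotation", function(object) {
  msgs <- character(0)
  forms <- c("no_protein_predicted", "substitution_ter", "frameshift_ter",
             "full_deletion", "unchanged", "other")
  if (!object@form %in% forms) msgs <- c(msgs, "unknown form")
  if (identical(object@form, "no_protein_predicted") &&
      !(is.na(object@firstAffectedCodon) && is.na(object@refResidue) &&
        is.na(object@newResidue) && is.na(object@terOffset)))
    msgs <- c(msgs, "no_protein_predicted must carry no residue fields")
  if (identical(object@form, "substitution_ter") &&
      (is.na(object@firstAffectedCodon) || is.na(object@refResidue)))
    msgs <- c(msgs, "substitution_ter requires codon and reference residue")
  if (identical(object@form, "frameshift_ter") &&
      (is.na(object@firstAffectedCodon) || is.na(object@refResidue) ||
       is.na(object@newResidue)))
    msgs <- c(msgs, "frameshift_ter requires codon and both residues")
  if (length(msgs)) msgs else TRUE
})

#' AnnotationRecord: the corrected annotation for one variant
#'
#' One record per input variant, carrying the consequence class, the NMD
#' fate, the corrected HGVS r./p. strings, VariO accessions, the predicted
#' loss-of-function type tag, the unsense-candidate flag and all caveats.
#'
#' @slot variantRaw input variant string.
#' @slot transcriptId transcript the variant was interpreted on.
#' @slot consequenceClass mRNA consequence class (or \code{"error"}).
#' @slot nmdFate \code{TRIGGER}/\code{INTERMEDIATE}/\code{ESCAPE} or
#'   \code{NA} for non-PTC variants.
#' @slot rulesFired NMD rules fired (empty for non-PTC variants).
#' @slot varioRna,varioProtein VariO accession + label (e.g.
#'   \code{"VariO:0245 missing RNA"}) or \code{NA}.
#' @slot hgvsR,hgvsP corrected RNA- and protein-level HGVS strings.
#' @slot plofTag \code{stop_gained}, \code{frameshift},
#'   \code{essential_splice} or \code{none} — a variant-type label, never a
#'   functional claim.
#' @slot unsenseCandidate \code{TRUE} for apparently-synonymous
#'   substitutions at splice-critical exonic positions (VariO:0514
#'   candidates).
#' @slot caveats free-text caveats.
#' @slot error \code{NA} on success; otherwise the per-variant failure
#'   (e.g. \code{"unsupported-region"}).
#' @export
setClass("AnnotationRecord",
  slots = c(
    variantRaw = "character",
    transcriptId = "character",
    consequenceClass = "character",
    nmdFate = "character",
    rulesFired = "character",
    varioRna = "character",
    varioProtein = "character",
    hgvsR = "character",
    hgvsP = "character",
    plofTag = "character",
    unsenseCandidate = "logical",
    caveats = "character",
    error = "character"
  ),
  prototype = list(
    nmdFate = NA_character_, rulesFired = character(0),
    varioRna = NA_character_, varioProtein = NA_character_,
    hgvsR = "", hgvsP = "", plofTag = "none",
    unsenseCandidate = FALSE, caveats = character(0),
    error = NA_character_
  )
)

setValidity("AnnotationRecord", function(object) {
  both <- grepl("VariO:0240", object@varioProtein %||% "") &&
    grepl("VariO:0015", object@varioProtein %||% "")
  if (isTRUE(both))
    return("a record must not carry both VariO:0240 and VariO:0015")
  TRUE
})
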