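VARIO_MISSING_PROTEIN <- "VariO:0240 missing protein"
VARIO_MISSING_RNA <- "VariO:0245 missing RNA"
VARIO_TRUNCATION <- "VariO:0015 protein truncation"

PREDICTION_CAVEAT <- paste(
  "computational prediction only; RNA and protein fate require",
  "experimental confirmation")

# Protein annotation for a PTC-bearing consequence (truncation form).
truncationAnnotation <- function(cons, predicted = TRUE) {
  if (identical(cons@consequenceClass, "nonsense") &&
      !is.na(cons@terOffset) && cons@terOffset == 1L) {
    new("ProteinAnnotation", form = "substitution_ter",
        firstAffectedCodon = cons@firstAffectedCodon,
        refResidue = cons@refResidue, predicted = predicted)
  } else if (!is.na(cons@terOffset) && cons@terOffset == 1L) {
    # shifted frame whose first changed codon is already the stop
    new("ProteinAnnotation", form = "substitution_ter",
        firstAffectedCodon = cons@firstAffectedCodon,
        refResidue = cons@refResidue, predicted = predicted)
  } else {
    new("ProteinAnnotation", form = "frameshift_ter",
        firstAffectedCodon = cons@firstAffectedCodon,
        refResidue = cons@refResidue, newResidue = cons@newResidue,
        terOffset = cons@terOffset, predicted = predicted)
  }
}

# p. payload for frame-preserving, non-PTC protein changes, from the
# protein diff (common prefix / suffix trimming).
proteinDiffAnnotation <- function(cons, predicted = TRUE) {
  ref <- strsplit(cons@refProtein, "")[[1]]
  mut <- strsplit(cons@mutProtein, "")[[1]]
  nR <- length(ref); nM <- length(mut)
  p <- 0L
  while (p < min(nR, nM) && ref[p + 1L] == mut[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nR, nM) - p && ref[nR - s] == mut[nM - s]) s <- s + 1L
  refSeg <- if (p + 1L <= nR - s) ref[(p + 1L):(nR - s)] else character(0)
  mutSeg <- if (p + 1L <= nM - s) mut[(p + 1L):(nM - s)] else character(0)
  seg3 <- function(x) paste(vapply(x, aa3, character(1)), collapse = "")
  payload <-
    if (!length(refSeg) && !length(mutSeg)) "="
    else if (length(refSeg) == 1L && length(mutSeg) == 1L)
      sprintf("%s%d%s", aa3(refSeg), p + 1L, aa3(mutSeg))
    else if (!length(mutSeg)) {
      if (length(refSeg) == 1L) sprintf("%s%ddel", aa3(refSeg), p + 1L)
      else sprintf("%s%d_%s%ddel", aa3(refSeg[1]), p + 1L,
                   aa3(refSeg[length(refSeg)]), p + length(refSeg))
    } else if (!length(refSeg)) {
      sprintf("%s%d_%s%dins%s", aa3(ref[p]), p, aa3(ref[p + 1L]), p + 1L,
              seg3(mutSeg))
    } else {
      left <- sprintf("%s%d", aa3(refSeg[1]), p + 1L)
      right <- if (length(refSeg) > 1L)
        sprintf("_%s%d", aa3(refSeg[length(refSeg)]), p + length(refSeg)) else ""
      sprintf("%s%sdelins%s", left, right, seg3(mutSeg))
    }
  new("ProteinAnnotation", form = "other", payload = payload,
      predicted = predicted)
}

#' Emit the corrected annotation record for one variant
#'
#' Maps an mRNA consequence plus (for PTC variants) an NMD verdict to the
#' corrected annotations:
#' \itemize{
#'   \item TRIGGER: the transcript is degraded and no protein is made —
#'     `hgvsR = "r.(0)"`, `hgvsP = "p.(0)"`, VariO:0245 missing RNA,
#'     VariO:0240 missing protein. The conventional truncation string is
#'     exactly what this corrects.
#'   \item ESCAPE: the transcript survives and a truncated protein is
#'     predicted — VariO:0015 protein truncation, a Ter/fs-Ter protein
#'     string, and the RNA-level form of the edit.
#'   \item INTERMEDIATE: partial degradation — the truncation-form HGVS is
#'     kept (some protein may exist, the less destructive claim) with the
#'     caveat "partial NMD predicted; residual expression possible";
#'     `varioRna` stays empty because VariO has no term for a partially
#'     degraded transcript.
#'   \item non-PTC consequences pass through with standard HGVS and no
#'     VariO terms (`p.(=)` for synonymous).
#' }
#' A record never carries both VariO:0240 and VariO:0015, and every PTC
#' record carries a fixed caveat that the annotation is a prediction, not
#' experimental evidence.
#'
#' @param consequence an [MrnaConsequence-class].
#' @param verdict an [NmdVerdict-class], required iff the consequence has a
#'   PTC (contradictory input is a validation error).
#' @param model the [TranscriptModel-class].
#' @param v the parsed [CodingVariant-class].
#' @param unsense optional `UnsenseFlag` from [screenUnsense()].
#' @param asserted when `TRUE` the r./p. strings are emitted without the
#'   prediction parentheses (`r.0`, `p.0`) — only appropriate when the
#'   outcome is experimentally established.
#' @return an [AnnotationRecord-class].
#' @export
emitAnnotation <- function(consequence, verdict = NULL, model, v,
                           unsense = NULL, asserted = FALSE) {
  stopifnot(is(consequence, "MrnaConsequence"), is(model, "TranscriptModel"),
            is(v, "CodingVariant"))
  hasPtc <- !is.na(consequence@ptcCdsPos)
  if (hasPtc && is.null(verdict))
    sfStop("stopfate_validation_error",
           "consequence has a PTC but no NMD verdict was supplied")
  if (!hasPtc && !is.null(verdict))
    sfStop("stopfate_validation_error",
           "NMD verdict supplied for a consequence without a PTC")
  predicted <- !isTRUE(asserted)
  caveats <- consequence@caveats
  plof <- plofTag(consequence)
  if (!identical(plof$tag, "none")) caveats <- c(caveats, plof$caveat)

  fate <- NA_character_
  rules <- character(0)
  varioRna <- NA_character_
  varioProtein <- NA_character_

  if (hasPtc) {
    fate <- verdict@fate
    rules <- verdict@rulesFired
    caveats <- c(caveats, PREDICTION_CAVEAT)
    if (nzchar(verdict@confidenceNote))
      caveats <- c(caveats, verdict@confidenceNote)
    if (identical(fate, "TRIGGER")) {
      varioRna <- VARIO_MISSING_RNA
      varioProtein <- VARIO_MISSING_PROTEIN
      hgvsR <- formatHgvsR(zero = TRUE, predicted = predicted)
      hgvsP <- formatHgvsP(new("ProteinAnnotation",
                               form = "no_protein_predicted",
                               predicted = predicted))
    } else if (identical(fate, "ESCAPE")) {
      varioProtein <- VARIO_TRUNCATION
      hgvsR <- formatHgvsR(v, predicted = predicted)
      hgvsP <- formatHgvsP(truncationAnnotation(consequence, predicted))
    } else {
      varioProtein <- VARIO_TRUNCATION
      hgvsR <- formatHgvsR(v, predicted = predicted)
      hgvsP <- formatHgvsP(truncationAnnotation(consequence, predicted))
      caveats <- c(caveats,
                   "partial NMD predicted; residual expression possible",
                   "no VariO term exists for a partially degraded transcript; varioRna left empty")
    }
  } else {
    hgvsR <- formatHgvsR(v, predicted = predicted)
    hgvsP <- switch(consequence@consequenceClass,
      synonymous = ,
      no_change = formatHgvsP(new("ProteinAnnotation", form = "unchanged",
                                  predicted = predicted)),
      missense = ,
      inframe_indel = formatHgvsP(proteinDiffAnnotation(consequence, predicted)),
      stop_lost = "p.?",
      frameshift_no_ptc = formatHgvsP(new("ProteinAnnotation",
        form = "frameshift_ter",
        firstAffectedCodon = consequence@firstAffectedCodon,
        refResidue = consequence@refResidue,
        newResidue = consequence@newResidue,
        terOffset = NA_integer_, predicted = predicted)),
      "p.?")
  }

  unsenseFlag <- FALSE
  if (!is.null(unsense) && inherits(unsense, "UnsenseFlag")) {
    unsenseFlag <- isTRUE(unsense$flagged)
    if (!is.na(unsense$caveat)) caveats <- c(caveats, unsense$caveat)
  }

  new("AnnotationRecord",
      variantRaw = v@raw,
      transcriptId = transcriptId(model),
      consequenceClass = consequence@consequenceClass,
      nmdFate = fate,
      rulesFired = rules,
      varioRna = varioRna,
      varioProtein = varioProtein,
      hgvsR = hgvsR,
      hgvsP = hgvsP,
      plofTag = plof$tag,
      unsenseCandidate = unsenseFlag,
      caveats = unique(caveats))
}

setMethod("show", "AnnotationRecord", function(object) {
  cat(sprintf("AnnotationRecord: %s on %s\n", object@variantRaw,
              object@transcriptId))
  cat(sprintf("  consequence: %s; NMD fate: %s [%s]\n",
              object@consequenceClass, object@nmdFate,
              paste(object@rulesFired, collapse = ", ")))
  cat(sprintf("  %s / %s\n", object@hgvsR, object@hgvsP))
  cat(sprintf("  VariO: rna=%s protein=%s; plof=%s%s\n", object@varioRna,
              object@varioProtein, object@plofTag,
              if (object@unsenseCandidate) "; unsense candidate" else ""))
})

ANNOTATION_COLUMNS <- c("variant", "transcript", "consequence", "nmd_fate",
                        "rules", "vario_rna", "vario_protein", "hgvs_r",
                        "hgvs_p", "plof", "unsense_candidate", "caveats",
                        "error")

#' Convert annotation records to a data.frame
#'
#' One row per record with the fixed, documented column order: variant,
#' transcript, consequence, nmd_fate, rules (comma-joined), vario_rna,
#' vario_protein, hgvs_r, hgvs_p, plof, unsense_candidate, caveats
#' (`"; "`-joined), error.
#'
#' @param records a list of [AnnotationRecord-class] objects.
#' @return a `data.frame`.
#' @export
recordsToDataFrame <- function(records) {
  stopifnot(is.list(records))
  rows <- lapply(records, function(r) {
    stopifnot(is(r, "AnnotationRecord"))
    data.frame(
      variant = r@variantRaw,
      transcript = r@transcriptId,
      consequence = r@consequenceClass,
      nmd_fate = r@nmdFate,
      rules = paste(r@rulesFired, collapse = ","),
      vario_rna = r@varioRna,
      vario_protein = r@varioProtein,
      hgvs_r = r@hgvsR,
      hgvs_p = r@hgvsP,
      plof = r@plofTag,
      unsense_candidate = r@unsenseCandidate,
      caveats = paste(r@caveats, collapse = "; "),
      error = r@error,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write annotation records as TSV
#'
#' @param records list of [AnnotationRecord-class] objects (or a
#'   `data.frame` already in the documented column layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(records, path) {
  df <- if (is.data.frame(records)) records else recordsToDataFrame(records)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    sfStop("stopfate_validation_error", "failed writing TSV to %s: %s",
           path, conditionMessage(ok))
  invisible(path)
}
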