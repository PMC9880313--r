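#' Annotate a set of HGVS c. variants on one transcript
#'
#' Full per-variant pipeline: parse, apply to the CDS, translate and scan
#' for a PTC, classify NMD fate when a PTC is found, screen
#' apparently-synonymous substitutions for unsense candidacy, and emit the
#' corrected [AnnotationRecord-class]. Variants that cannot be processed
#' (unsupported regions, parse failures, reference mismatches) yield
#' records with the `error` field set — reported, never silently dropped.
#'
#' @param model a [TranscriptModel-class].
#' @param variants character vector of HGVS c. strings, or a list of
#'   pre-parsed [CodingVariant-class] objects.
#' @param cfg an [NmdRuleConfig-class].
#' @param unsenseWindowNt exonic window for [screenUnsense()].
#' @param asserted emit evidence-asserted (`r.0`/`p.0`) rather than
#'   predicted (`r.(0)`/`p.(0)`) forms.
#' @return a list of [AnnotationRecord-class] objects.
#' @examples
#' tx <- loadFixture(system.file("extdata", "btk_like_tx.json",
#'                               package = "stopfate"))
#' recs <- annotateVariants(tx, "c.592_595delinsCTAACTACATA")
#' recs[[1]]
#' @export
annotateVariants <- function(model, variants, cfg = NmdRuleConfig(),
                             unsenseWindowNt = 3L, asserted = FALSE) {
  stopifnot(is(model, "TranscriptModel"))
  lapply(variants, function(x) {
    raw <- if (is.character(x)) x else x@raw
    errRecord <- function(msg) new("AnnotationRecord", variantRaw = raw,
                                   transcriptId = transcriptId(model),
                                   consequenceClass = "error", error = msg)
    tryCatch({
      v <- if (is.character(x)) parseHgvsC(x) else x
      cons <- variantConsequence(model, v)
      verdict <- if (!is.na(cons@ptcCdsPos))
        classifyNmd(locateCdsPos(model, cons@ptcCdsPos), cons@ptcCdsPos,
                    model, cfg) else NULL
      unsense <- screenUnsense(v, cons, model, windowNt = unsenseWindowNt)
      emitAnnotation(cons, verdict, model, v, unsense = unsense,
                     asserted = asserted)
    },
    stopfate_unsupported_region = function(e)
      errRecord(paste0("unsupported-region: ", conditionMessage(e))),
    stopfate_parse_error = function(e)
      errRecord(paste0("parse-error: ", conditionMessage(e))),
    stopfate_refcheck_error = function(e)
      errRecord(paste0("reference-mismatch: ", conditionMessage(e))),
    stopfate_scan_aborted = function(e)
      errRecord(paste0("scan-aborted: ", conditionMessage(e))))
  })
}

# record for an essential splice-site change arriving through the VCF path:
# consequence is not computable from the codon scan, only the plof type is.
spliceRecord <- function(model, raw) {
  pt <- plofTag("essential_splice")
  new("AnnotationRecord", variantRaw = raw,
      transcriptId = transcriptId(model),
      consequenceClass = "splice_site",
      plofTag = pt$tag, hgvsR = "r.(?)", hgvsP = "p.?",
      caveats = c(pt$caveat,
                  "essential splice-site nucleotide: transcript-level outcome (exon skipping, intron inclusion) not modelled"))
}

#' Run the annotator end to end
#'
#' Orchestrates a complete run: read the transcript (fixture JSON or
#' GTF/GFF3 + FASTA), read the variants (HGVS list or VCF), annotate,
#' and write the TSV (always) plus an annotated VCF when the input was a
#' VCF. Per-variant failures are reported in the TSV `error` column and
#' counted in the returned summary; they do not abort the run.
#'
#' @param transcripts fixture JSON (`.json`) or GTF/GFF3 path.
#' @param variants HGVS variant list (text) or VCF path (`.vcf`).
#' @param out output TSV path.
#' @param fasta genome FASTA (required with GTF/GFF3 input).
#' @param transcriptId transcript to extract from GTF/GFF3.
#' @param vcfOut optional annotated-VCF output path (VCF input only).
#' @param config optional YAML/JSON rule-config path.
#' @param penultimateWindowNt,startProximalNt,longExonNt per-threshold
#'   overrides applied on top of `config`.
#' @param unsenseWindowNt exonic window for the unsense screen.
#' @param asserted emit evidence-asserted rather than predicted forms.
#' @return invisibly, a list: `records`, `table` (the written
#'   `data.frame`), `warnings` (number of per-variant errors).
#' @export
runAnnotate <- function(transcripts, variants, out, fasta = NULL,
                        transcriptId = NULL, vcfOut = NULL, config = NULL,
                        penultimateWindowNt = NULL, startProximalNt = NULL,
                        longExonNt = NULL, unsenseWindowNt = 3L,
                        asserted = FALSE) {
  cfg <- if (!is.null(config)) readNmdConfig(config) else NmdRuleConfig()
  if (!is.null(penultimateWindowNt))
    cfg@penultimateWindowNt <- as.integer(penultimateWindowNt)
  if (!is.null(startProximalNt))
    cfg@startProximalNt <- as.integer(startProximalNt)
  if (!is.null(longExonNt)) cfg@longExonNt <- as.integer(longExonNt)
  validObject(cfg)

  ext <- tolower(tools::file_ext(transcripts))
  model <- if (ext == "json") loadFixture(transcripts) else {
    if (is.null(fasta) || is.null(transcriptId))
      sfStop("stopfate_validation_error",
             "GTF/GFF3 input requires 'fasta' and 'transcriptId'")
    loadGtf(transcripts, fasta, transcriptId)
  }

  isVcf <- tolower(tools::file_ext(variants)) == "vcf"
  if (isVcf) {
    entries <- loadVcfVariants(variants, model)
    records <- lapply(entries, function(e) {
      if (!is.null(e$error))
        return(new("AnnotationRecord", variantRaw = e$raw,
                   transcriptId = transcriptId(model),
                   consequenceClass = "error", error = e$error))
      rec <- if (isTRUE(e$splice)) spliceRecord(model, e$raw)
        else annotateVariants(model, list(e$variant), cfg = cfg,
                              unsenseWindowNt = unsenseWindowNt,
                              asserted = asserted)[[1]]
      if (!is.null(e$note)) rec@caveats <- unique(c(rec@caveats, e$note))
      rec
    })
  } else {
    records <- annotateVariants(model, readVariantList(variants), cfg = cfg,
                                unsenseWindowNt = unsenseWindowNt,
                                asserted = asserted)
  }

  df <- recordsToDataFrame(records)
  writeAnnotationTsv(df, out)
  if (isVcf && !is.null(vcfOut)) writeVcfInfo(records, variants, vcfOut)
  nErr <- sum(!is.na(df$error))
  if (nErr > 0L)
    message(sprintf("stopfate: %d of %d variants could not be annotated (see 'error' column)",
                    nErr, nrow(df)))
  invisible(list(records = records, table = df, warnings = nErr))
}
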