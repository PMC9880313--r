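#' Read coding variants from a VCF against a genomically-anchored model
#'
#' Uses the standard VCF parser (`VariantAnnotation::readVcf`) and maps
#' each record onto the transcript: exonic records within the CDS become
#' [CodingVariant-class] edits in CDS coordinates (minus-strand transcripts
#' get complemented alleles), intronic records at the two essential
#' splice-site nucleotides are tagged `essential_splice`, and anything else
#' is returned as a reportable error entry — never silently dropped.
#'
#' Left-anchored indels (REF/ALT sharing their first base, the VCF norm)
#' are supported on plus-strand transcripts; minus-strand indel mapping is
#' reported as unsupported. Only the first ALT allele of a multi-allelic
#' record is interpreted (noted per record).
#'
#' @param vcfPath path to a VCF 4.x file.
#' @param model a [TranscriptModel-class] with genomic exon ranges.
#' @return a list with one entry per VCF record; each entry is a list with
#'   elements `raw`, and one of `variant` (a [CodingVariant-class]),
#'   `splice = TRUE`, or `error` (message), plus `note` when applicable.
#' @export
loadVcfVariants <- function(vcfPath, model) {
  stopifnot(is(model, "TranscriptModel"))
  if (!file.exists(vcfPath))
    sfStop("stopfate_not_found", "VCF not found: %s", vcfPath)
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  minus <- model@txStrand == "-"
  comp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))

  lapply(seq_along(rr), function(i) {
    gpos <- GenomicRanges::start(rr)[i]
    ref <- refs[i]
    altSet <- as.character(alts[[i]])
    note <- if (length(altSet) > 1L)
      "multi-allelic record: only the first ALT interpreted" else NULL
    alt <- altSet[1]
    raw <- sprintf("%s:%d %s>%s",
                   as.character(GenomicRanges::seqnames(rr))[i], gpos, ref, alt)
    entry <- function(...) c(list(raw = raw), list(...),
                             if (!is.null(note)) list(note = note))
    if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
      return(entry(error = "non-ACGT alleles unsupported"))

    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      m <- genomicToCds(model, gpos)
      if (identical(m$region, "intron"))
        return(if (m$essentialSplice) entry(splice = TRUE)
               else entry(error = "intronic position beyond the essential splice sites"))
      if (is.na(m$cdsPos))
        return(entry(error = "position outside the CDS"))
      r <- if (minus) comp(ref) else ref
      a <- if (minus) comp(alt) else alt
      v <- new("CodingVariant", kind = "substitution",
               start = m$cdsPos, end = m$cdsPos, refSeq = r, altSeq = a,
               raw = raw)
      return(entry(variant = v))
    }

    if (minus)
      return(entry(error = "indel mapping on minus-strand transcripts unsupported"))
    if (substring(ref, 1L, 1L) != substring(alt, 1L, 1L))
      return(entry(error = "complex allele (no shared anchor base) unsupported"))

    if (nchar(ref) > 1L && nchar(alt) == 1L) {          # deletion
      delLen <- nchar(ref) - 1L
      m1 <- genomicToCds(model, gpos + 1L)
      m2 <- genomicToCds(model, gpos + delLen)
      if (is.na(m1$cdsPos) || is.na(m2$cdsPos))
        return(entry(error = "deletion not fully within the CDS of one exon"))
      v <- new("CodingVariant", kind = "deletion",
               start = m1$cdsPos, end = m2$cdsPos,
               refSeq = substring(ref, 2L), raw = raw)
      return(entry(variant = v))
    }
    if (nchar(alt) > 1L && nchar(ref) == 1L) {          # insertion
      m <- genomicToCds(model, gpos)
      if (is.na(m$cdsPos) || m$cdsPos >= cdsLength(model))
        return(entry(error = "insertion anchor outside the CDS"))
      v <- new("CodingVariant", kind = "insertion",
               start = m$cdsPos, end = m$cdsPos + 1L,
               altSeq = substring(alt, 2L), raw = raw)
      return(entry(variant = v))
    }
    # delins with shared anchor
    m1 <- genomicToCds(model, gpos + 1L)
    m2 <- genomicToCds(model, gpos + nchar(ref) - 1L)
    if (is.na(m1$cdsPos) || is.na(m2$cdsPos))
      return(entry(error = "delins not fully within the CDS of one exon"))
    v <- new("CodingVariant", kind = "delins",
             start = m1$cdsPos, end = m2$cdsPos,
             refSeq = substring(ref, 2L), altSeq = substring(alt, 2L),
             raw = raw)
    entry(variant = v)
  })
}

#' Annotate a VCF with the STOPFATE INFO key
#'
#' Copies the input VCF, declares one INFO key in the header and appends
#' `STOPFATE=<consequence>|<fate>|<rules>|<varioRna>|<varioProtein>|<hgvs_r>|<hgvs_p>|<plof>`
#' (pipe-delimited subfields, spaces encoded as underscores) to each data
#' line. `records` must hold one [AnnotationRecord-class] per VCF data
#' line, in file order.
#'
#' @param records list of [AnnotationRecord-class] objects.
#' @param inVcf input VCF path.
#' @param outVcf output VCF path.
#' @return `outVcf`, invisibly.
#' @export
writeVcfInfo <- function(records, inVcf, outVcf) {
  if (!file.exists(inVcf))
    sfStop("stopfate_not_found", "VCF not found: %s", inVcf)
  lines <- readLines(inVcf, warn = FALSE)
  isHeader <- startsWith(lines, "#")
  dataIdx <- which(!isHeader)
  if (length(dataIdx) != length(records))
    sfStop("stopfate_validation_error",
           "VCF has %d data lines but %d records were supplied",
           length(dataIdx), length(records))
  chromIdx <- which(startsWith(lines, "#CHROM"))
  if (length(chromIdx) != 1L)
    sfStop("stopfate_parse_error", "no #CHROM header line in %s", inVcf)
  infoLine <- paste0(
    '##INFO=<ID=STOPFATE,Number=1,Type=String,Description=',
    '"NMD-aware PTC fate: consequence|fate|rules|varioRna|varioProtein|',
    'hgvs_r|hgvs_p|plof">')

  enc <- function(x) {
    x <- ifelse(is.na(x) | !nzchar(x), ".", x)
    gsub("[ ;=,]", "_", x)
  }
  tags <- vapply(records, function(r) {
    paste(enc(c(r@consequenceClass, r@nmdFate,
                paste(r@rulesFired, collapse = "&"),
                r@varioRna, r@varioProtein, r@hgvsR, r@hgvsP, r@plofTag)),
          collapse = "|")
  }, character(1))

  for (j in seq_along(dataIdx)) {
    fields <- strsplit(lines[dataIdx[j]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L)
      sfStop("stopfate_parse_error", "VCF data line %d has fewer than 8 fields",
             j)
    info <- fields[8]
    fields[8] <- if (info %in% c(".", ""))
      paste0("STOPFATE=", tags[j]) else paste0(info, ";STOPFATE=", tags[j])
    lines[dataIdx[j]] <- paste(fields, collapse = "\t")
  }
  out <- append(lines, infoLine, after = chromIdx - 1L)
  ok <- tryCatch({ writeLines(out, outVcf); TRUE }, error = function(e) e)
  if (!isTRUE(ok))
    sfStop("stopfate_validation_error", "failed writing VCF to %s: %s",
           outVcf, conditionMessage(ok))
  invisible(outVcf)
}
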