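#' Load a transcript model from GTF/GFF3 plus genome FASTA
#'
#' Imports exon and CDS features for one transcript, orders exons 5' to 3'
#' in transcript orientation, splices the genomic sequence (minus-strand
#' transcripts are reverse-complemented so `splicedSeq` is always
#' sense-strand mRNA) and derives the CDS span in spliced coordinates.
#' Ensembl-dialect GTF CDS features exclude the stop codon; when
#' `stop_codon` features are absent the CDS is extended by 3 nt if the next
#' in-frame codon is a stop. The resulting span, stop included, must be
#' divisible by 3.
#'
#' @param gtfPath GTF or GFF3 file (dialect detected by `rtracklayer`).
#' @param fastaPath genome FASTA covering the transcript's contig.
#' @param transcriptId transcript to extract.
#' @param permissiveStart waive the ATG start-codon check.
#' @return a [TranscriptModel-class] with `exonRanges` populated.
#' @export
loadGtf <- function(gtfPath, fastaPath, transcriptId, permissiveStart = FALSE) {
  if (!file.exists(gtfPath))
    sfStop("stopfate_not_found", "annotation file not found: %s", gtfPath)
  if (!file.exists(fastaPath))
    sfStop("stopfate_not_found", "FASTA file not found: %s", fastaPath)
  gr <- rtracklayer::import(gtfPath)
  md <- S4Vectors::mcols(gr)

  belongsTo <- function(gr) {
    md <- S4Vectors::mcols(gr)
    if ("transcript_id" %in% colnames(md)) {
      !is.na(md$transcript_id) & md$transcript_id == transcriptId
    } else if ("Parent" %in% colnames(md)) {
      # GFF3: Parent is a CharacterList; accept bare and "transcript:"-prefixed ids
      vapply(md$Parent, function(p)
        any(p %in% c(transcriptId, paste0("transcript:", transcriptId))),
        logical(1))
    } else rep(FALSE, length(gr))
  }

  sel <- belongsTo(gr)
  exons <- gr[sel & tolower(as.character(md$type)) == "exon"]
  cds <- gr[sel & tolower(as.character(md$type)) == "cds"]
  stops <- gr[sel & tolower(as.character(md$type)) == "stop_codon"]
  if (length(exons) == 0L)
    sfStop("stopfate_not_found", "transcript '%s' not found in %s",
           transcriptId, gtfPath)
  if (length(cds) == 0L)
    sfStop("stopfate_not_found", "no CDS features for transcript '%s'",
           transcriptId)

  strand <- as.character(GenomicRanges::strand(exons))[1]
  if (!strand %in% c("+", "-"))
    sfStop("stopfate_validation_error",
           "transcript '%s' has no usable strand", transcriptId)
  minus <- strand == "-"
  ord <- order(GenomicRanges::start(exons), decreasing = minus)
  exons <- exons[ord]

  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  contig <- as.character(GenomicRanges::seqnames(exons))[1]
  if (!contig %in% names(genome))
    sfStop("stopfate_not_found", "contig '%s' absent from %s", contig, fastaPath)
  contigSeq <- genome[[contig]]

  pieces <- lapply(seq_along(exons), function(i) {
    s <- Biostrings::subseq(contigSeq, GenomicRanges::start(exons)[i],
                            GenomicRanges::end(exons)[i])
    if (minus) Biostrings::reverseComplement(s) else s
  })
  spliced <- do.call(Biostrings::xscat, pieces)

  exonLens <- GenomicRanges::width(exons)
  cum <- c(0L, cumsum(exonLens))

  genomicToTx <- function(gpos) {
    for (i in seq_along(exons)) {
      st <- GenomicRanges::start(exons)[i]
      en <- GenomicRanges::end(exons)[i]
      if (gpos >= st && gpos <= en)
        return(cum[i] + if (minus) en - gpos + 1L else gpos - st + 1L)
    }
    NA_integer_
  }

  if (length(stops) > 0L)
    cds <- c(GenomicRanges::granges(cds), GenomicRanges::granges(stops))
  cds5 <- if (minus) max(GenomicRanges::end(cds)) else min(GenomicRanges::start(cds))
  cds3 <- if (minus) min(GenomicRanges::start(cds)) else max(GenomicRanges::end(cds))
  cdsStart <- genomicToTx(cds5)
  cdsEnd <- genomicToTx(cds3)
  if (is.na(cdsStart) || is.na(cdsEnd))
    sfStop("stopfate_validation_error",
           "CDS of '%s' does not lie on its exons", transcriptId)

  cdsLen <- cdsEnd - cdsStart + 1L
  txLen <- sum(exonLens)
  if (length(stops) == 0L && cdsEnd + 3L <= txLen) {
    nextCodon <- as.character(Biostrings::subseq(spliced, cdsEnd + 1L, cdsEnd + 3L))
    if (nextCodon %in% STOP_CODONS) {
      cdsEnd <- cdsEnd + 3L
      cdsLen <- cdsLen + 3L
    }
  }
  if (cdsLen %% 3L != 0L)
    sfStop("stopfate_validation_error",
           "CDS length %d of '%s' not divisible by 3", cdsLen, transcriptId)

  TranscriptModel(transcriptId = transcriptId,
                  exonLengths = exonLens,
                  cdsStartTx = cdsStart, cdsEndTx = cdsEnd,
                  splicedSeq = spliced, txStrand = strand,
                  exonRanges = GenomicRanges::granges(exons),
                  permissiveStart = permissiveStart)
}

#' Map a genomic position to transcript / CDS coordinates
#'
#' Requires a model with genomic exon ranges (GTF/GFF3 ingestion). Returns
#' the spliced-mRNA position, the CDS position (`NA` when outside the
#' CDS), and — for intronic positions — whether the site is one of the two
#' essential splice-site nucleotides flanking an exon.
#'
#' @param model a [TranscriptModel-class] with `exonRanges`.
#' @param gpos 1-based genomic position.
#' @return a list: `mrnaPos`, `cdsPos`, `region` (`"exon"`, `"intron"` or
#'   `"outside"`), `essentialSplice` (logical).
#' @export
genomicToCds <- function(model, gpos) {
  stopifnot(is(model, "TranscriptModel"))
  if (is.null(model@exonRanges))
    sfStop("stopfate_validation_error",
           "model '%s' has no genomic exon coordinates", model@transcriptId)
  ex <- model@exonRanges
  minus <- model@txStrand == "-"
  starts <- GenomicRanges::start(ex)
  ends <- GenomicRanges::end(ex)
  cum <- c(0L, cumsum(model@exonLengths))
  n <- length(ex)
  for (i in seq_len(n)) {
    if (gpos >= starts[i] && gpos <= ends[i]) {
      mrna <- cum[i] + if (minus) ends[i] - gpos + 1L else gpos - starts[i] + 1L
      cdsPos <- mrna - model@cdsStartTx + 1L
      if (cdsPos < 1L || cdsPos > cdsLength(model)) cdsPos <- NA_integer_
      return(list(mrnaPos = mrna, cdsPos = cdsPos, region = "exon",
                  essentialSplice = FALSE))
    }
  }
  # intronic: essential splice sites are the two nt beyond internal exon
  # boundaries (transcript ends excluded)
  gmin <- min(starts); gmax <- max(ends)
  if (gpos < gmin || gpos > gmax)
    return(list(mrnaPos = NA_integer_, cdsPos = NA_integer_,
                region = "outside", essentialSplice = FALSE))
  ess <- FALSE
  for (i in seq_len(n)) {
    leftEdge <- starts[i]; rightEdge <- ends[i]
    if (gpos %in% c(leftEdge - 1L, leftEdge - 2L) && leftEdge > gmin) ess <- TRUE
    if (gpos %in% c(rightEdge + 1L, rightEdge + 2L) && rightEdge < gmax) ess <- TRUE
  }
  list(mrnaPos = NA_integer_, cdsPos = NA_integer_, region = "intron",
       essentialSplice = ess)
}
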