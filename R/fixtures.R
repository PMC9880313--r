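#' Generate a synthetic protein-coding transcript
#'
#' Deterministic for a given seed: the CDS is an ATG start, a random fill of
#' sense codons (no internal stop), and a single terminal stop codon; UTRs
#' are random nucleotides. `forceCodons` overwrites named codon indices with
#' specific codons after the random fill (used to pin down worked-example
#' sites); forcing a stop codon is rejected.
#'
#' @param exonLengths integer vector of exon lengths (nt), 5' to 3'.
#' @param cdsStartTx 1-based spliced-mRNA position of the first CDS
#'   nucleotide.
#' @param cdsLengthNt CDS length in nt including the stop codon (divisible
#'   by 3).
#' @param seed RNG seed; regeneration with the same arguments is
#'   bit-identical.
#' @param transcriptId identifier for the generated transcript.
#' @param forceCodons named character vector, names = codon indices,
#'   values = codons to place there (e.g. `c("24" = "TGG")`).
#' @return a validated [TranscriptModel-class].
#' @examples
#' makeTranscript(c(200L, 150L, 300L), cdsStartTx = 1L,
#'                cdsLengthNt = 600L, seed = 7)
#' @export
makeTranscript <- function(exonLengths, cdsStartTx, cdsLengthNt, seed = 1L,
                           transcriptId = "synthetic_tx",
                           forceCodons = NULL) {
  exonLengths <- as.integer(exonLengths)
  cdsStartTx <- as.integer(cdsStartTx)
  cdsLengthNt <- as.integer(cdsLengthNt)
  txLen <- sum(exonLengths)
  if (cdsLengthNt %% 3L != 0L || cdsLengthNt < 6L)
    sfStop("stopfate_validation_error",
           "cdsLengthNt must be divisible by 3 and >= 6 (got %d)", cdsLengthNt)
  cdsEnd <- cdsStartTx + cdsLengthNt - 1L
  if (cdsStartTx < 1L || cdsEnd > txLen)
    sfStop("stopfate_validation_error",
           "CDS span %d..%d impossible for transcript length %d",
           cdsStartTx, cdsEnd, txLen)
  nCodons <- cdsLengthNt %/% 3L
  seq <- withSeed(seed, {
    codons <- c("ATG",
                sample(SENSE_CODONS, nCodons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    utr5 <- paste(sample(c("A", "C", "G", "T"), cdsStartTx - 1L,
                         replace = TRUE), collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"), txLen - cdsEnd,
                         replace = TRUE), collapse = "")
    if (!is.null(forceCodons)) {
      idx <- as.integer(names(forceCodons))
      if (any(is.na(idx)) || any(idx < 2L) || any(idx >= nCodons))
        sfStop("stopfate_validation_error",
               "forceCodons indices must lie strictly inside the CDS (2..%d)",
               nCodons - 1L)
      if (any(forceCodons %in% STOP_CODONS))
        sfStop("stopfate_validation_error", "forceCodons must not place a stop codon")
      codons[idx] <- unname(forceCodons)
    }
    paste0(utr5, paste(codons, collapse = ""), utr3)
  })
  TranscriptModel(transcriptId = transcriptId, exonLengths = exonLengths,
                  cdsStartTx = cdsStartTx, cdsEndTx = cdsEnd,
                  splicedSeq = seq)
}

#' Synthetic worked-example transcripts
#'
#' `dmdLikeTranscript()` emulates dystrophin isoform 1: 3,685 amino acids
#' (CDS 11,058 nt including the stop codon) across 79 exons, with codon 24
#' pinned to TGG (Trp) so that `c.72G>A` creates a TGA stop — a PTC in exon
#' 1, 70 nt into the CDS, where the start-proximal rule applies.
#'
#' `btkLikeTranscript()` emulates Bruton tyrosine kinase: 659 amino acids
#' (CDS 1,980 nt) across 19 exons, with codons 198/199 pinned to CTA/AAA so
#' that `c.592_595delinsCTAACTACATA` leaves codon 198 silent and shifts the
#' frame from Lys199, terminating three codons into the new frame
#' (Lys199Thrfs*3) — a PTC in exon 8, mid-transcript, which triggers NMD.
#'
#' Both are synthetic stand-ins generated by [makeTranscript()] with fixed
#' seeds; only the features the worked examples exercise (exon counts, CDS
#' sizes, the pinned codons and the exon holding the variant) mirror the
#' real genes.
#'
#' @return a [TranscriptModel-class].
#' @export
dmdLikeTranscript <- function() {
  makeTranscript(
    exonLengths = c(300L, rep(140L, 77L), 1300L),
    cdsStartTx = 101L,
    cdsLengthNt = 11058L,
    seed = 1101L,
    transcriptId = "DMD_like",
    forceCodons = c("24" = "TGG"))
}

#' @rdname dmdLikeTranscript
#' @export
btkLikeTranscript <- function() {
  makeTranscript(
    exonLengths = c(100L, 80L, 90L, 80L, 90L, 80L, 90L, 120L, rep(130L, 10L),
                    350L),
    cdsStartTx = 89L,
    cdsLengthNt = 1980L,
    seed = 1902L,
    transcriptId = "BTK_like",
    forceCodons = c("198" = "CTA", "199" = "AAA"))
}

#' Sweep templates for the rule-boundary harness
#'
#' `threeExonTemplate()` has a 300 nt penultimate exon with all its CDS
#' positions beyond the start-proximal window — the substrate for the 50 nt
#' rule boundary. `fiveExonTemplate()` places the start-proximal window
#' inside short internal exons — the substrate for the 150 nt boundary.
#' `growableExonTemplate()` returns a `function(exonLengthNt)` producing a
#' five-exon transcript whose second exon has the requested length, with a
#' mid-exon PTC position — the substrate for the 400 bp long-exon boundary.
#'
#' @param seed RNG seed forwarded to [makeTranscript()].
#' @return a [TranscriptModel-class], or for `growableExonTemplate()` a
#'   function as described.
#' @export
threeExonTemplate <- function(seed = 11L) {
  makeTranscript(c(200L, 300L, 200L), cdsStartTx = 1L, cdsLengthNt = 699L,
                 seed = seed, transcriptId = "three_exon_template")
}

#' @rdname threeExonTemplate
#' @export
fiveExonTemplate <- function(seed = 12L) {
  makeTranscript(c(100L, 100L, 100L, 100L, 100L), cdsStartTx = 1L,
                 cdsLengthNt = 498L, seed = seed,
                 transcriptId = "five_exon_template")
}

#' @rdname threeExonTemplate
#' @export
growableExonTemplate <- function(seed = 13L) {
  function(exonLengthNt) {
    exonLengthNt <- as.integer(exonLengthNt)
    lens <- c(150L, exonLengthNt, 150L, 150L, 150L)
    total <- sum(lens)
    cdsLen <- (total %/% 3L) * 3L
    model <- makeTranscript(lens, cdsStartTx = 1L, cdsLengthNt = cdsLen,
                            seed = seed,
                            transcriptId = sprintf("growable_exon_%d", exonLengthNt))
    # mid-exon-2 PTC position: past the start-proximal window by construction
    list(model = model, ptcCdsPos = 150L + exonLengthNt %/% 2L)
  }
}

#' Enumerate single-nucleotide nonsense variants across a transcript
#'
#' For every codon of the CDS except the initiator and the reference stop,
#' yields one substitution creating a stop codon when one is reachable by a
#' single-nucleotide change; codons from which no stop is reachable are
#' skipped and counted.
#'
#' @param model a [TranscriptModel-class].
#' @return a list of [CodingVariant-class] objects, with attributes
#'   `skipped` (number of codons with no reachable stop) and `codon`
#'   (integer vector, the codon each variant hits).
#' @export
ptcSweep <- function(model) {
  cds <- cdsSeq(model)
  codons <- codonSplit(cds)
  nC <- length(codons)
  bases <- c("A", "C", "G", "T")
  out <- list()
  hitCodon <- integer(0)
  skipped <- 0L
  for (k in seq.int(2L, nC - 1L)) {
    codon <- codons[k]
    found <- FALSE
    for (posInCodon in 1:3) {
      refBase <- substring(codon, posInCodon, posInCodon)
      for (alt in setdiff(bases, refBase)) {
        newCodon <- codon
        substring(newCodon, posInCodon, posInCodon) <- alt
        if (newCodon %in% STOP_CODONS) {
          cdsPos <- 3L * (k - 1L) + posInCodon
          out[[length(out) + 1L]] <- new("CodingVariant",
            kind = "substitution", start = cdsPos, end = cdsPos,
            refSeq = refBase, altSeq = alt,
            raw = sprintf("c.%d%s>%s", cdsPos, refBase, alt))
          hitCodon <- c(hitCodon, k)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) skipped <- skipped + 1L
  }
  attr(out, "skipped") <- skipped
  attr(out, "codon") <- hitCodon
  out
}

#' Regenerate the committed fixture JSON files
#'
#' Writes `dmd_like_tx.json` and `btk_like_tx.json` into `dir`. The
#' committed copies under `inst/extdata/` are exactly these; the test suite
#' cross-checks that regeneration is bit-identical.
#'
#' @param dir output directory.
#' @return character vector of the written paths, invisibly.
#' @export
regenerateFixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "dmd_like_tx.json"),
             file.path(dir, "btk_like_tx.json"))
  writeFixtureJson(dmdLikeTranscript(), paths[1])
  writeFixtureJson(btkLikeTranscript(), paths[2])
  invisible(paths)
}
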