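# Independent oracles used across the suite. They deliberately avoid the
# package's incremental codon scan: translation goes through
# Biostrings::translate on the full sequence, comparisons are whole-vector.

# Brute-force full-translation comparison of reference and mutated CDS.
# Returns indices in the mutated frame: first residue differing from the
# reference frame, the first stop of the mutated translation, and the
# fs*N offset.
bruteScan <- function(refCds, mutCds, utr3 = "") {
  aaOf <- function(s) {
    n <- (nchar(s) %/% 3L) * 3L
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n)), no.init.codon = TRUE)), "")[[1]]
  }
  refAa <- aaOf(refCds)
  mutAa <- aaOf(paste0(mutCds, utr3))
  cmp <- min(length(refAa), length(mutAa))
  diffs <- which(refAa[seq_len(cmp)] != mutAa[seq_len(cmp)])
  firstAffected <- if (length(diffs)) diffs[1] else NA_integer_
  mutStop <- which(mutAa == "*")[1]
  list(
    firstAffected = firstAffected,
    mutStop = mutStop,
    terOffset = if (!is.na(mutStop) && !is.na(firstAffected))
      mutStop - firstAffected + 1L else NA_integer_
  )
}

# The six precedence steps of the NMD classifier collapsed into a single
# boolean expression over the raw measurements.
nmdOracleFate <- function(nExons, exonRank, dist, exonLen, cdsPos, cfg) {
  escape <- (nExons == 1L) || (exonRank == nExons) ||
    (exonRank == nExons - 1L && !is.na(dist) && dist <= cfg@penultimateWindowNt)
  attenuated <- (cdsPos <= cfg@startProximalNt) || (exonLen > cfg@longExonNt)
  if (escape) "ESCAPE" else if (attenuated) "INTERMEDIATE" else "TRIGGER"
}

# Random supported edit within the CDS of `model`, valid by construction.
randomVariant <- function(model) {
  cds <- cdsSeq(model)
  L <- nchar(cds)
  kind <- sample(c("substitution", "deletion", "insertion", "duplication",
                   "delins"), 1L)
  bases <- c("A", "C", "G", "T")
  start <- sample(4:(L - 20L), 1L)
  switch(kind,
    substitution = {
      ref <- substring(cds, start, start)
      new("CodingVariant", kind = kind, start = start, end = start,
          refSeq = ref, altSeq = sample(setdiff(bases, ref), 1L),
          raw = "random")
    },
    deletion = {
      end <- start + sample(0:5, 1L)
      new("CodingVariant", kind = kind, start = start, end = end,
          refSeq = substring(cds, start, end), raw = "random")
    },
    insertion = {
      new("CodingVariant", kind = kind, start = start, end = start + 1L,
          altSeq = paste(sample(bases, sample(1:12, 1L), replace = TRUE),
                         collapse = ""), raw = "random")
    },
    duplication = {
      end <- start + sample(0:5, 1L)
      new("CodingVariant", kind = kind, start = start, end = end,
          raw = "random")
    },
    delins = {
      end <- start + sample(0:5, 1L)
      new("CodingVariant", kind = kind, start = start, end = end,
          altSeq = paste(sample(bases, sample(1:12, 1L), replace = TRUE),
                         collapse = ""), raw = "random")
    })
}

# --- toy genomic fixtures (built in code at test time) ---------------------

# Embeds a 2-exon transcript into a 600 nt contig and writes GTF + FASTA.
# Exon 1: genomic 101-200 (tx 1-100); exon 2: genomic 301-450 (tx 101-250).
# CDS tx 11..160 incl. stop; the GTF carries Ensembl-style CDS features
# that exclude the stop codon, exercising the loader's stop extension.
writeToyGtfFasta <- function(dir, strand = "+", seed = 42L) {
  spliced <- as.character(splicedSeq(makeTranscript(
    c(100L, 150L), cdsStartTx = 11L, cdsLengthNt = 150L, seed = seed,
    transcriptId = "toy")))
  genome <- paste(
    sample(c("A", "C", "G", "T"), 600L, replace = TRUE), collapse = "")
  substring(genome, 101L, 200L) <- substr(spliced, 1L, 100L)
  substring(genome, 301L, 450L) <- substr(spliced, 101L, 250L)

  exons <- rbind(c(101L, 200L), c(301L, 450L))
  cdsg <- rbind(c(111L, 200L), c(301L, 357L))  # tx 11..157 (stop excluded)
  contig <- genome
  if (strand == "-") {
    glen <- 600L
    contig <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genome)))
    flip <- function(m) {
      out <- cbind(glen - m[, 2] + 1L, glen - m[, 1] + 1L)
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    exons <- flip(exons)
    cdsg <- flip(cdsg)
  }
  fa <- file.path(dir, sprintf("toy_%s.fa", if (strand == "+") "plus" else "minus"))
  gtf <- file.path(dir, sprintf("toy_%s.gtf", if (strand == "+") "plus" else "minus"))
  writeLines(c(">chrT toy contig", contig), fa)
  attr <- 'gene_id "g1"; transcript_id "tx1";'
  lines <- c(
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
            exons[, 1], exons[, 2], strand, attr),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t0\t%s",
            cdsg[, 1], cdsg[, 2], strand, attr))
  writeLines(lines, gtf)
  list(gtf = gtf, fasta = fa, spliced = spliced)
}

# Map a CDS position of the plus-strand toy transcript to its genomic
# position (hand-derived from the embedding above).
toyCdsToGenomic <- function(cdsPos) {
  mrna <- 10L + cdsPos
  if (mrna <= 100L) 100L + mrna else 300L + (mrna - 100L)
}

writeToyVcf <- function(path, rows) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=600>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows), path)
}
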