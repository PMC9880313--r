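# A transcript engineered so exon-boundary codons admit synonymous changes:
# third codon positions falling on exon edges are easy to find in a 3-exon
# layout with exon lengths that are multiples of 3 and CDS from position 1.
makeUnsenseTx <- function(seed = 41L) {
  makeTranscript(c(99L, 99L, 102L), cdsStartTx = 1L, cdsLengthNt = 300L,
                 seed = seed)
}

findSynAt <- function(tx, cdsPos) {
  cds <- cdsSeq(tx)
  codonIdx <- cdsPosToCodon(cdsPos)
  codon <- substring(cds, 3L * codonIdx - 2L, 3L * codonIdx)
  posInCodon <- cdsPos - (3L * codonIdx - 3L)
  refBase <- substring(codon, posInCodon, posInCodon)
  for (alt in setdiff(c("A", "C", "G", "T"), refBase)) {
    cand <- codon
    substring(cand, posInCodon, posInCodon) <- alt
    if (!(cand %in% c("TAA", "TAG", "TGA")) &&
        Biostrings::GENETIC_CODE[[cand]] == Biostrings::GENETIC_CODE[[codon]])
      return(new("CodingVariant", kind = "substitution", start = cdsPos,
                 end = cdsPos, refSeq = refBase, altSeq = alt,
                 raw = sprintf("c.%d%s>%s", cdsPos, refBase, alt)))
  }
  NULL
}

test_that("synonymous substitutions at exon edges are flagged as unsense candidates", {
  # third codon positions are the most degenerate site; scan a few seeds
  # until the last nt of exon 1 (cds 99) admits a synonymous change
  v <- NULL
  for (s in 41:60) {
    tx <- makeUnsenseTx(seed = s)
    v <- findSynAt(tx, 99L)
    if (!is.null(v)) break
  }
  expect_false(is.null(v))
  cons <- variantConsequence(tx, v)
  expect_equal(cons@consequenceClass, "synonymous")
  flag <- screenUnsense(v, cons, tx)
  expect_true(flag$flagged)
  expect_equal(flag$reason, "exonic_splice_site_proximal")
  expect_equal(flag$distToNearestJunction, 1L)
  expect_equal(flag$vario, "VariO:0514")
})

test_that("mid-exon synonymous variants pass with the codon-table caveat", {
  v <- NULL
  for (s in 41:60) {
    tx <- makeUnsenseTx(seed = s)
    v <- findSynAt(tx, 45L)   # 45 nt from the 5' edge, 55 from the junction
    if (!is.null(v)) break
  }
  expect_false(is.null(v))
  cons <- variantConsequence(tx, v)
  flag <- screenUnsense(v, cons, tx)
  expect_false(flag$flagged)
  expect_equal(flag$reason, "none")
  expect_match(flag$caveat, "codon-table")
})

test_that("non-synonymous input yields a not-applicable result, not an error", {
  tx <- makeUnsenseTx()
  cds <- cdsSeq(tx)
  # force a missense at the junction: change a first-codon-position base
  p <- 97L
  ref <- substring(cds, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- new("CodingVariant", kind = "substitution", start = p, end = p,
           refSeq = ref, altSeq = alt, raw = "x")
  cons <- variantConsequence(tx, v)
  flag <- screenUnsense(v, cons, tx)
  expect_equal(flag$reason, "not_applicable")
  expect_false(flag$flagged)

  del <- new("CodingVariant", kind = "deletion", start = 10L, end = 12L,
             raw = "y")
  consDel <- variantConsequence(tx, del)
  expect_equal(screenUnsense(del, consDel, tx)$reason, "not_applicable")
})

test_that("a flagged variant never changes the encoded residue; window is monotone", {
  set.seed(77)
  for (s in 61:70) {
    tx <- makeUnsenseTx(seed = s)
    for (p in c(1:6, 94:105, 196:204, 295:300)) {
      v <- findSynAt(tx, p)
      if (is.null(v)) next
      cons <- variantConsequence(tx, v)
      for (w in 1:6) {
        flag <- screenUnsense(v, cons, tx, windowNt = w)
        if (flag$flagged) {
          # synonymy by codon table holds for every flagged record
          expect_equal(cons@mutProtein, cons@refProtein)
          # enlarging the window never unflags
          for (w2 in w:6)
            expect_true(screenUnsense(v, cons, tx, windowNt = w2)$flagged)
          break
        }
      }
    }
  }
})

test_that("unsense candidacy is folded into the annotation record and TSV", {
  v <- NULL
  for (s in 41:60) {
    tx <- makeUnsenseTx(seed = s)
    v <- findSynAt(tx, 99L)
    if (!is.null(v)) break
  }
  rec <- annotateVariants(tx, list(v))[[1]]
  expect_true(rec@unsenseCandidate)
  expect_true(any(grepl("VariO:0514", rec@caveats)))
  df <- recordsToDataFrame(list(rec))
  expect_true(df$unsense_candidate[1])
})
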