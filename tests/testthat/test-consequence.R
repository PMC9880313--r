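test_that("applyVariant performs pure CDS edits with reference checking", {
  tx <- makeTranscript(c(120L, 150L, 120L), cdsStartTx = 1L,
                       cdsLengthNt = 390L, seed = 8)
  cds <- cdsSeq(tx)

  v <- parseHgvsC(sprintf("c.4%s>T", substring(cds, 4, 4)))
  mut <- applyVariant(tx, v)
  expect_equal(nchar(mut), nchar(cds))
  expect_equal(substring(mut, 4, 4), "T")
  expect_equal(substring(mut, 1, 3), substring(cds, 1, 3))

  # delins removing 4 nt and inserting 11 nt: net +7
  d <- parseHgvsC("c.10_13delinsCTAACTACATA")
  expect_equal(nchar(applyVariant(tx, d)) - nchar(cds), 7L)

  # duplication inserts a copy of its span after the span
  dup <- parseHgvsC("c.10_12dup")
  expect_equal(substring(applyVariant(tx, dup), 13, 15), substring(cds, 10, 12))

  # reference mismatch is a typed error naming expected vs found
  refBase <- substring(cds, 20, 20)
  wrong <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  err <- tryCatch(applyVariant(tx, parseHgvsC(sprintf("c.20%s>T", wrong))),
                  error = identity)
  expect_s3_class(err, "stopfate_refcheck_error")
  expect_match(conditionMessage(err), "expected")

  # spans outside the CDS are unsupported, not silently shifted
  expect_error(applyVariant(tx, parseHgvsC("c.395G>A")),
               class = "stopfate_unsupported_region")
})

test_that("frame-preserving consequences classify by translation comparison", {
  tx <- makeTranscript(c(120L, 150L, 120L), cdsStartTx = 1L,
                       cdsLengthNt = 390L, seed = 9)
  cds <- cdsSeq(tx)

  # in-frame deletion of one full codon (positions 10-12), no new stop
  cons <- variantConsequence(tx, parseHgvsC("c.10_12del"))
  expect_equal(cons@frameOffset, 0L)
  expect_true(cons@consequenceClass %in% c("inframe_indel", "nonsense"))
  if (cons@consequenceClass == "inframe_indel")
    expect_true(is.na(cons@ptcCdsPos))

  # third-base synonymous change somewhere in the CDS
  syn <- NULL
  for (p in seq(6L, 300L, by = 3L)) {
    codon <- substring(cds, p - 2L, p)
    for (alt in setdiff(c("A", "C", "G", "T"), substring(codon, 3, 3))) {
      cand <- paste0(substring(codon, 1, 2), alt)
      if (!(cand %in% c("TAA", "TAG", "TGA")) &&
          Biostrings::GENETIC_CODE[[cand]] == Biostrings::GENETIC_CODE[[codon]]) {
        syn <- sprintf("c.%d%s>%s", p, substring(codon, 3, 3), alt)
        break
      }
    }
    if (!is.null(syn)) break
  }
  expect_false(is.null(syn))
  expect_equal(variantConsequence(tx, parseHgvsC(syn))@consequenceClass,
               "synonymous")
})

test_that("the DMD-like substitution yields a nonsense PTC at codon 24", {
  tx <- loadFixture(system.file("extdata", "dmd_like_tx.json",
                                package = "stopfate"))
  cons <- variantConsequence(tx, parseHgvsC("c.72G>A"))
  expect_equal(cons@consequenceClass, "nonsense")
  expect_equal(cons@ptcCodon, 24L)
  expect_equal(cons@ptcCdsPos, 70L)  # 3*24 - 2
  expect_equal(cons@refResidue, "W")
})

test_that("the BTK-like delins frameshifts from Lys199 with stop at offset 3", {
  tx <- loadFixture(system.file("extdata", "btk_like_tx.json",
                                package = "stopfate"))
  cons <- variantConsequence(tx, parseHgvsC("c.592_595delinsCTAACTACATA"))
  expect_equal(cons@consequenceClass, "frameshift_with_ptc")
  expect_equal(cons@netLengthChange, 7L)
  expect_equal(cons@frameOffset, 1L)
  expect_equal(cons@firstAffectedCodon, 199L)
  expect_equal(cons@refResidue, "K")
  expect_equal(cons@newResidue, "T")
  expect_equal(cons@terOffset, 3L)
  # brute-force oracle agrees
  oracle <- bruteScan(cdsSeq(tx), applyVariant(tx, parseHgvsC(
    "c.592_595delinsCTAACTACATA")), utr3Seq(tx))
  expect_equal(oracle$firstAffected, 199L)
  expect_equal(oracle$terOffset, 3L)
})

test_that("scan agrees with the brute-force translation oracle on random edits", {
  set.seed(101)
  nCases <- 0L
  for (m in 1:6) {
    lens <- sample(80:200, 3L)
    cdsLen <- ((sum(lens) - 30L) %/% 3L) * 3L
    tx <- makeTranscript(lens, cdsStartTx = 7L, cdsLengthNt = cdsLen,
                         seed = 500 + m)
    for (i in 1:60) {
      v <- randomVariant(tx)
      mut <- applyVariant(tx, v)
      cons <- translateAndScan(cdsSeq(tx), mut, v, utr3 = utr3Seq(tx))
      oracle <- bruteScan(cdsSeq(tx), mut, utr3Seq(tx))
      if (!is.na(cons@firstAffectedCodon) && !is.na(oracle$firstAffected))
        expect_equal(cons@firstAffectedCodon, oracle$firstAffected,
                     info = sprintf("model %d case %d (%s)", m, i, formatHgvsC(v)))
      if (!is.na(cons@terOffset)) {
        expect_equal(cons@firstAffectedCodon + cons@terOffset - 1L,
                     oracle$mutStop,
                     info = sprintf("model %d case %d (%s)", m, i, formatHgvsC(v)))
      }
      nCases <- nCases + 1L
    }
  }
  expect_gte(nCases, 360L)
})

test_that("exactly the non-multiples of three shift the frame (lengths 1..12)", {
  tx <- makeTranscript(c(200L, 200L), cdsStartTx = 1L, cdsLengthNt = 390L,
                       seed = 10)
  for (len in 1:12) {
    del <- new("CodingVariant", kind = "deletion", start = 30L,
               end = 30L + len - 1L, raw = "sweep")
    consDel <- translateAndScan(cdsSeq(tx), applyVariant(tx, del), del,
                                utr3 = utr3Seq(tx))
    expect_equal(consDel@netLengthChange, -len)
    expect_equal(consDel@frameOffset, ((-len %% 3L) + 3L) %% 3L)
    expect_identical(consDel@frameOffset != 0L, len %% 3L != 0L)

    ins <- new("CodingVariant", kind = "insertion", start = 30L, end = 31L,
               altSeq = paste(rep("C", len), collapse = ""), raw = "sweep")
    consIns <- translateAndScan(cdsSeq(tx), applyVariant(tx, ins), ins,
                                utr3 = utr3Seq(tx))
    expect_equal(consIns@netLengthChange, len)
    expect_identical(consIns@frameOffset != 0L, len %% 3L != 0L)
  }
})

test_that("codons containing N abort the scan; internal ref stops are caught", {
  v <- new("CodingVariant", kind = "substitution", start = 5L, end = 5L,
           refSeq = "A", altSeq = "T", raw = "x")
  expect_error(translateAndScan("ATGANAGCTTGA", "ATGTNAGCTTGA", v),
               class = "stopfate_scan_aborted")
  expect_error(translateAndScan("ATGTAAAAATGA", "ATGTATAAATGA", v),
               class = "stopfate_validation_error")
})

test_that("plof tags derive from variant type, never from NMD fate", {
  tx <- loadFixture(system.file("extdata", "dmd_like_tx.json",
                                package = "stopfate"))
  nonsense <- variantConsequence(tx, parseHgvsC("c.72G>A"))
  expect_equal(plofTag(nonsense)$tag, "stop_gained")

  btk <- loadFixture(system.file("extdata", "btk_like_tx.json",
                                 package = "stopfate"))
  fs <- variantConsequence(btk, parseHgvsC("c.592_595delinsCTAACTACATA"))
  expect_equal(plofTag(fs)$tag, "frameshift")

  expect_equal(plofTag("essential_splice")$tag, "essential_splice")
  expect_match(plofTag(fs)$caveat, "not of functional effect")
})
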