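btkTx <- loadFixture(system.file("extdata", "btk_like_tx.json",
                                 package = "stopfate"))
dmdTx <- loadFixture(system.file("extdata", "dmd_like_tx.json",
                                 package = "stopfate"))

test_that("TRIGGER emits missing RNA / missing protein and the zero forms", {
  rec <- annotateVariants(btkTx, "c.592_595delinsCTAACTACATA")[[1]]
  expect_equal(rec@nmdFate, "TRIGGER")
  expect_equal(rec@hgvsR, "r.(0)")
  expect_equal(rec@hgvsP, "p.(0)")
  expect_equal(rec@varioRna, "VariO:0245 missing RNA")
  expect_equal(rec@varioProtein, "VariO:0240 missing protein")
  expect_equal(rec@plofTag, "frameshift")
  expect_true(any(grepl("prediction", rec@caveats)))

  asserted <- annotateVariants(btkTx, "c.592_595delinsCTAACTACATA",
                               asserted = TRUE)[[1]]
  expect_equal(asserted@hgvsR, "r.0")
  expect_equal(asserted@hgvsP, "p.0")
})

test_that("ESCAPE emits protein truncation with a Ter-form p. string", {
  # nonsense in the last exon of the BTK-like transcript
  sweep <- ptcSweep(btkTx)
  codons <- attr(sweep, "codon")
  pick <- which(codons > 640L)[1]  # deep in the final exon
  expect_false(is.na(pick))
  rec <- annotateVariants(btkTx, list(sweep[[pick]]))[[1]]
  expect_equal(rec@nmdFate, "ESCAPE")
  expect_equal(rec@varioProtein, "VariO:0015 protein truncation")
  expect_true(is.na(rec@varioRna))
  expect_match(rec@hgvsP, "^p\\.\\([A-Z][a-z]{2}\\d+\\*\\)$")
  expect_match(rec@hgvsR, "^r\\.\\(\\d+[acgu]>[acgu]\\)$")
})

test_that("INTERMEDIATE keeps the truncation form plus the residual-expression caveat", {
  rec <- annotateVariants(dmdTx, "c.72G>A")[[1]]
  expect_equal(rec@nmdFate, "INTERMEDIATE")
  expect_equal(rec@hgvsP, "p.(Trp24*)")
  expect_equal(rec@varioProtein, "VariO:0015 protein truncation")
  expect_true(is.na(rec@varioRna))
  expect_true(any(grepl("partial NMD predicted", rec@caveats)))
})

test_that("non-PTC consequences pass through with standard HGVS and no VariO terms", {
  tx <- makeTranscript(c(150L, 150L), cdsStartTx = 1L, cdsLengthNt = 270L,
                       seed = 31)
  cds <- cdsSeq(tx)
  # find a synonymous third-base change mid-exon
  syn <- NULL
  for (p in seq(75L, 150L, by = 3L)) {
    codon <- substring(cds, p - 2L, p)
    for (alt in setdiff(c("A", "C", "G", "T"), substring(codon, 3, 3))) {
      cand <- paste0(substring(codon, 1, 2), alt)
      if (!(cand %in% c("TAA", "TAG", "TGA")) &&
          Biostrings::GENETIC_CODE[[cand]] == Biostrings::GENETIC_CODE[[codon]]) {
        syn <- sprintf("c.%d%s>%s", p, substring(codon, 3, 3), alt); break
      }
    }
    if (!is.null(syn)) break
  }
  rec <- annotateVariants(tx, syn)[[1]]
  expect_equal(rec@consequenceClass, "synonymous")
  expect_equal(rec@hgvsP, "p.(=)")
  expect_true(is.na(rec@varioRna) && is.na(rec@varioProtein))
  expect_true(is.na(rec@nmdFate))
  expect_equal(rec@plofTag, "none")
})

test_that("a verdict without a PTC (or vice versa) is rejected", {
  consNoPtc <- new("MrnaConsequence", consequenceClass = "synonymous",
                   netLengthChange = 0L, frameOffset = 0L)
  verdict <- classifyNmd(locateCdsPos(btkTx, 592L), 592L, btkTx)
  vv <- new("CodingVariant", kind = "substitution", start = 10L, end = 10L,
            refSeq = "A", altSeq = "G", raw = "c.10A>G")
  expect_error(emitAnnotation(consNoPtc, verdict, btkTx, vv),
               class = "stopfate_validation_error")
})

test_that("no record ever carries both missing-protein and truncation terms", {
  sweep <- ptcSweep(btkTx)
  recs <- annotateVariants(btkTx, sweep[seq(1, length(sweep), by = 7)])
  df <- recordsToDataFrame(recs)
  both <- grepl("VariO:0240", df$vario_protein) &
    grepl("VariO:0015", df$vario_protein)
  expect_equal(sum(both, na.rm = TRUE), 0L)
  withRna <- !is.na(df$vario_rna) & grepl("0245", df$vario_rna)
  expect_false(any(withRna & grepl("0015", df$vario_protein)))
  # every PTC record carries the prediction disclaimer
  expect_true(all(grepl("prediction", df$caveats[!is.na(df$nmd_fate)])))
})

test_that("TSV output uses the fixed column order and round-trips", {
  recs <- annotateVariants(btkTx, c("c.592_595delinsCTAACTACATA", "c.30G>T"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationTsv(recs, path)
  back <- utils::read.delim(path, sep = "\t", comment.char = "",
                            stringsAsFactors = FALSE, na.strings = "")
  expect_equal(colnames(back),
               c("variant", "transcript", "consequence", "nmd_fate", "rules",
                 "vario_rna", "vario_protein", "hgvs_r", "hgvs_p", "plof",
                 "unsense_candidate", "caveats", "error"))
  expect_equal(nrow(back), 2L)
  orig <- recordsToDataFrame(recs)
  blank <- function(x) ifelse(is.na(x), "", x)  # empty cells read back as NA
  expect_equal(back$variant, orig$variant)
  expect_equal(blank(back$hgvs_p), blank(orig$hgvs_p))
  expect_equal(blank(back$caveats), blank(orig$caveats))
})
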