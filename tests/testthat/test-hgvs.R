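test_that("the supported c. kinds parse losslessly", {
  v <- parseHgvsC("c.592_595delinsCTAACTACATA")
  expect_equal(v@kind, "delins")
  expect_equal(c(v@start, v@end), c(592L, 595L))
  expect_equal(v@altSeq, "CTAACTACATA")

  v2 <- parseHgvsC("c.72G>A")
  expect_equal(v2@kind, "substitution")
  expect_equal(v2@start, 72L)
  expect_equal(c(v2@refSeq, v2@altSeq), c("G", "A"))

  v3 <- parseHgvsC("NM_000000.1:c.100_102del")
  expect_equal(v3@kind, "deletion")
  expect_equal(v3@refPrefix, "NM_000000.1")

  expect_equal(parseHgvsC("c.100_101insACT")@altSeq, "ACT")
  expect_equal(parseHgvsC("c.100dup")@kind, "duplication")

  # explicit-reference delins parses to the same variant as the ref-less form
  a <- parseHgvsC("c.592_595delACTAinsCTAACTACATA")
  b <- parseHgvsC("c.592_595delinsCTAACTACATA")
  expect_equal(a@kind, b@kind)
  expect_equal(c(a@start, a@end, a@altSeq), c(b@start, b@end, b@altSeq))
  expect_equal(a@refSeq, "ACTA")
})

test_that("intronic and UTR positions raise the unsupported-region condition", {
  expect_error(parseHgvsC("c.100+2T>C"), class = "stopfate_unsupported_region")
  expect_error(parseHgvsC("c.-14G>A"), class = "stopfate_unsupported_region")
  expect_error(parseHgvsC("c.*6T>A"), class = "stopfate_unsupported_region")
})

test_that("malformed strings raise a parse error carrying an offset", {
  err <- tryCatch(parseHgvsC("c.100_99del"), error = identity)
  expect_s3_class(err, "stopfate_parse_error")
  err2 <- tryCatch(parseHgvsC("c.100X>Y"), error = identity)
  expect_s3_class(err2, "stopfate_parse_error")
  expect_match(conditionMessage(err2), "offset")
  expect_error(parseHgvsC("p.Trp24Ter"), class = "stopfate_parse_error")
  expect_error(parseHgvsC("c.100_102insAAA"), class = "stopfate_parse_error")
})

test_that("parse and format round-trip over all supported kinds", {
  cases <- c("c.72G>A", "c.100del", "c.100_102del", "c.100_102delACT",
             "c.100dup", "c.97_99dup", "c.100_101insACGT",
             "c.592_595delinsCTAACTACATA", "c.50delinsTT")
  for (s in cases) {
    v <- parseHgvsC(s)
    v2 <- parseHgvsC(formatHgvsC(v))
    expect_equal(v2@kind, v@kind, info = s)
    expect_equal(c(v2@start, v2@end), c(v@start, v@end), info = s)
    expect_equal(c(v2@refSeq, v2@altSeq), c(v@refSeq, v@altSeq), info = s)
  }
  # prefix is retained and re-attachable
  v <- parseHgvsC("LRG_199t1:c.72G>A")
  expect_equal(formatHgvsC(v, withPrefix = TRUE), "LRG_199t1:c.72G>A")
})

test_that("r. emission covers the zero and edit forms", {
  expect_equal(formatHgvsR(zero = TRUE), "r.(0)")
  expect_equal(formatHgvsR(zero = TRUE, predicted = FALSE), "r.0")
  expect_equal(formatHgvsR(parseHgvsC("c.72G>A")), "r.(72g>a)")
  expect_equal(formatHgvsR(parseHgvsC("c.592_595delinsCTAACTACATA")),
               "r.(592_595delinscuaacuacaua)")
})

test_that("p. emission covers predicted/asserted and all forms", {
  noProt <- new("ProteinAnnotation", form = "no_protein_predicted")
  expect_equal(formatHgvsP(noProt), "p.(0)")
  noProt@predicted <- FALSE
  expect_equal(formatHgvsP(noProt), "p.0")

  subTer <- new("ProteinAnnotation", form = "substitution_ter",
                firstAffectedCodon = 24L, refResidue = "W",
                predicted = FALSE)
  expect_equal(formatHgvsP(subTer), "p.Trp24*")

  fs <- new("ProteinAnnotation", form = "frameshift_ter",
            firstAffectedCodon = 199L, refResidue = "K", newResidue = "T",
            terOffset = 3L)
  expect_equal(formatHgvsP(fs), "p.(Lys199Thrfs*3)")
  # 1-letter mode never mixes codes within a string
  expect_equal(formatHgvsP(fs, oneLetter = TRUE), "p.(K199Tfs*3)")

  expect_equal(formatHgvsP(new("ProteinAnnotation", form = "unchanged")),
               "p.(=)")
  # inconsistent annotations are rejected
  expect_error(formatHgvsP(new("ProteinAnnotation",
                               form = "no_protein_predicted",
                               firstAffectedCodon = 5L)),
               "residue fields")
})

test_that("variant lists read one-column and transcript-tab-variant forms", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "c.72G>A", "", "TX9\tc.100del"), path)
  vs <- readVariantList(path)
  expect_equal(unname(vs), c("c.72G>A", "c.100del"))
  expect_equal(names(vs)[2], "TX9")
})
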