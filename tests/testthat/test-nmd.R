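test_that("worked-example fates: mid-transcript TRIGGER, last-exon ESCAPE, start-proximal INTERMEDIATE", {
  btk <- loadFixture(system.file("extdata", "btk_like_tx.json",
                                 package = "stopfate"))
  # PTC in exon 8 of 19, short exon, >150 nt from the start codon
  loc <- locateCdsPos(btk, 592L)
  expect_equal(loc$exonRank, 8L)
  v <- classifyNmd(loc, 592L, btk)
  expect_equal(v@fate, "TRIGGER")
  expect_identical(v@rulesFired, "none")

  # any PTC in the final exon escapes
  lastPos <- cdsLength(btk) - 30L
  locL <- locateCdsPos(btk, lastPos)
  expect_true(locL$lastExon)
  vL <- classifyNmd(locL, lastPos, btk)
  expect_equal(vL@fate, "ESCAPE")
  expect_true("last_exon" %in% vL@rulesFired)

  dmd <- loadFixture(system.file("extdata", "dmd_like_tx.json",
                                 package = "stopfate"))
  vD <- classifyNmd(locateCdsPos(dmd, 70L), 70L, dmd)
  expect_equal(vD@fate, "INTERMEDIATE")
  expect_true("start_proximal" %in% vD@rulesFired)
  expect_match(vD@confidenceNote, "may not|escape")
})

test_that("single-exon transcripts escape; verdicts are deterministic", {
  single <- makeTranscript(600L, cdsStartTx = 10L, cdsLengthNt = 501L, seed = 14)
  v <- classifyNmd(locateCdsPos(single, 300L), 300L, single)
  expect_equal(v@fate, "ESCAPE")
  expect_true("single_exon" %in% v@rulesFired)

  v2 <- classifyNmd(locateCdsPos(single, 300L), 300L, single)
  expect_identical(v@fate, v2@fate)
  expect_identical(v@rulesFired, v2@rulesFired)
  expect_identical(v@measurements, v2@measurements)
})

test_that("classifier agrees with the one-expression oracle at every CDS position", {
  cfg <- NmdRuleConfig()
  tx <- makeTranscript(c(90L, 450L, 120L, 80L, 160L), cdsStartTx = 13L,
                       cdsLengthNt = 810L, seed = 15)
  for (p in seq_len(cdsLength(tx))) {
    loc <- locateCdsPos(tx, p)
    got <- classifyNmd(loc, p, tx, cfg)@fate
    want <- nmdOracleFate(nExons(tx), loc$exonRank, loc$distToLastJunction,
                          loc$exonLength, p, cfg)
    expect_identical(got, want, info = sprintf("cds position %d", p))
  }
})

test_that("escape is monotone 3' in the last exon; long exons never upgrade to TRIGGER", {
  tx <- makeTranscript(c(100L, 100L, 300L), cdsStartTx = 1L,
                       cdsLengthNt = 480L, seed = 16)
  lastExonPositions <- 201:477
  fates <- vapply(lastExonPositions, function(p)
    classifyNmd(locateCdsPos(tx, p), p, tx)@fate, character(1))
  expect_true(all(fates == "ESCAPE"))

  # growing the PTC exon past the threshold can only attenuate, never
  # upgrade INTERMEDIATE back to TRIGGER
  tpl <- growableExonTemplate(seed = 17)
  for (L in c(380L, 400L, 401L, 450L)) {
    t <- tpl(L)
    fate <- classifyNmd(locateCdsPos(t$model, t$ptcCdsPos), t$ptcCdsPos,
                        t$model)@fate
    expect_identical(fate, if (L > 400L) "INTERMEDIATE" else "TRIGGER")
  }
})

test_that("boundary sweeps recover the printed rule thresholds", {
  expect_equal(sweepBoundary(threeExonTemplate(seed = 18), "penultimate_50nt"),
               50L)
  expect_equal(sweepBoundary(fiveExonTemplate(seed = 19), "start_proximal"),
               150L)
  expect_equal(sweepBoundary(growableExonTemplate(seed = 21), "long_exon"),
               400L)

  # the flip is sharp: dist 50 escapes, dist 51 does not
  tx <- threeExonTemplate(seed = 18)
  cum <- cumsum(exonLengths(tx))
  pAt <- function(d) cum[2] - d + 1L  # cds position at distance d (CDS starts at 1)
  f50 <- classifyNmd(locateCdsPos(tx, pAt(50L)), pAt(50L), tx)
  f51 <- classifyNmd(locateCdsPos(tx, pAt(51L)), pAt(51L), tx)
  expect_equal(f50@fate, "ESCAPE")
  expect_false("penultimate_50nt" %in% f51@rulesFired)
})

test_that("thresholds are configurable and zero windows remove the escapes", {
  tx <- threeExonTemplate(seed = 22)
  wide <- NmdRuleConfig(penultimateWindowNt = 55L)
  expect_equal(sweepBoundary(tx, "penultimate_50nt", wide), 55L)
  expect_error(sweepBoundary(tx, "penultimate_50nt",
                             NmdRuleConfig(penultimateWindowNt = 0L)),
               class = "stopfate_no_boundary")

  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("penultimate_window_nt: 40", "start_proximal_nt: 100",
               "long_exon_nt: 350"), cfgFile)
  cfg <- readNmdConfig(cfgFile)
  expect_equal(cfg@penultimateWindowNt, 40L)
  expect_equal(cfg@startProximalNt, 100L)
  expect_equal(cfg@longExonNt, 350L)
})

test_that("stop codons straddling an exon junction are assigned to the first-nt exon", {
  tx <- makeTranscript(c(100L, 100L, 100L), cdsStartTx = 1L,
                       cdsLengthNt = 270L, seed = 23)
  # position 99: stop codon would span 99-101, crossing the exon 1|2 junction
  v <- classifyNmd(locateCdsPos(tx, 99L), 99L, tx)
  expect_equal(v@measurements$ptcExonRank, 1L)
  expect_match(v@confidenceNote, "straddles")
})
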