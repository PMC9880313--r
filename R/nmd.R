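#' Construct an NmdRuleConfig
#'
#' @param penultimateWindowNt escape window at the 3' end of the
#'   penultimate exon (nt; default 50).
#' @param startProximalNt start-proximal window measured from the first CDS
#'   nucleotide (nt; default 150).
#' @param longExonNt exon length above which NMD efficiency is reduced
#'   (bp; default 400).
#' @return an [NmdRuleConfig-class].
#' @export
NmdRuleConfig <- function(penultimateWindowNt = 50L, startProximalNt = 150L,
                          longExonNt = 400L) {
  new("NmdRuleConfig",
      penultimateWindowNt = as.integer(penultimateWindowNt),
      startProximalNt = as.integer(startProximalNt),
      longExonNt = as.integer(longExonNt))
}

setMethod("show", "NmdRuleConfig", function(object) {
  cat(sprintf(
    "NmdRuleConfig: penultimate window %d nt, start-proximal %d nt, long exon > %d bp\n",
    object@penultimateWindowNt, object@startProximalNt, object@longExonNt))
})

#' Read NMD rule thresholds from a YAML or JSON config file
#'
#' Keys match the [NmdRuleConfig-class] fields in snake_case
#' (`penultimate_window_nt`, `start_proximal_nt`, `long_exon_nt`);
#' camelCase is accepted too. Missing keys keep their defaults.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return an [NmdRuleConfig-class].
#' @export
readNmdConfig <- function(path) {
  if (!file.exists(path))
    sfStop("stopfate_not_found", "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::fromJSON(path)
    else sfStop("stopfate_parse_error", "config must be YAML or JSON: %s", path)
  pick <- function(snake, camel, default) {
    val <- obj[[snake]] %||% obj[[camel]] %||% default
    as.integer(val)
  }
  NmdRuleConfig(
    penultimateWindowNt = pick("penultimate_window_nt", "penultimateWindowNt", 50L),
    startProximalNt = pick("start_proximal_nt", "startProximalNt", 150L),
    longExonNt = pick("long_exon_nt", "longExonNt", 400L))
}

#' Classify the NMD fate of a premature termination codon
#'
#' Applies the NMD escape and attenuation rules to a located PTC, in a
#' declared precedence: escape rules first (they describe where degradation
#' does not occur, so they dominate efficiency modifiers), then attenuation
#' rules, then the default.
#'
#' \enumerate{
#'   \item single-exon transcript \eqn{\to} ESCAPE (`single_exon`; no
#'     exon-junction complex downstream of any stop);
#'   \item PTC in the last exon \eqn{\to} ESCAPE (`last_exon`);
#'   \item PTC in the penultimate exon with
#'     `distToLastJunction <= penultimateWindowNt` \eqn{\to} ESCAPE
#'     (`penultimate_50nt`, the 50 nt rule);
#'   \item `ptcCdsPos <= startProximalNt` \eqn{\to} INTERMEDIATE
#'     (`start_proximal`; hedged in the literature — "may not cause
#'     degradation" — so it attenuates rather than escapes);
#'   \item PTC-containing exon longer than `longExonNt` \eqn{\to}
#'     INTERMEDIATE (`long_exon`);
#'   \item otherwise TRIGGER (efficient NMD; `rulesFired == "none"`).
#' }
#'
#' All applicable rules of the winning class are listed in `rulesFired`.
#' The 50 nt distance is measured from the first nucleotide of the stop
#' codon to the 3' end of the penultimate exon, inclusive (last exonic nt
#' of the penultimate exon = distance 1). A stop codon straddling an exon
#' junction is assigned to the exon containing its first nucleotide and
#' noted in `confidenceNote`.
#'
#' @param loc an `ExonLocation` from [locateCdsPos()], derived from the
#'   same `model` and `ptcCdsPos`.
#' @param ptcCdsPos 1-based CDS position of the PTC's first nucleotide.
#' @param model the [TranscriptModel-class].
#' @param cfg an [NmdRuleConfig-class].
#' @return an [NmdVerdict-class].
#' @examples
#' tx <- loadFixture(system.file("extdata", "btk_like_tx.json",
#'                               package = "stopfate"))
#' classifyNmd(locateCdsPos(tx, 592L), 592L, tx, NmdRuleConfig())
#' @export
classifyNmd <- function(loc, ptcCdsPos, model, cfg = NmdRuleConfig()) {
  stopifnot(inherits(loc, "ExonLocation"), is(model, "TranscriptModel"),
            is(cfg, "NmdRuleConfig"))
  validObject(cfg)
  ptcCdsPos <- as.integer(ptcCdsPos)
  check <- locateCdsPos(model, ptcCdsPos)
  if (!identical(check$exonRank, loc$exonRank) ||
      !identical(check$offsetInExon, loc$offsetInExon))
    sfStop("stopfate_validation_error",
           "ExonLocation inconsistent with model %s at CDS position %d",
           model@transcriptId, ptcCdsPos)

  n <- nExons(model)
  notes <- character(0)
  escape <- character(0)
  if (loc$singleExon) escape <- c(escape, "single_exon", "last_exon")
  else if (loc$lastExon) escape <- c(escape, "last_exon")
  else if (loc$exonRank == n - 1L && !is.na(loc$distToLastJunction) &&
           loc$distToLastJunction <= cfg@penultimateWindowNt)
    escape <- c(escape, "penultimate_50nt")

  if (loc$offsetInExon + 2L > loc$exonLength && !loc$lastExon)
    notes <- c(notes, paste(
      "stop codon straddles an exon junction; assigned to the exon",
      "containing its first nucleotide"))

  meas <- list(ptcExonRank = loc$exonRank, ptcExonLength = loc$exonLength,
               distToLastJunction = loc$distToLastJunction,
               cdsPosOfPtc = ptcCdsPos)
  modifiersNote <- paste(
    "unquantified NMD modifiers not evaluated: last exon size,",
    "re-initiation of transcription, splice site rescue")

  if (length(escape)) {
    return(new("NmdVerdict", fate = "ESCAPE", rulesFired = escape,
               measurements = meas,
               confidenceNote = paste(c(notes, modifiersNote), collapse = "; ")))
  }
  inter <- character(0)
  if (ptcCdsPos <= cfg@startProximalNt) {
    inter <- c(inter, "start_proximal")
    notes <- c(notes, paste(
      "start-proximal PTC: degradation may not occur; escape via",
      "re-initiation of translation downstream is possible"))
  }
  if (loc$exonLength > cfg@longExonNt) {
    inter <- c(inter, "long_exon")
    notes <- c(notes, sprintf(
      "PTC-containing exon length %d bp exceeds %d bp; NMD efficiency reduced",
      loc$exonLength, cfg@longExonNt))
  }
  if (length(inter)) {
    return(new("NmdVerdict", fate = "INTERMEDIATE", rulesFired = inter,
               measurements = meas,
               confidenceNote = paste(c(notes, modifiersNote), collapse = "; ")))
  }
  new("NmdVerdict", fate = "TRIGGER", rulesFired = "none",
      measurements = meas,
      confidenceNote = paste(notes, collapse = "; "))
}

setMethod("show", "NmdVerdict", function(object) {
  cat(sprintf("NmdVerdict: %s [%s]\n", object@fate,
              paste(object@rulesFired, collapse = ", ")))
  m <- object@measurements
  cat(sprintf("  PTC: CDS nt %s, exon %s (length %s), dist to last junction %s\n",
              as.character(m$cdsPosOfPtc), as.character(m$ptcExonRank),
              as.character(m$ptcExonLength),
              as.character(m$distToLastJunction)))
  if (nzchar(object@confidenceNote))
    cat("  note:", object@confidenceNote, "\n")
})

#' Sweep a rule boundary on a synthetic transcript
#'
#' Validation harness for the rule thresholds. For the position-based rules
#' (`penultimate_50nt`, `start_proximal`) a hypothetical PTC is classified
#' at every CDS position of the template transcript (the classifier needs
#' only the position on the exon scaffold, so every position is reachable —
#' a single-nucleotide nonsense sweep could not place a stop at every
#' coordinate). For `long_exon` the template must be a function
#' `function(exonLengthNt)` returning `list(model=, ptcCdsPos=)`, and the
#' PTC-bearing exon is grown in 1-bp steps around the configured threshold.
#'
#' @param template a [TranscriptModel-class] (position rules) or a
#'   template function (`long_exon`); see [growableExonTemplate()].
#' @param rule one of `"penultimate_50nt"`, `"start_proximal"`,
#'   `"long_exon"`.
#' @param cfg an [NmdRuleConfig-class].
#' @return the empirical boundary: for `penultimate_50nt` the largest
#'   distance to the last junction still classified ESCAPE by that rule;
#'   for `start_proximal` the largest CDS position at which the rule fires;
#'   for `long_exon` the largest exon length at which the rule does NOT
#'   fire. Raises `stopfate_no_boundary` if the rule never fires on the
#'   template.
#' @examples
#' sweepBoundary(threeExonTemplate(seed = 1), "penultimate_50nt")
#' @export
sweepBoundary <- function(template, rule, cfg = NmdRuleConfig()) {
  rule <- match.arg(rule, c("penultimate_50nt", "start_proximal", "long_exon"))

  if (rule == "long_exon") {
    if (!is.function(template))
      sfStop("stopfate_validation_error",
             "long_exon sweep requires a template function(exonLengthNt)")
    lens <- seq.int(max(cfg@longExonNt - 10L, 1L), cfg@longExonNt + 10L)
    fired <- vapply(lens, function(L) {
      tpl <- template(L)
      verdict <- classifyNmd(locateCdsPos(tpl$model, tpl$ptcCdsPos),
                             tpl$ptcCdsPos, tpl$model, cfg)
      "long_exon" %in% verdict@rulesFired
    }, logical(1))
    if (!any(fired))
      sfStop("stopfate_no_boundary", "long_exon rule never fired on template")
    return(max(lens[!fired]))
  }

  stopifnot(is(template, "TranscriptModel"))
  vals <- integer(0)
  for (p in seq_len(cdsLength(template))) {
    loc <- locateCdsPos(template, p)
    verdict <- classifyNmd(loc, p, template, cfg)
    if (rule == "penultimate_50nt") {
      if ("penultimate_50nt" %in% verdict@rulesFired &&
          identical(verdict@fate, "ESCAPE"))
        vals <- c(vals, loc$distToLastJunction)
    } else {
      if ("start_proximal" %in% verdict@rulesFired) vals <- c(vals, p)
    }
  }
  if (!length(vals))
    sfStop("stopfate_no_boundary", "%s rule never fired on template", rule)
  max(vals)
}
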