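#' Screen an apparently-synonymous substitution for unsense candidacy
#'
#' A substitution that is synonymous by the codon table can still destroy a
#' splice site or its exonic regulatory context and thereby change — or
#' abolish — the protein (unsense variation, VariO:0514). No motif models
#' are applied; the only computable signal here is junction proximity, so
#' the screen flags synonymous substitutions whose spliced-mRNA position
#' lies within `windowNt` exonic nucleotides of a splice junction (the
#' junction-adjacent nucleotide counts as distance 1; transcript ends are
#' not junctions). The flag is a candidate label, never a classification.
#'
#' Synonymous substitutions outside the window pass unflagged but carry the
#' caveat that synonymy is a codon-table statement only. Non-substitution
#' input yields a not-applicable result (not an error).
#'
#' @param v a [CodingVariant-class].
#' @param consequence the [MrnaConsequence-class] computed for `v`.
#' @param model the [TranscriptModel-class].
#' @param windowNt exonic window at each junction (default 3 nt).
#' @return a list of class `UnsenseFlag`: `flagged`, `reason`
#'   (`exonic_splice_site_proximal`, `none` or `not_applicable`),
#'   `distToNearestJunction`, `vario` (`"VariO:0514"` when flagged, else
#'   `NA`), `caveat`.
#' @export
screenUnsense <- function(v, consequence, model, windowNt = 3L) {
  stopifnot(is(v, "CodingVariant"), is(consequence, "MrnaConsequence"),
            is(model, "TranscriptModel"))
  windowNt <- as.integer(windowNt)
  if (is.na(windowNt) || windowNt < 1L)
    sfStop("stopfate_domain_error", "windowNt must be >= 1")
  res <- function(flagged, reason, dist, vario = NA_character_,
                  caveat = NA_character_) {
    structure(list(flagged = flagged, reason = reason,
                   distToNearestJunction = dist, vario = vario,
                   caveat = caveat),
              class = "UnsenseFlag")
  }
  if (!identical(v@kind, "substitution") ||
      !identical(consequence@consequenceClass, "synonymous"))
    return(res(FALSE, "not_applicable", NA_integer_))

  loc <- locateCdsPos(model, v@start)
  dists <- integer(0)
  if (loc$exonRank > 1L) dists <- c(dists, loc$offsetInExon)  # 5' junction side
  if (!loc$lastExon) dists <- c(dists, loc$exonLength - loc$offsetInExon + 1L)
  dist <- if (length(dists)) min(dists) else NA_integer_

  if (!is.na(dist) && dist <= windowNt) {
    res(TRUE, "exonic_splice_site_proximal", dist, vario = "VariO:0514",
        caveat = sprintf(paste(
          "candidate unsense variant (VariO:0514): synonymous by codon table",
          "but %d nt from a splice junction; splicing impact not excluded"),
          dist))
  } else {
    res(FALSE, "none", dist,
        caveat = paste(
          "synonymy is a codon-table statement only; effects on splicing,",
          "splicing regulation or miRNA binding are not excluded"))
  }
}

#' @export
print.UnsenseFlag <- function(x, ...) {
  cat(sprintf("UnsenseFlag: %s (%s), dist to nearest junction %s\n",
              if (x$flagged) "FLAGGED" else "not flagged", x$reason,
              as.character(x$distToNearestJunction)))
  invisible(x)
}
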