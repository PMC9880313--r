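#' Parse an HGVS c. expression
#'
#' Parses the coding-DNA subset the annotator operates on: substitution
#' (`c.72G>A`), deletion (`c.100del`, `c.100_102delACT`), duplication,
#' insertion (`c.100_101insACT`) and delins (`c.592_595delinsCTAACTACATA`,
#' including the explicit-reference `delACTAins...` form, which parses to
#' the same [CodingVariant-class]). An optional reference prefix
#' (`NM_...:`, `LRG_...t1:`) is split off and retained.
#'
#' Positions with intronic offsets (`c.100+2T>C`), 5' UTR (`c.-14G>A`) or
#' 3' UTR (`c.*6T>A`) positions are syntactically valid HGVS but outside
#' the coding-region scope; they raise a distinct
#' `stopfate_unsupported_region` condition so callers can report rather
#' than misannotate. Anything else unparseable raises a
#' `stopfate_parse_error` whose message carries the character offset.
#'
#' @param hgvs a single HGVS c. string.
#' @return a [CodingVariant-class].
#' @examples
#' parseHgvsC("c.72G>A")
#' parseHgvsC("c.592_595delinsCTAACTACATA")
#' @export
parseHgvsC <- function(hgvs) {
  stopifnot(is.character(hgvs), length(hgvs) == 1L)
  raw <- hgvs
  s <- trimws(hgvs)
  prefix <- NA_character_
  m <- regexpr("^[A-Za-z][A-Za-z0-9_.()-]*:", s)
  if (m == 1L) {
    prefix <- sub(":$", "", regmatches(s, m))
    s <- substring(s, attr(m, "match.length") + 1L)
  }
  if (!startsWith(s, "c."))
    sfStop("stopfate_parse_error",
           "not a c. expression (offset %d): %s", nchar(raw) - nchar(s) + 1L, raw)
  payload <- substring(s, 3L)
  payloadOffset <- nchar(raw) - nchar(payload)
  if (grepl("[+*]", payload) || grepl("^-", payload) || grepl("_-", payload, fixed = TRUE))
    sfStop("stopfate_unsupported_region",
           "unsupported-region: intronic or UTR position in '%s'", raw)

  mk <- function(kind, start, end, ref = "", alt = "") {
    new("CodingVariant", kind = kind, start = as.integer(start),
        end = as.integer(end), refSeq = ref, altSeq = alt, raw = raw,
        refPrefix = prefix)
  }

  # order matters: delins before del; dup/ins before substitution fallback
  m <- regmatches(payload,
    regexec("^([0-9]+)(?:_([0-9]+))?del([ACGTacgt]*)ins([ACGTacgt]+)$", payload))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    checkSpanOrder(start, end, raw)
    return(mk("delins", start, end, toupper(m[4]), toupper(m[5])))
  }
  m <- regmatches(payload,
    regexec("^([0-9]+)(?:_([0-9]+))?del([ACGTacgt]*)$", payload))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    checkSpanOrder(start, end, raw)
    v <- mk("deletion", start, end, ref = toupper(m[4]))
    if (nzchar(m[4]) && nchar(m[4]) != v@end - v@start + 1L)
      sfStop("stopfate_parse_error",
             "deleted bases (%d) disagree with span %d_%d in '%s'",
             nchar(m[4]), v@start, v@end, raw)
    return(v)
  }
  m <- regmatches(payload,
    regexec("^([0-9]+)(?:_([0-9]+))?dup([ACGTacgt]*)$", payload))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    checkSpanOrder(start, end, raw)
    v <- mk("duplication", start, end, ref = toupper(m[4]))
    if (nzchar(m[4]) && nchar(m[4]) != v@end - v@start + 1L)
      sfStop("stopfate_parse_error",
             "duplicated bases (%d) disagree with span %d_%d in '%s'",
             nchar(m[4]), v@start, v@end, raw)
    return(v)
  }
  m <- regmatches(payload,
    regexec("^([0-9]+)_([0-9]+)ins([ACGTacgt]+)$", payload))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (end != start + 1L)
      sfStop("stopfate_parse_error",
             "insertion must use flanking positions N_N+1 in '%s'", raw)
    return(mk("insertion", start, end, alt = toupper(m[4])))
  }
  m <- regmatches(payload,
    regexec("^([0-9]+)([ACGTacgt])>([ACGTacgt])$", payload))[[1]]
  if (length(m)) {
    p <- as.integer(m[2])
    return(mk("substitution", p, p, toupper(m[3]), toupper(m[4])))
  }
  # report the offset of the first character that breaks the grammar
  lead <- regmatches(payload, regexpr("^[0-9_]*", payload))
  sfStop("stopfate_parse_error",
         "malformed HGVS c. expression at offset %d: %s",
         payloadOffset + nchar(lead) + 1L, raw)
}

checkSpanOrder <- function(start, end, raw) {
  if (start > end)
    sfStop("stopfate_parse_error", "start > end in '%s'", raw)
  invisible(TRUE)
}

#' Format a CodingVariant back to HGVS c. notation
#'
#' Inverse of [parseHgvsC()] over the supported kinds; reference bases are
#' included for del/dup forms when the variant carries them, so
#' `parseHgvsC(formatHgvsC(v))` reproduces `v`.
#'
#' @param v a [CodingVariant-class].
#' @param withPrefix prepend the retained reference prefix, when present.
#' @return an HGVS c. string.
#' @export
formatHgvsC <- function(v, withPrefix = FALSE) {
  stopifnot(is(v, "CodingVariant"))
  span <- if (v@start == v@end) as.character(v@start) else
    sprintf("%d_%d", v@start, v@end)
  body <- switch(v@kind,
    substitution = sprintf("%d%s>%s", v@start, v@refSeq, v@altSeq),
    deletion = sprintf("%sdel%s", span, v@refSeq),
    duplication = sprintf("%sdup%s", span, v@refSeq),
    insertion = sprintf("%d_%dins%s", v@start, v@end, v@altSeq),
    delins = sprintf("%sdel%sins%s", span, v@refSeq, v@altSeq)
  )
  out <- paste0("c.", body)
  if (withPrefix && !is.na(v@refPrefix)) out <- paste0(v@refPrefix, ":", out)
  out
}

setMethod("show", "CodingVariant", function(object) {
  cat(sprintf("CodingVariant: %s [%s %d..%d]\n", formatHgvsC(object),
              object@kind, object@start, object@end))
})

#' Format an RNA-level (r.) HGVS string
#'
#' Two modes. With `zero = TRUE` the no-transcript form is emitted —
#' `"r.(0)"` by default, `"r.0"` when `predicted = FALSE` (i.e. the caller
#' asserts experimental evidence). Otherwise the coding edit is re-expressed
#' at RNA level: lowercase bases with u for t, e.g. `"r.(72g>a)"`.
#'
#' @param v a [CodingVariant-class] (ignored when `zero = TRUE`).
#' @param zero emit the no-transcript form.
#' @param predicted wrap the payload in parentheses (theoretical
#'   construction rather than observed molecule).
#' @return an HGVS r. string.
#' @export
formatHgvsR <- function(v = NULL, zero = FALSE, predicted = TRUE) {
  payload <- if (zero) "0" else {
    stopifnot(is(v, "CodingVariant"))
    body <- sub("^c\\.", "", formatHgvsC(v))
    chartr("ACGT", "acgu", body)
  }
  if (predicted) sprintf("r.(%s)", payload) else paste0("r.", payload)
}

#' Format a protein-level (p.) HGVS string
#'
#' Emits the corrected protein annotation for a [ProteinAnnotation-class]:
#' `p.(0)`/`p.0` for predicted/asserted absence of protein,
#' `p.(Trp24*)` for a stop substitution, `p.(Lys199Thrfs*3)` for a
#' frameshift terminating at offset 3 in the new frame, `p.(=)` for an
#' unchanged protein. The `*` symbol is used for the termination codon
#' (`Ter` accepted on input elsewhere). Three-letter residue codes are the
#' default; `oneLetter = TRUE` switches the whole string — codes are never
#' mixed within one string.
#'
#' @param pa a [ProteinAnnotation-class].
#' @param oneLetter use 1-letter residue codes.
#' @return an HGVS p. string.
#' @export
formatHgvsP <- function(pa, oneLetter = FALSE) {
  stopifnot(is(pa, "ProteinAnnotation"))
  validObject(pa)
  res <- function(aa1) if (oneLetter) aa1 else aa3(aa1)
  payload <- switch(pa@form,
    no_protein_predicted = "0",
    unchanged = "=",
    full_deletion = "0",
    substitution_ter = sprintf("%s%d*", res(pa@refResidue), pa@firstAffectedCodon),
    frameshift_ter = sprintf("%s%d%sfs*%s", res(pa@refResidue),
                             pa@firstAffectedCodon, res(pa@newResidue),
                             if (is.na(pa@terOffset)) "?" else pa@terOffset),
    other = {
      if (is.na(pa@payload))
        sfStop("stopfate_validation_error", "form 'other' requires a payload")
      pa@payload
    }
  )
  if (pa@predicted) sprintf("p.(%s)", payload) else paste0("p.", payload)
}

setMethod("show", "ProteinAnnotation", function(object) {
  cat("ProteinAnnotation:", formatHgvsP(object), "\n")
})

#' Read a plain-text variant list
#'
#' One HGVS c. expression per line; an optional two-column
#' `transcript_id<TAB>hgvs` form is accepted, in which case the transcript
#' column is returned as the names of the vector. Blank lines and `#`
#' comments are skipped.
#'
#' @param path path to the variant list.
#' @return character vector of HGVS strings (possibly named by transcript).
#' @export
readVariantList <- function(path) {
  if (!file.exists(path))
    sfStop("stopfate_not_found", "variant list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hasTab <- grepl("\t", lines, fixed = TRUE)
  out <- character(length(lines))
  nms <- rep(NA_character_, length(lines))
  for (i in seq_along(lines)) {
    if (hasTab[i]) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      nms[i] <- parts[1]
      out[i] <- parts[2]
    } else out[i] <- lines[i]
  }
  if (any(!is.na(nms))) names(out) <- nms
  out
}
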