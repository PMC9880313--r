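# Classed conditions so callers can distinguish "unsupported HGVS region"
# (report, don't misannotate) from genuine malformation or internal errors.

sfCondition <- function(class, message, ...) {
  structure(
    class = c(class, "stopfate_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
}

sfStop <- function(class, fmt, ...) {
  stop(sfCondition(class, sprintf(fmt, ...)))
}

#' Condition classes used by stopfate
#'
#' All errors signalled by the package carry a subclass of
#' \code{stopfate_error} so that callers can react to the kind of failure:
#' \describe{
#'   \item{stopfate_parse_error}{malformed HGVS string (carries the character
#'     offset at which parsing failed)}
#'   \item{stopfate_unsupported_region}{syntactically valid HGVS that refers
#'     to a region outside the supported coding subset (intronic offsets,
#'     5'/3' UTR positions, spans outside the CDS)}
#'   \item{stopfate_validation_error}{an object invariant was violated}
#'   \item{stopfate_refcheck_error}{variant reference bases disagree with the
#'     transcript sequence}
#'   \item{stopfate_domain_error}{argument outside its mathematical domain}
#'   \item{stopfate_not_found}{requested transcript/record absent}
#'   \item{stopfate_scan_aborted}{a codon containing N was met during the
#'     PTC scan; translation outcome would be a guess, so the scan stops}
#'   \item{stopfate_no_boundary}{a rule-boundary sweep in which the rule
#'     never fired}
#' }
#'
#' @name stopfate-conditions
#' @keywords internal
NULL
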