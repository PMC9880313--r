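STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  !grepl("[^ACGT]", names(Biostrings::GENETIC_CODE))], STOP_CODONS)

# 1-letter -> 3-letter amino acid codes (HGVS protein convention)
AA_1TO3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  "*" = "Ter"
)
AA_3TO1 <- stats::setNames(names(AA_1TO3), AA_1TO3)

aa3 <- function(aa1) {
  out <- AA_1TO3[aa1]
  if (anyNA(out)) sfStop("stopfate_domain_error", "unknown amino acid code '%s'", aa1[is.na(out)][1])
  unname(out)
}

# Split a sequence into complete codons (trailing 1-2 nt dropped).
codonSplit <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Codon -> 1-letter aa using the standard genetic code; codon with N -> NA.
translateCodons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

# Run code with a temporary RNG seed, restoring prior RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
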