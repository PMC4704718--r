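#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif binom.test setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Classed condition helper: every parabsa error carries "parabsa_error" plus a
# specific subclass so callers (and tests) can match on the failure kind.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "parabsa_error", "error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# A seed of NA means "use whatever RNG state is current".
with_seed_if <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit signed integer range R requires of set.seed().
child_seed <- function(seed, stream) {
  if (is.null(seed) || is.na(seed)) return(NA_integer_)
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inclusive >= with a small slack so that exact rational boundaries
# (e.g. 14/20 against a threshold of 0.7) are never lost to floating point.
geq <- function(x, threshold, tol = 1e-9) x >= threshold - tol

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[[x]]
}

translate_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random open reading frame of `n_codons` codons (including the stop):
# ATG start, no internal stop codons, TAA end.
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}
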