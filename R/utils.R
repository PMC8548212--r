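#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet
NULL

# reverse complement of a plain character string (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# round half away from zero at `digits` decimals (reproduces printed roundings
# like 3.3333 -> 3.3, 0.25 -> 0.3, independent of banker's rounding)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# random DNA string(s) from the current RNG stream
random_dna <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = rep(0.25, 4)) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# split a sequence into consecutive codons starting at `from` (1-based)
codons_from <- function(seq, from) {
  n <- nchar(seq)
  if (from > n - 2) return(character(0))
  last <- from + ((n - from + 1) %/% 3) * 3 - 1
  substring(seq, seq(from, last - 2, by = 3), seq(from + 2, last, by = 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
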