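#' @useDynLib mosaicamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom runif
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# For each base, the three alternative bases in alphabetical order.
# Row order follows DNA_BASES; used by the simulator's substitution draw.
DNA_ALTERNATIVES <- rbind(
  A = c("C", "G", "T"),
  C = c("A", "G", "T"),
  G = c("A", "C", "T"),
  T = c("A", "C", "G")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

#' Reverse-complement a DNA string vector
#'
#' Thin wrapper around [Biostrings::reverseComplement()] accepting plain
#' character vectors (N allowed).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round a count ratio to a percentage, half-up, in exact arithmetic
#'
#' Computes `100 * count / depth` rounded half-up to `digits` decimals using
#' integer arithmetic, so printed mutation frequencies are reproduced exactly
#' (no binary floating-point tie surprises). Ties (exactly .xx5) round up.
#'
#' @param count Non-negative integer vector (mutant read counts).
#' @param depth Positive integer vector (total depth), recycled.
#' @param digits Decimals to keep (default 2).
#' @return Numeric vector of rounded percentages.
#' @export
round_percent <- function(count, depth, digits = 2) {
  stopifnot(all(depth >= 1), all(count >= 0), all(count <= depth))
  scaled <- count * 100 * 10^digits
  q <- scaled %/% depth
  r <- scaled - q * depth
  (q + as.numeric(2 * r >= depth)) / 10^digits
}
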