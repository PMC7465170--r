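#' @importFrom rlang .data abort `%||%`
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_int pmap imap
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' `N` is its own complement.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate/normalize a nucleotide string; non-ACGTN characters are rejected so
# downstream alignment behaviour is deterministic.
check_seq <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single string", what))
  }
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s}",
                  what, if (allow_n) ",N" else ""))
  }
  x
}

# round-half-up: deterministic "nearest integer" used for cluster positions
round_half_up <- function(x) floor(x + 0.5)

# 0-based substring extraction: [start, end) half-open; vectorized over
# any argument (substring(), unlike substr(), recycles to the longest)
substr0 <- function(x, start, end) substring(x, start + 1L, end)
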