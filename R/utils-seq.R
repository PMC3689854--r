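# Sequence-level helpers shared across modules. Internal alphabet is RNA
# ({A,C,G,U}); DNA input is normalized on the way in, and converters back to
# DNA are provided at the I/O boundary.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and converts T to U. Characters outside A/C/G/U/N raise an
#' error.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
normalize_seq <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U,T,N}: ",
         x[which(bad)[1L]])
  }
  out
}

#' Convert internal RNA sequences to DNA
#' @param x character vector over \{A,C,G,U\}.
#' @return character vector over \{A,C,G,T\}.
#' @export
rna_to_dna <- function(x) chartr("U", "T", x)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Watson-Crick complement (RNA)
WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement (RNA alphabet)
#' @param x character vector of sequences over \{A,C,G,U\}.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chars_to_seq(rev(unname(WC_PARTNER[seq_chars(s)])))
  }, character(1L), USE.NAMES = FALSE)
}

# TRUE for Watson-Crick pairs, G:U wobble, or either (used by the aligner and
# the encoder; both must agree on what counts as pairing).
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

is_wobble_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

is_complementary <- function(a, b) is_wc_pair(a, b) | is_wobble_pair(a, b)

random_seq <- function(len) {
  chars_to_seq(sample(RNA_BASES, len, replace = TRUE))
}
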