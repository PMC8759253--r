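# Internal sequence helpers. All internal comparison is on the DNA alphabet
# (U canonicalized to T at parse time).

#' Canonicalize nucleotide sequences
#'
#' Uppercases and converts U to T so that RNA and DNA input compare on a
#' single alphabet. `N` is retained.
#'
#' @param x character vector of sequences.
#' @return character vector on the `{A,C,G,T,N}` alphabet.
#' @export
canonicalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (canonical alphabet).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Integer-encode a sequence: A=0 C=1 G=2 T=3, anything else (N) = 4.
encode_seq <- function(s) {
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L
  m - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
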