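# Low-level sequence helpers shared across modules. Sequences are plain
# character strings over A/C/G/T (N allowed only in raw reads); positions are
# 1-based throughout.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Single strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    abort("hamming() requires equal-length strings")
  }
  sum(ca != cb)
}

# Encode equal-length sequences as an n x L integer matrix (A=1,C=2,G=3,T=4).
# Other characters (e.g. N) become NA.
encode_seqs <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("sequences must all have the same length")
  }
  matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), the_bases),
         nrow = length(seqs), ncol = lens[[1]], byrow = TRUE)
}

decode_seqs <- function(m) {
  apply(m, 1L, function(row) paste(the_bases[row], collapse = ""))
}

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string", name))
  }
}
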