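# Integer encodings of an msa for the compiled kernels.
#
# "mi"  alphabet: 1..20 amino acids, 0 for gap and 'X' (excluded from counts).
# "dca" alphabet: 1..20 amino acids, 21 for gap; 'X' maps to the gap state so
#        it carries no information (q = 21, gap explicit).
# "identity" alphabet: 1..20 amino acids, 0 for gap, -1 for 'X' (non-gap in
#        the identity denominator but never matching).

#' Encode an msa as an integer state matrix
#'
#' @param x An `msa`.
#' @param alphabet `"mi"` (20 states, gap/unknown = 0), `"dca"`
#'   (21 states, gap = 21, unknown treated as gap) or `"identity"`
#'   (gap = 0, unknown = -1).
#' @return Integer matrix, records x columns.
#' @keywords internal
#' @export
encode_msa <- function(x, alphabet = c("mi", "dca", "identity")) {
  alphabet <- match.arg(alphabet)
  code <- match(x$seqs, AA20)
  enc <- matrix(code, nrow = nrow(x$seqs))
  if (alphabet == "mi") {
    enc[is.na(enc)] <- 0L
  } else if (alphabet == "dca") {
    enc[is.na(enc)] <- 21L
  } else {
    enc[is.na(enc) & x$seqs == "-"] <- 0L
    enc[is.na(enc)] <- -1L
  }
  storage.mode(enc) <- "integer"
  enc
}

#' Number of states of an encoding
#' @keywords internal
#' @noRd
encoding_q <- function(alphabet) if (alphabet == "mi") 20L else 21L
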