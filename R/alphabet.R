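#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in the fixed published order
#' `"ACDEFGHIKLMNPQRSTVWY"`, followed by `"X"` for unknown residues.
#' All encoders, checkpoints and reports use this ordering, so saved
#' models are portable across sessions.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
}

# 20 standard letters (no X)
aa_standard <- function() aa_alphabet()[1:20]

# residue letter -> index 1..20, X/unknown -> 0 (shared padding/unknown token)
aa_index_map <- function() {
  m <- stats::setNames(seq_len(20), aa_standard())
  c(m, X = 0L)
}
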