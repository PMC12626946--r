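#' Encode padded chains as one-hot vectors
#'
#' Each real residue becomes a 21-dimensional binary vector over the fixed
#' alphabet [aa_alphabet()] (20 standard amino acids, then `"X"` as its own
#' 21st category). Padded positions are all-zero vectors with mask 0.
#'
#' @param chains List of `padded_chain` objects sharing one padded length.
#' @return An `encoded_batch` with fields `encoding = "onehot"`,
#'   `x` (array `n x L x 21`), `mask` and `labels` (matrices `n x L`),
#'   `n`, `L`, `d`.
#' @export
encode_one_hot <- function(chains) {
  info <- batch_info(chains)
  d <- 21L
  x <- array(0, dim = c(info$n, info$L, d))
  alpha <- aa_alphabet()
  for (b in seq_len(info$n)) {
    ch <- chains[[b]]$chain
    letters_b <- strsplit(ch$sequence, "")[[1]]
    j <- match(letters_b, alpha)
    if (anyNA(j)) stop("character outside alphabet in complex '", ch$complex_id, "'")
    x[cbind(b, seq_along(j), j)] <- 1
  }
  structure(list(encoding = "onehot", x = x, idx = NULL,
                 mask = info$mask, labels = info$labels,
                 n = info$n, L = info$L, d = d),
            class = "encoded_batch")
}

#' Encode padded chains as integer indices
#'
#' The 20 standard amino acids map to indices 1-20 in alphabet order;
#' index 0 is the shared token for padding and unknown (`"X"`) residues.
#'
#' @inheritParams encode_one_hot
#' @return An `encoded_batch` with `encoding = "embedding"` and an integer
#'   index matrix `idx` (`n x L`, values 0-20) in place of `x`.
#' @export
encode_indices <- function(chains) {
  info <- batch_info(chains)
  idx <- matrix(0L, info$n, info$L)
  imap <- aa_index_map()
  for (b in seq_len(info$n)) {
    ch <- chains[[b]]$chain
    letters_b <- strsplit(ch$sequence, "")[[1]]
    v <- imap[letters_b]
    if (anyNA(v)) stop("character outside alphabet in complex '", ch$complex_id, "'")
    idx[b, seq_along(v)] <- as.integer(v)
  }
  structure(list(encoding = "embedding", x = NULL, idx = idx,
                 mask = info$mask, labels = info$labels,
                 n = info$n, L = info$L, d = 21L),
            class = "encoded_batch")
}

# shared mask/label assembly and padded-length check
batch_info <- function(chains) {
  stopifnot(is.list(chains), length(chains) > 0L)
  lapply(chains, function(pc) stopifnot(inherits(pc, "padded_chain")))
  Ls <- vapply(chains, `[[`, integer(1), "padded_length")
  if (length(unique(Ls)) != 1L) stop("all padded chains must share one padded_length")
  n <- length(chains); L <- Ls[1]
  mask <- do.call(rbind, lapply(chains, `[[`, "mask"))
  labels <- do.call(rbind, lapply(chains, `[[`, "padded_labels"))
  list(n = n, L = L, mask = mask, labels = labels)
}

#' Decode integer indices back to residue letters
#'
#' Inverse of [encode_indices()] for indices 1-20; index 0 decodes to `"X"`
#' (the shared padding/unknown token).
#'
#' @param idx Integer vector or matrix with values in 0-20.
#' @return Character vector/matrix of residue letters.
#' @export
decode_indices <- function(idx) {
  if (any(idx < 0 | idx > 20)) stop("indices must be in [0, 20]")
  out <- c("X", aa_standard())[as.integer(idx) + 1L]
  if (is.matrix(idx)) out <- matrix(out, nrow(idx), ncol(idx))
  out
}

# encode a list of padded chains under a named scheme
encode_batch <- function(chains, encoding = c("onehot", "embedding")) {
  encoding <- match.arg(encoding)
  if (encoding == "onehot") encode_one_hot(chains) else encode_indices(chains)
}

# subset an encoded batch by example index (used for minibatching)
subset_batch <- function(batch, rows) {
  out <- batch
  if (!is.null(batch$x)) out$x <- batch$x[rows, , , drop = FALSE]
  if (!is.null(batch$idx)) out$idx <- batch$idx[rows, , drop = FALSE]
  out$mask <- batch$mask[rows, , drop = FALSE]
  out$labels <- batch$labels[rows, , drop = FALSE]
  out$n <- length(rows)
  out
}
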