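# shared fixtures built in code

# minimal 2-complex TSV on disk; returns the path
write_tiny_tsv <- function(path = tempfile(fileext = ".tsv")) {
  tab <- data.frame(
    complex_id = c("X1", "X1", "X2", "X2"),
    chain_type = c("H", "L", "H", "L"),
    sequence = c("ACDE", "WYKL", "MNPQ", "RSTV"),
    labels = c("0100", "1000", "0011", "0000"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small random labeled chain with at least one positive and one negative
random_chain <- function(id, type = "H", len = 12L) {
  seqs <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                       replace = TRUE), collapse = "")
  labs <- integer(len)
  labs[sample.int(len, max(1L, len %/% 5L))] <- 1L
  labeled_chain(id, type, seqs, labs)
}

# tiny deterministic model for forward/backward tests
tiny_config <- function(encoding = "embedding", L = 6L, H = 2L, k = 3L,
                        C = 2L, dropout = 0, seed = 3L) {
  model_config(encoding = encoding, hidden_size = H, kernel_sizes = k,
               conv_channels = C, dropout_p = dropout, padded_length = L,
               seed = seed)
}

tiny_batch <- function(encoding = "embedding", L = 6L) {
  ch1 <- labeled_chain("c1", "H", "ACDYW", "01100")
  ch2 <- labeled_chain("c2", "H", "WYSN", "1010")
  pads <- lapply(list(ch1, ch2), pad_and_mask, padded_length = L)
  encode_batch(pads, encoding)
}

# brute-force reference convolution: nested loops, zero same-padding
oracle_conv1d <- function(x, w, bias = 0, relu = FALSE) {
  L <- nrow(x); k <- dim(w)[1]; Cin <- dim(w)[2]; Cout <- dim(w)[3]
  pl <- (k - 1L) %/% 2L
  bias <- rep_len(bias, Cout)
  out <- matrix(0, L, Cout)
  for (t in seq_len(L)) {
    for (co in seq_len(Cout)) {
      acc <- bias[co]
      for (j in seq_len(k)) {
        src <- t + j - 1L - pl
        if (src >= 1L && src <= L) {
          for (ci in seq_len(Cin)) acc <- acc + x[src, ci] * w[j, ci, co]
        }
      }
      out[t, co] <- if (relu) max(0, acc) else acc
    }
  }
  out
}

# brute-force reference metric panel from the confusion formulas
oracle_panel <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  acc <- (tp + tn) / (tp + fp + fn + tn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  bac <- (rec + spec) / 2
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(precision = prec, recall = rec, f1 = f1, accuracy = acc, bac = bac, mcc = mcc)
}

# exhaustive pair-counting ROC AUC (ties get half credit)
oracle_roc_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
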