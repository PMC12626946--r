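# Low-level network primitives.
#
# Internal activation layout: a sequence batch of B examples with padded
# length L and C features is a (B*L) x C matrix whose row for example b at
# position t is  r = b + (t-1)*B  (examples fastest). This matches R's
# column-major flattening of a B x L x C array, so matrix(x, B*L, C) and
# array(m, c(B, L, C)) convert without copying logic.

sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout; mask is pre-scaled by 1/(1-p) so eval needs no rescale
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  keep <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(keep) <- dim(x)
  list(out = x * keep, mask = keep)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# ---- LSTM (one direction) ---------------------------------------------------
# par: Wx (d x 4H), Wh (H x 4H), b (4H). Gate column blocks: i, f, g, o.

lstm_forward <- function(X, B, L, par, reverse = FALSE) {
  H <- nrow(par$Wh)
  Hs <- matrix(0, B * L, H)
  Gates <- matrix(0, B * L, 4L * H)
  Cs <- matrix(0, B * L, H)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  bmat <- matrix(par$b, nrow = B, ncol = 4L * H, byrow = TRUE)
  i_cols <- seq_len(H); f_cols <- H + i_cols; g_cols <- 2L * H + i_cols; o_cols <- 3L * H + i_cols
  ts <- if (reverse) rev(seq_len(L)) else seq_len(L)
  for (t in ts) {
    r <- (t - 1L) * B + seq_len(B)
    G <- X[r, , drop = FALSE] %*% par$Wx + h %*% par$Wh + bmat
    gi <- sigmoid(G[, i_cols, drop = FALSE])
    gf <- sigmoid(G[, f_cols, drop = FALSE])
    gg <- tanh(G[, g_cols, drop = FALSE])
    go <- sigmoid(G[, o_cols, drop = FALSE])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    Gates[r, ] <- cbind(gi, gf, gg, go)
    Cs[r, ] <- cc
    Hs[r, ] <- h
  }
  list(H = Hs, Gates = Gates, Cs = Cs)
}

lstm_backward <- function(X, B, L, par, cache, dH, reverse = FALSE) {
  H <- nrow(par$Wh)
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- matrix(0, nrow(X), ncol(X))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  i_cols <- seq_len(H); f_cols <- H + i_cols; g_cols <- 2L * H + i_cols; o_cols <- 3L * H + i_cols
  # walk positions in the reverse of the processing order
  ts <- if (reverse) seq_len(L) else rev(seq_len(L))
  for (t in ts) {
    r <- (t - 1L) * B + seq_len(B)
    gi <- cache$Gates[r, i_cols, drop = FALSE]
    gf <- cache$Gates[r, f_cols, drop = FALSE]
    gg <- cache$Gates[r, g_cols, drop = FALSE]
    go <- cache$Gates[r, o_cols, drop = FALSE]
    c_t <- cache$Cs[r, , drop = FALSE]
    first_step <- if (reverse) t == L else t == 1L
    if (first_step) {
      c_prev <- matrix(0, B, H); h_prev <- matrix(0, B, H)
    } else {
      tp <- if (reverse) t + 1L else t - 1L
      rp <- (tp - 1L) * B + seq_len(B)
      c_prev <- cache$Cs[rp, , drop = FALSE]
      h_prev <- cache$H[rp, , drop = FALSE]
    }
    tanh_c <- tanh(c_t)
    dh <- dH[r, , drop = FALSE] + dh_next
    dgo <- dh * tanh_c
    dc <- dh * go * (1 - tanh_c^2) + dc_next
    dgi <- dc * gg
    dgf <- dc * c_prev
    dgg <- dc * gi
    dc_next <- dc * gf
    dG <- cbind(dgi * gi * (1 - gi), dgf * gf * (1 - gf),
                dgg * (1 - gg^2), dgo * go * (1 - go))
    dWx <- dWx + crossprod(X[r, , drop = FALSE], dG)
    dWh <- dWh + crossprod(h_prev, dG)
    db <- db + colSums(dG)
    dX[r, ] <- dG %*% t(par$Wx)
    dh_next <- dG %*% t(par$Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- 1D convolution, same padding ------------------------------------------
# W: array (k, Cin, Cout); pad left floor((k-1)/2), right ceil((k-1)/2).

conv_pad_left <- function(k) (k - 1L) %/% 2L

conv1d_forward <- function(X, B, L, W, b) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  if (k > L) stop("kernel size ", k, " exceeds sequence length ", L)
  pl <- conv_pad_left(k)
  Xpad <- matrix(0, B * (L + k - 1L), Cin)
  Xpad[pl * B + seq_len(B * L), ] <- X
  Z <- matrix(b, B * L, Cout, byrow = TRUE)
  for (j in seq_len(k)) {
    Wj <- matrix(W[j, , ], Cin, Cout)
    Z <- Z + Xpad[(j - 1L) * B + seq_len(B * L), , drop = FALSE] %*% Wj
  }
  list(Z = Z, Xpad = Xpad)
}

conv1d_backward <- function(Xpad, B, L, W, dZ) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  pl <- conv_pad_left(k)
  dW <- array(0, dim = dim(W))
  dXpad <- matrix(0, nrow(Xpad), Cin)
  rows0 <- seq_len(B * L)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * B + rows0
    Xj <- Xpad[rows, , drop = FALSE]
    dW[j, , ] <- crossprod(Xj, dZ)
    Wj <- matrix(W[j, , ], Cin, Cout)
    dXpad[rows, ] <- dXpad[rows, , drop = FALSE] + dZ %*% t(Wj)
  }
  list(dX = dXpad[pl * B + rows0, , drop = FALSE],
       dW = dW, db = colSums(dZ))
}

#' Length-preserving 1D convolution over a single sequence
#'
#' Convolves per-position feature vectors with `same` zero padding so the
#' output has the input length: for kernel size `k`, `floor((k-1)/2)` zeros
#' are prepended and `ceil((k-1)/2)` appended. No pooling is applied, so
#' per-residue resolution is preserved.
#'
#' @param x Numeric matrix `L x Cin` (a plain vector is treated as
#'   `L x 1`).
#' @param w Kernel array `k x Cin x Cout` (a plain vector of length `k` is
#'   treated as `k x 1 x 1`).
#' @param bias Numeric vector of length `Cout` (recycled scalar allowed).
#' @param activation `"none"` or `"relu"` (`max(0, z)` elementwise).
#' @return Numeric matrix `L x Cout` of convolved features.
#' @export
#' @examples
#' conv1d_same(c(1, 2, 3, 4), c(1, 1, 1))  # sliding window sums: 3 6 9 7
conv1d_same <- function(x, w, bias = 0, activation = c("none", "relu")) {
  activation <- match.arg(activation)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(w))) w <- array(w, dim = c(length(w), 1L, 1L))
  stopifnot(length(dim(w)) == 3L, dim(w)[2] == ncol(x))
  k <- dim(w)[1]
  if (k < 1L) stop("kernel size must be >= 1")
  if (k > nrow(x)) stop("kernel size ", k, " exceeds sequence length ", nrow(x))
  bias <- rep_len(bias, dim(w)[3])
  Z <- conv1d_forward(x, B = 1L, L = nrow(x), W = w, b = bias)$Z
  if (activation == "relu") Z <- pmax(Z, 0)
  Z
}

relu_forward <- function(z) pmax(z, 0)
relu_backward <- function(dout, z) dout * (z > 0)
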