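#' Model hyperparameter configuration
#'
#' Defines the BiLSTM-CNN architecture: residue encoding, LSTM hidden size
#' per direction, one or more length-preserving convolution kernel sizes
#' with their channel count, dropout probability (applied after the
#' embedding, after the BiLSTM and after the convolution, training mode
#' only), padded input length and initialization seed.
#'
#' @param encoding `"onehot"` (21-dim binary vectors) or `"embedding"`
#'   (learnable 21-dim vectors over integer indices).
#' @param hidden_size LSTM hidden size per direction (contextual vectors
#'   have dimension `2 * hidden_size`).
#' @param kernel_sizes Integer vector of convolution kernel sizes; with
#'   several sizes the feature maps are concatenated channel-wise before
#'   the dense head. A kernel equal to `padded_length` spans the whole
#'   padded sequence ("full-length" receptive field).
#' @param conv_channels Output channels per kernel size.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param padded_length Fixed input length all chains are padded to.
#' @param embed_dim Embedding dimension (embedding encoding only).
#' @param seed Integer seed for parameter initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(encoding = c("onehot", "embedding"),
                         hidden_size = 64L,
                         kernel_sizes = 31L,
                         conv_channels = 64L,
                         dropout_p = 0.3,
                         padded_length = 130L,
                         embed_dim = 21L,
                         seed = 1L) {
  encoding <- match.arg(encoding)
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(kernel_sizes) < 1L || any(kernel_sizes < 1L) ||
      any(kernel_sizes > padded_length)) {
    stop("every kernel size must satisfy 1 <= k <= padded_length (", padded_length, ")")
  }
  if (hidden_size < 1L) stop("hidden_size must be >= 1")
  if (conv_channels < 1L) stop("conv_channels must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  structure(list(encoding = encoding, hidden_size = as.integer(hidden_size),
                 kernel_sizes = kernel_sizes, conv_channels = as.integer(conv_channels),
                 dropout_p = dropout_p, padded_length = as.integer(padded_length),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "model_config")
}

# uniform(-s, s) init helper
runif_mat <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)

# random orthogonal H x H matrix (QR of a Gaussian, sign-corrected)
orthogonal_mat <- function(H) {
  qr_ <- qr(matrix(stats::rnorm(H * H), H, H))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), H)
}

#' Initialize model parameters
#'
#' Deterministic given `config$seed`: two calls with the same seed produce
#' bit-identical parameters. LSTM weights are uniform in
#' `(-1/sqrt(H), 1/sqrt(H))`; convolution and dense weights uniform in
#' `(-1/sqrt(fan_in), 1/sqrt(fan_in))`; embeddings standard normal.
#'
#' @param config A [model_config()].
#' @return A `model_state` with the parameter list, parameter count and the
#'   alphabet ordering the model was built for.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  H <- config$hidden_size
  d <- if (config$encoding == "embedding") config$embed_dim else 21L
  params <- list()
  if (config$encoding == "embedding") {
    # row 1 = token 0 (padding/unknown), rows 2..21 = the 20 amino acids
    params$emb <- matrix(stats::rnorm(21L * d), 21L, d)
  }
  s <- 1 / sqrt(H)
  for (dir in c("lf", "lb")) {
    params[[paste0(dir, "_Wx")]] <- runif_mat(d, 4L * H, s)
    # orthogonal recurrent blocks (one per gate) stabilize long-range dynamics
    params[[paste0(dir, "_Wh")]] <- do.call(cbind, lapply(1:4, function(g) orthogonal_mat(H)))
    b <- stats::runif(4L * H, -s, s)
    b[H + seq_len(H)] <- 1  # forget-gate bias at 1 eases long-range memory
    params[[paste0(dir, "_b")]] <- b
  }
  Cin <- 2L * H
  for (i in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[i]
    sc <- 1 / sqrt(k * Cin)
    params[[paste0("conv", i, "_W")]] <-
      array(stats::runif(k * Cin * config$conv_channels, -sc, sc),
            dim = c(k, Cin, config$conv_channels))
    params[[paste0("conv", i, "_b")]] <- stats::runif(config$conv_channels, -sc, sc)
  }
  Ctot <- config$conv_channels * length(config$kernel_sizes)
  sd_ <- 1 / sqrt(Ctot)
  params$dense_W <- runif_mat(Ctot, 1L, sd_)
  params$dense_b <- stats::runif(1L, -sd_, sd_)
  state <- structure(list(config = config, params = params,
                          alphabet = aa_alphabet(),
                          n_params = sum(vapply(params, length, integer(1)))),
                     class = "model_state")
  state
}

#' @export
print.model_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<model_state> %s encoding, H=%d/dir, kernels {%s} x %d channels, %s parameters\n",
              cfg$encoding, cfg$hidden_size,
              paste(cfg$kernel_sizes, collapse = ","), cfg$conv_channels,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# flatten the encoded input of a batch to the internal (B*L) x d matrix
input_matrix <- function(state, batch) {
  cfg <- state$config
  if (batch$encoding != cfg$encoding) {
    stop("batch encoding '", batch$encoding, "' does not match model encoding '",
         cfg$encoding, "'")
  }
  if (batch$L != cfg$padded_length) {
    stop("batch padded length ", batch$L, " != model padded_length ", cfg$padded_length)
  }
  B <- batch$n; L <- batch$L
  if (cfg$encoding == "onehot") {
    matrix(batch$x, B * L, batch$d)
  } else {
    state$params$emb[as.vector(batch$idx) + 1L, , drop = FALSE]
  }
}

# full forward pass; keep_cache retains intermediates for backprop
model_forward <- function(state, batch, training = FALSE, keep_cache = FALSE) {
  cfg <- state$config
  p <- state$params
  B <- batch$n; L <- cfg$padded_length; H <- cfg$hidden_size
  X0 <- input_matrix(state, batch)
  # input-site dropout regularizes the learnable embedding; one-hot inputs
  # carry bare residue identity, which dropout would simply delete
  d1 <- dropout_forward(X0, if (cfg$encoding == "embedding") cfg$dropout_p else 0,
                        training)
  fwd <- lstm_forward(d1$out, B, L, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                      reverse = FALSE)
  bwd <- lstm_forward(d1$out, B, L, list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b),
                      reverse = TRUE)
  Hseq <- cbind(fwd$H, bwd$H)                      # h_t = fwd (+) bwd, dim 2H
  d2 <- dropout_forward(Hseq, cfg$dropout_p, training)
  convs <- vector("list", length(cfg$kernel_sizes))
  Zs <- vector("list", length(cfg$kernel_sizes))
  for (i in seq_along(cfg$kernel_sizes)) {
    cv <- conv1d_forward(d2$out, B, L, p[[paste0("conv", i, "_W")]],
                         p[[paste0("conv", i, "_b")]])
    convs[[i]] <- cv
    Zs[[i]] <- relu_forward(cv$Z)
  }
  Zcat <- do.call(cbind, Zs)                       # concat feature maps over kernels
  d3 <- dropout_forward(Zcat, cfg$dropout_p, training)
  logits <- drop(d3$out %*% p$dense_W) + p$dense_b
  probs <- sigmoid(logits)
  out <- list(probs = matrix(probs, B, L), logits = matrix(logits, B, L),
              B = B, L = L)
  if (keep_cache) {
    out$cache <- list(X0 = X0, d1 = d1, fwd = fwd, bwd = bwd,
                      Hseq = Hseq, d2 = d2, convs = convs, Zs = Zs,
                      Zcat = Zcat, d3 = d3, logits = logits)
  }
  out
}

# backward pass from d(loss)/d(logits) (a B x L matrix or B*L vector);
# returns gradients named like state$params
model_backward <- function(state, batch, cache, dlogits) {
  cfg <- state$config
  p <- state$params
  B <- batch$n; L <- cfg$padded_length; H <- cfg$hidden_size
  dlog <- matrix(as.vector(dlogits), B * L, 1L)
  grads <- list()
  grads$dense_W <- crossprod(cache$d3$out, dlog)
  grads$dense_b <- sum(dlog)
  dZcat <- dlog %*% t(p$dense_W)
  dZcat <- dropout_backward(dZcat, cache$d3$mask)
  C <- cfg$conv_channels
  dHd <- matrix(0, B * L, 2L * H)
  for (i in seq_along(cfg$kernel_sizes)) {
    cols <- (i - 1L) * C + seq_len(C)
    dZ <- relu_backward(dZcat[, cols, drop = FALSE], cache$convs[[i]]$Z)
    cb <- conv1d_backward(cache$convs[[i]]$Xpad, B, L,
                          p[[paste0("conv", i, "_W")]], dZ)
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    grads[[paste0("conv", i, "_b")]] <- cb$db
    dHd <- dHd + cb$dX
  }
  dHseq <- dropout_backward(dHd, cache$d2$mask)
  lb_f <- lstm_backward(cache$d1$out, B, L,
                        list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                        cache$fwd, dHseq[, seq_len(H), drop = FALSE], reverse = FALSE)
  lb_b <- lstm_backward(cache$d1$out, B, L,
                        list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b),
                        cache$bwd, dHseq[, H + seq_len(H), drop = FALSE], reverse = TRUE)
  grads$lf_Wx <- lb_f$dWx; grads$lf_Wh <- lb_f$dWh; grads$lf_b <- lb_f$db
  grads$lb_Wx <- lb_b$dWx; grads$lb_Wh <- lb_b$dWh; grads$lb_b <- lb_b$db
  dX0 <- dropout_backward(lb_f$dX + lb_b$dX, cache$d1$mask)
  if (cfg$encoding == "embedding") {
    v <- as.vector(batch$idx)
    g <- rowsum(dX0, group = v)
    demb <- matrix(0, 21L, cfg$embed_dim)
    demb[as.integer(rownames(g)) + 1L, ] <- g
    grads$emb <- demb
  }
  grads[names(state$params)]
}

#' BiLSTM contextualization of an encoded batch
#'
#' Runs the (optionally dropout-regularized) bidirectional LSTM and returns
#' the per-position contextual vectors `h_t`, the concatenation of the
#' forward and backward hidden states (dimension `2 * hidden_size`, i.e.
#' 128 at the default hidden size of 64 per direction).
#'
#' @param state A `model_state` from [init_model()].
#' @param batch An `encoded_batch` matching the model's encoding.
#' @param training If `TRUE`, dropout is applied to the input encoding;
#'   in eval mode the output is deterministic.
#' @return Numeric array `n x L x 2H` of contextual vectors.
#' @export
bilstm_contextualize <- function(state, batch, training = FALSE) {
  cfg <- state$config
  B <- batch$n; L <- cfg$padded_length; H <- cfg$hidden_size
  X0 <- input_matrix(state, batch)
  d1 <- dropout_forward(X0, if (cfg$encoding == "embedding") cfg$dropout_p else 0,
                        training)
  p <- state$params
  fwd <- lstm_forward(d1$out, B, L, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b), FALSE)
  bwd <- lstm_forward(d1$out, B, L, list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b), TRUE)
  array(cbind(fwd$H, bwd$H), dim = c(B, L, 2L * H))
}

#' Per-residue binding probabilities for an encoded batch
#'
#' Full forward pass: encoding -> dropout -> BiLSTM -> dropout ->
#' length-preserving 1D convolution with ReLU (feature maps concatenated
#' over kernel sizes) -> dropout -> per-position dense layer -> sigmoid.
#' Probabilities are produced at every padded position; padding is excluded
#' downstream via the mask, never by truncation here.
#'
#' @inheritParams bilstm_contextualize
#' @param training If `TRUE` the three dropout sites are active (training
#'   mode); eval mode is deterministic.
#' @return List with `probs` and `logits` (`n x L` matrices).
#' @export
predict_residues <- function(state, batch, training = FALSE) {
  out <- model_forward(state, batch, training = training, keep_cache = FALSE)
  list(probs = out$probs, logits = out$logits)
}

#' Predict binding probabilities for labeled chains
#'
#' Convenience wrapper: pads and encodes `chains` per the model config,
#' runs the model in eval mode and strips padding.
#'
#' @param state A trained `model_state`.
#' @param chains List of `labeled_chain` objects.
#' @param batch_size Chains per forward batch.
#' @return List (one element per chain) of numeric probability vectors of
#'   the chain's real length.
#' @export
predict_chains <- function(state, chains, batch_size = 64L) {
  cfg <- state$config
  padded <- lapply(chains, pad_and_mask, padded_length = cfg$padded_length)
  out <- vector("list", length(chains))
  idx_sets <- split(seq_along(chains),
                    ceiling(seq_along(chains) / batch_size))
  for (rows in idx_sets) {
    batch <- encode_batch(padded[rows], cfg$encoding)
    pr <- model_forward(state, batch, training = FALSE)$probs
    for (j in seq_along(rows)) {
      n <- chain_length(chains[[rows[j]]])
      out[[rows[j]]] <- pr[j, seq_len(n)]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing container holding the format
#' version, package version, [model_config()], all parameters and the
#' alphabet ordering; loading reproduces eval-mode outputs bit-exactly on
#' the saving platform.
#'
#' @param state A `model_state`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the restored
#'   `model_state` (`load_checkpoint`).
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  obj <- list(format_version = 1L,
              package_version = as.character(utils::packageVersion("paratopeR")),
              config = state$config, params = state$params,
              alphabet = state$alphabet, n_params = state$n_params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unrecognized checkpoint format in ", path)
  }
  if (!identical(obj$alphabet, aa_alphabet())) {
    stop("checkpoint alphabet ordering differs from this package's alphabet")
  }
  structure(list(config = obj$config, params = obj$params,
                 alphabet = obj$alphabet, n_params = obj$n_params),
            class = "model_state")
}
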