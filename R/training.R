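#' Class-weight specification from a training set
#'
#' The positive-class weight is the non-binding to binding residue ratio
#' `w+ = N_neg / N_pos`, counted over the real (unpadded) residues of the
#' training portion only; the negative weight is 1. Recomputed per
#' training split, so it adapts to each fold and chain regime.
#'
#' @param chains List of `padded_chain` objects (the training portion).
#' @return A `loss_spec` list with `w_plus`, `w_minus`, `epsilon`.
#' @export
compute_class_weight <- function(chains) {
  lapply(chains, function(pc) stopifnot(inherits(pc, "padded_chain")))
  labs <- unlist(lapply(chains, function(pc) pc$chain$labels))
  n_pos <- sum(labs == 1L)
  n_neg <- sum(labs == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate training set: need at least one positive and one negative residue")
  }
  loss_spec(w_plus = n_neg / n_pos)
}

#' @rdname compute_class_weight
#' @param w_plus Positive-class weight (> 0).
#' @param w_minus Negative-class weight (default 1).
#' @param epsilon Clamp for log arguments.
#' @export
loss_spec <- function(w_plus, w_minus = 1, epsilon = 1e-7) {
  stopifnot(w_plus > 0, w_minus > 0, epsilon > 0, epsilon < 0.5)
  structure(list(w_plus = w_plus, w_minus = w_minus, epsilon = epsilon),
            class = "loss_spec")
}

#' Masked, class-weighted binary cross-entropy
#'
#' `loss = -sum_t m_t [ w+ y*_t log p_t + w- (1 - y*_t) log(1 - p_t) ] / n`,
#' where `m_t` is the padding mask and `n = sum(m_t)` is the number of real
#' residues, so the reported value is the mean masked loss (batch-size
#' invariant; normalization does not change the optimum). Log arguments
#' are clamped at `spec$epsilon`. Labels at masked positions never
#' contribute.
#'
#' @param probs,labels,mask Conforming numeric vectors/matrices;
#'   `probs` in `[0, 1]`, `labels` and `mask` binary.
#' @param spec A [loss_spec()].
#' @return Scalar loss.
#' @export
masked_weighted_bce <- function(probs, labels, mask, spec) {
  stopifnot(inherits(spec, "loss_spec"))
  p <- as.vector(probs); y <- as.vector(labels); m <- as.vector(mask)
  if (length(p) != length(y) || length(p) != length(m)) stop("shape mismatch")
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  n <- sum(m)
  if (n == 0) stop("all positions are masked; no real residues to score")
  pc <- pmin(pmax(p, spec$epsilon), 1 - spec$epsilon)
  -sum(m * (spec$w_plus * y * log(pc) + spec$w_minus * (1 - y) * log(1 - pc))) / n
}

# d(loss)/d(logits) for the mean masked weighted BCE (p = sigmoid(logit))
bce_dlogits <- function(probs, labels, mask, spec) {
  p <- as.vector(probs); y <- as.vector(labels); m <- as.vector(mask)
  n <- sum(m)
  (m / n) * (spec$w_minus * (1 - y) * p - spec$w_plus * y * (1 - p))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early stopping patience: training stops when the
#'   monitored quantity fails to improve for this many consecutive epochs.
#' @param batch_size Chains per minibatch.
#' @param early_stop_monitor `"val_mcc_max"` (default; maximize validation
#'   MCC) or `"val_loss_min"` (minimize validation loss).
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 100L,
                         patience = 5L, batch_size = 16L,
                         early_stop_monitor = c("val_mcc_max", "val_loss_min"),
                         seed = 1L) {
  early_stop_monitor <- match.arg(early_stop_monitor)
  stopifnot(learning_rate > 0, patience >= 1L, max_epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch_size = as.integer(batch_size),
                 early_stop_monitor = early_stop_monitor, seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- early stopping ---------------------------------------------------------
# pure tracker: maximize = TRUE for MCC-style monitors
early_stop_tracker <- function(patience, maximize) {
  list(best = if (maximize) -Inf else Inf, best_epoch = 0L, wait = 0L,
       stop = FALSE, patience = as.integer(patience), maximize = maximize)
}

early_stop_update <- function(tracker, value, epoch) {
  improved <- if (tracker$maximize) value > tracker$best else value < tracker$best
  if (improved) {
    tracker$best <- value
    tracker$best_epoch <- epoch
    tracker$wait <- 0L
  } else {
    tracker$wait <- tracker$wait + 1L
    if (tracker$wait >= tracker$patience) tracker$stop <- TRUE
  }
  tracker
}

# ---- training runner --------------------------------------------------------

#' Train a BiLSTM-CNN paratope model
#'
#' Minimizes the mean masked, class-weighted binary cross-entropy with
#' Adam. After each epoch the model is evaluated on the validation chains
#' (eval mode, threshold 0.5); training stops when the monitored quantity
#' (validation MCC by default) fails to improve for `patience` consecutive
#' epochs or `max_epochs` is reached, and the parameters from the best
#' epoch are restored. Fully seeded: identical seeds and data reproduce
#' identical histories.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param train_chains,val_chains Lists of `labeled_chain`; their complex
#'   id sets must be disjoint (leakage guard).
#' @param verbose Print one line per epoch.
#' @return List with `state` (parameters from the best epoch), `history`
#'   (one row per epoch: losses, validation panel), `best_epoch`,
#'   `stop_reason` and `loss_spec`.
#' @export
train_model <- function(model_cfg, train_cfg, train_chains, val_chains,
                        verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"), inherits(train_cfg, "train_config"))
  if (length(train_chains) == 0L || length(val_chains) == 0L) {
    stop("train and validation chain sets must be non-empty")
  }
  tr_ids <- vapply(train_chains, `[[`, character(1), "complex_id")
  va_ids <- vapply(val_chains, `[[`, character(1), "complex_id")
  overlap <- intersect(tr_ids, va_ids)
  if (length(overlap)) {
    stop("complex id(s) on both the training and validation side: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  L <- model_cfg$padded_length
  tr_pad <- lapply(train_chains, pad_and_mask, padded_length = L)
  va_pad <- lapply(val_chains, pad_and_mask, padded_length = L)
  spec <- compute_class_weight(tr_pad)
  tr_all <- encode_batch(tr_pad, model_cfg$encoding)
  va_all <- encode_batch(va_pad, model_cfg$encoding)

  state <- init_model(model_cfg)
  opt <- adam_init(state$params)
  set.seed(train_cfg$seed)
  maximize <- train_cfg$early_stop_monitor == "val_mcc_max"
  tracker <- early_stop_tracker(train_cfg$patience, maximize)
  best_params <- state$params
  history <- list()
  n_tr <- length(tr_pad)
  stop_reason <- "max_epochs"
  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample.int(n_tr)
    batch_starts <- seq(1L, n_tr, by = train_cfg$batch_size)
    ep_loss <- 0; ep_n <- 0
    for (s in batch_starts) {
      rows <- perm[s:min(s + train_cfg$batch_size - 1L, n_tr)]
      batch <- subset_batch(tr_all, rows)
      fw <- model_forward(state, batch, training = TRUE, keep_cache = TRUE)
      loss <- masked_weighted_bce(fw$probs, batch$labels, batch$mask, spec)
      dlog <- bce_dlogits(fw$probs, batch$labels, batch$mask, spec)
      grads <- model_backward(state, batch, fw$cache, dlog)
      upd <- adam_step(state$params, grads, opt, train_cfg$learning_rate)
      state$params <- upd$params
      opt <- upd$opt
      nb <- sum(batch$mask)
      ep_loss <- ep_loss + loss * nb
      ep_n <- ep_n + nb
    }
    val <- evaluate_batch(state, va_all, spec)
    monitor_value <- if (maximize) val$panel[["mcc"]] else val$loss
    tracker <- early_stop_update(tracker, monitor_value, epoch)
    if (tracker$best_epoch == epoch) best_params <- state$params
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val$loss,
      val_accuracy = val$panel[["accuracy"]], val_precision = val$panel[["precision"]],
      val_recall = val$panel[["recall"]], val_f1 = val$panel[["f1"]],
      val_bac = val$panel[["bac"]], val_mcc = val$panel[["mcc"]],
      improved = tracker$best_epoch == epoch
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val MCC %.4f%s",
                      epoch, ep_loss / ep_n, val$loss, val$panel[["mcc"]],
                      if (tracker$best_epoch == epoch) " *" else ""))
    }
    if (tracker$stop) { stop_reason <- "early_stop"; break }
  }
  state$params <- best_params
  list(state = state, history = do.call(rbind, history),
       best_epoch = tracker$best_epoch, stop_reason = stop_reason,
       loss_spec = spec)
}

# eval-mode loss + threshold-0.5 panel on a pre-encoded batch
evaluate_batch <- function(state, batch, spec, threshold = 0.5,
                           batch_size = 64L) {
  n <- batch$n
  probs <- matrix(0, n, batch$L)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    probs[rows, ] <- model_forward(state, subset_batch(batch, rows),
                                   training = FALSE)$probs
  }
  loss <- masked_weighted_bce(probs, batch$labels, batch$mask, spec)
  counts <- confusion_at_threshold(probs, batch$labels, batch$mask, threshold)
  list(loss = loss, panel = metric_panel(counts), probs = probs)
}

#' Enumerate or run the encoding x regime x kernel configuration sweep
#'
#' The default grid is 2 encodings x 3 chain regimes x 5 kernel sizes =
#' 30 configurations; with a k-fold plan every configuration trains once
#' per fold (150 fold-runs at defaults). Results are aggregated per
#' configuration as mean and sample standard deviation of the validation
#' panel over folds and ranked by mean MCC.
#'
#' @param data A `labeled_dataset` (the modeling set).
#' @param plan A `split_plan` over `data`.
#' @param encodings,regimes,kernel_sizes Grid axes.
#' @param model_cfg_base Base [model_config()] whose encoding/kernels are
#'   overridden per grid cell.
#' @param train_cfg A [train_config()].
#' @param dry_run If `TRUE`, only instantiate the grid and report planned
#'   run counts without training.
#' @param verbose Progress messages.
#' @return For `dry_run`, a list with `grid`, `n_configurations`,
#'   `n_fold_runs`. Otherwise a data.frame, one row per configuration,
#'   with per-metric `mean_*` / `sd_*` columns, ranked by `mean_mcc`.
#' @export
run_configuration_sweep <- function(data, plan,
                                    encodings = c("onehot", "embedding"),
                                    regimes = c("H", "L", "HL"),
                                    kernel_sizes = c(7L, 15L, 31L, 71L, 130L),
                                    model_cfg_base = model_config(),
                                    train_cfg = train_config(),
                                    dry_run = FALSE, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  grid <- expand.grid(encoding = encodings, regime = regimes,
                      kernel_size = kernel_sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$config_id <- sprintf("%s_%s_k%d", grid$encoding, grid$regime,
                            grid$kernel_size)
  k <- length(plan$folds)
  if (dry_run) {
    return(list(grid = grid, n_configurations = nrow(grid),
                n_fold_runs = nrow(grid) * k))
  }
  metrics <- c("accuracy", "precision", "recall", "f1", "bac", "mcc")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- model_cfg_base
    cfg$encoding <- grid$encoding[i]
    cfg$kernel_sizes <- grid$kernel_size[i]
    fold_panels <- matrix(NA_real_, k, length(metrics),
                          dimnames = list(NULL, metrics))
    for (f in seq_len(k)) {
      ids <- fold_ids(plan, f)
      tr <- select_chain_regime(subset_dataset(data, ids$train), grid$regime[i])
      va <- select_chain_regime(subset_dataset(data, ids$val), grid$regime[i])
      fit <- train_model(cfg, train_cfg, tr, va)
      best <- fit$history[fit$history$epoch == fit$best_epoch, ]
      fold_panels[f, ] <- c(best$val_accuracy, best$val_precision,
                            best$val_recall, best$val_f1, best$val_bac,
                            best$val_mcc)
      if (verbose) {
        message(sprintf("[%s] fold %d/%d: MCC %.3f", grid$config_id[i], f, k,
                        best$val_mcc))
      }
    }
    stats_row <- c(as.list(grid[i, c("config_id", "encoding", "regime", "kernel_size")]),
                   stats::setNames(as.list(colMeans(fold_panels)),
                                   paste0("mean_", metrics)),
                   stats::setNames(as.list(apply(fold_panels, 2, stats::sd)),
                                   paste0("sd_", metrics)))
    rows[[i]] <- as.data.frame(stats_row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_mcc), ]
  rownames(out) <- NULL
  out
}
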