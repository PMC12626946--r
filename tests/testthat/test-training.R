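test_that("class weight is the negative/positive ratio over unpadded residues", {
  ch <- labeled_chain("W1", "H", "ACDEFGHIKL", "1100000000")
  spec <- compute_class_weight(list(pad_and_mask(ch, 12L)))
  expect_equal(spec$w_plus, 4.0)   # 8 negatives / 2 positives
  expect_equal(spec$w_minus, 1)
  balanced <- labeled_chain("W2", "H", "ACDE", "1100")
  expect_equal(compute_class_weight(list(pad_and_mask(balanced, 4L)))$w_plus, 1.0)
  allpos <- labeled_chain("W3", "H", "ACDE", "1111")
  expect_error(compute_class_weight(list(pad_and_mask(allpos, 6L))), "degenerate")
})

test_that("masked weighted BCE matches closed forms and ignores masked labels", {
  spec <- loss_spec(w_plus = 1)
  # p = 0.5 everywhere with unit weights: mean loss is log 2
  expect_equal(masked_weighted_bce(rep(0.5, 8), rep(c(0, 1), 4), rep(1, 8), spec),
               log(2))
  # near-perfect predictions: loss collapses to the clamp floor
  expect_lt(masked_weighted_bce(c(1, 0), c(1, 0), c(1, 1), spec), 1e-6)
  # flipping labels at masked positions leaves the loss unchanged
  p <- c(0.8, 0.3, 0.6, 0.2)
  m <- c(1, 1, 0, 0)
  spec2 <- loss_spec(w_plus = 5)
  l1 <- masked_weighted_bce(p, c(1, 0, 0, 0), m, spec2)
  l2 <- masked_weighted_bce(p, c(1, 0, 1, 1), m, spec2)
  expect_identical(l1, l2)
  expect_error(masked_weighted_bce(p, c(1, 0, 0, 0), c(0, 0, 0, 0), spec), "masked")
  expect_error(masked_weighted_bce(c(1.2, 0), c(1, 0), c(1, 1), spec), "\\[0, 1\\]")
})

test_that("analytic gradients match finite differences on a tiny model", {
  for (enc in c("embedding", "onehot")) {
    cfg <- tiny_config(encoding = enc, L = 6L, H = 2L, k = 3L, C = 2L,
                       dropout = 0, seed = 31L)
    state <- init_model(cfg)
    batch <- tiny_batch(enc)
    spec <- loss_spec(w_plus = 3)
    loss_at <- function(st) {
      fw <- model_forward(st, batch, training = FALSE)
      masked_weighted_bce(fw$probs, batch$labels, batch$mask, spec)
    }
    fw <- model_forward(state, batch, training = TRUE, keep_cache = TRUE)
    dlog <- bce_dlogits(fw$probs, batch$labels, batch$mask, spec)
    grads <- model_backward(state, batch, fw$cache, dlog)
    eps <- 1e-5
    set.seed(99)
    for (nm in names(state$params)) {
      idx <- sample.int(length(state$params[[nm]]),
                        min(10L, length(state$params[[nm]])))
      for (i in idx) {
        up <- state; up$params[[nm]][i] <- up$params[[nm]][i] + eps
        dn <- state; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s gradient [%s, %d]", enc, nm, i))
      }
    }
  }
})

test_that("early stopping tracker obeys patience counter semantics", {
  # monitor improves through epoch 3, then never again: with patience 5 the
  # run stops after epoch 8 with best epoch 3
  tr <- early_stop_tracker(patience = 5L, maximize = TRUE)
  values <- c(0.1, 0.2, 0.3, 0.3, 0.29, 0.3, 0.25, 0.3, 0.3, 0.3)
  stopped_at <- NA_integer_
  for (e in seq_along(values)) {
    tr <- early_stop_update(tr, values[e], e)
    if (tr$stop) { stopped_at <- e; break }
  }
  expect_identical(stopped_at, 8L)
  expect_identical(tr$best_epoch, 3L)
  # minimizing monitor
  tr2 <- early_stop_tracker(patience = 2L, maximize = FALSE)
  for (e in 1:4) tr2 <- early_stop_update(tr2, c(1.0, 0.5, 0.6, 0.7)[e], e)
  expect_true(tr2$stop)
  expect_identical(tr2$best_epoch, 2L)
})

test_that("training is deterministic, restores the best epoch, and guards leakage", {
  set.seed(71)
  tr_chains <- lapply(1:12, function(i) random_chain(sprintf("TR%02d", i), "H", 14L))
  va_chains <- lapply(1:4, function(i) random_chain(sprintf("VA%02d", i), "H", 14L))
  cfg <- model_config(encoding = "onehot", hidden_size = 4L, kernel_sizes = 3L,
                      conv_channels = 4L, dropout_p = 0.1, padded_length = 16L,
                      seed = 5L)
  tcfg <- train_config(max_epochs = 4L, patience = 2L, batch_size = 4L, seed = 5L)
  f1 <- train_model(cfg, tcfg, tr_chains, va_chains)
  f2 <- train_model(cfg, tcfg, tr_chains, va_chains)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$state$params, f2$state$params)
  expect_identical(f1$best_epoch,
                   f1$history$epoch[which.max(f1$history$val_mcc)])
  # early stopping never trains past best_epoch + patience
  expect_lte(nrow(f1$history), f1$best_epoch + tcfg$patience)
  # leakage guard: shared complex id across sides
  expect_error(train_model(cfg, tcfg, tr_chains, tr_chains[1]), "both")
  expect_error(train_model(cfg, tcfg, list(), va_chains), "non-empty")
})

test_that("raising the positive weight does not lower training-set recall (trend over seeds)", {
  rec <- matrix(NA_real_, 2, 3)
  for (s in 1:3) {
    set.seed(300 + s)
    chains <- lapply(1:16, function(i) random_chain(sprintf("RW%02d_%d", i, s), "H", 14L))
    cfg <- model_config(encoding = "onehot", hidden_size = 4L, kernel_sizes = 3L,
                        conv_channels = 4L, dropout_p = 0, padded_length = 16L,
                        seed = s)
    pads <- lapply(chains, pad_and_mask, padded_length = 16L)
    batch <- encode_batch(pads, "onehot")
    for (wi in 1:2) {
      w <- c(1, 20)[wi]
      state <- init_model(cfg)
      opt <- adam_init(state$params)
      spec <- loss_spec(w_plus = w)
      set.seed(s)
      for (step in 1:25) {
        fw <- model_forward(state, batch, training = TRUE, keep_cache = TRUE)
        dlog <- bce_dlogits(fw$probs, batch$labels, batch$mask, spec)
        grads <- model_backward(state, batch, fw$cache, dlog)
        upd <- adam_step(state$params, grads, opt, 0.01)
        state$params <- upd$params; opt <- upd$opt
      }
      fw <- model_forward(state, batch, training = FALSE)
      panel <- metric_panel(confusion_at_threshold(fw$probs, batch$labels, batch$mask))
      rec[wi, s] <- panel[["recall"]]
    }
  }
  expect_gte(mean(rec[2, ]), mean(rec[1, ]))
})

test_that("the sweep grid instantiates every encoding x regime x kernel cell", {
  ds <- generate_dataset(generator_spec(12, seed = 3))
  plan <- make_folds(ds, k = 3L, seed = 3L)
  dry <- run_configuration_sweep(ds, plan, dry_run = TRUE)
  expect_identical(dry$n_configurations, 30L)
  expect_identical(dry$n_fold_runs, 90L)
  expect_identical(sort(unique(dry$grid$kernel_size)), c(7L, 15L, 31L, 71L, 130L))
  expect_identical(anyDuplicated(dry$grid$config_id), 0L)
})

test_that("a reduced sweep trains per fold and reports mean and spread", {
  ds <- generate_dataset(generator_spec(9, seed = 4))
  plan <- make_folds(ds, k = 3L, seed = 4L)
  res <- run_configuration_sweep(
    ds, plan, encodings = "onehot", regimes = "H", kernel_sizes = 7L,
    model_cfg_base = model_config(hidden_size = 4L, conv_channels = 4L,
                                  dropout_p = 0.1, seed = 2L),
    train_cfg = train_config(max_epochs = 2L, patience = 1L, batch_size = 4L,
                             seed = 2L))
  expect_identical(nrow(res), 1L)
  expect_identical(res$config_id, "onehot_H_k7")
  expect_gte(res$sd_mcc, 0)
  expect_true(res$mean_mcc >= -1 && res$mean_mcc <= 1)
})
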