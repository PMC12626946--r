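test_that("initialization is deterministic given the seed and counts parameters", {
  cfg <- model_config(encoding = "onehot", seed = 9L)
  s1 <- init_model(cfg)
  s2 <- init_model(cfg)
  expect_identical(s1$params, s2$params)
  s3 <- init_model(model_config(encoding = "onehot", seed = 10L))
  expect_false(identical(s1$params, s3$params))
  # default-scale configuration stays far under ten million parameters
  big <- init_model(model_config(encoding = "embedding", kernel_sizes = 130L))
  expect_lt(big$n_params, 1e7)
  expect_identical(s1$n_params, sum(vapply(s1$params, length, integer(1))))
  expect_error(model_config(kernel_sizes = 0L), "kernel")
  expect_error(model_config(kernel_sizes = 131L), "kernel")
  expect_error(model_config(dropout_p = 1), "dropout_p")
})

test_that("conv1d_same matches the stated sliding-window examples", {
  expect_equal(drop(conv1d_same(c(1, 2, 3, 4), c(1, 1, 1))), c(3, 6, 9, 7))
  # kernel size 1 with unit weight is the identity
  expect_equal(drop(conv1d_same(c(-2, 5, 0.5), 1)), c(-2, 5, 0.5))
  # ReLU clips negatives
  out <- conv1d_same(c(-1, -2, 3), c(1, 1, 1), activation = "relu")
  expect_true(all(out >= 0))
  expect_error(conv1d_same(c(1, 2), c(1, 1, 1)), "exceeds")
})

test_that("conv1d_same agrees with a nested-loop oracle on random instances", {
  set.seed(42)
  for (i in 1:100) {
    L <- sample(3:8, 1); Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    k <- sample(seq_len(L), 1)
    x <- matrix(rnorm(L * Cin), L, Cin)
    w <- array(rnorm(k * Cin * Cout), dim = c(k, Cin, Cout))
    b <- rnorm(Cout)
    expect_equal(conv1d_same(x, w, b), oracle_conv1d(x, w, b), tolerance = 1e-6)
    expect_equal(conv1d_same(x, w, b, activation = "relu"),
                 oracle_conv1d(x, w, b, relu = TRUE), tolerance = 1e-6)
  }
})

test_that("contextual vectors have dimension 2H and eval mode is deterministic", {
  cfg <- model_config(encoding = "onehot", seed = 2L)
  state <- init_model(cfg)
  ch <- lapply(1:3, function(i) pad_and_mask(random_chain(paste0("B", i), "H", 120L), 130L))
  batch <- encode_batch(ch, "onehot")
  h1 <- bilstm_contextualize(state, batch, training = FALSE)
  expect_identical(dim(h1), c(3L, 130L, 128L))
  h2 <- bilstm_contextualize(state, batch, training = FALSE)
  expect_identical(h1, h2)
})

test_that("reversing the input and swapping directional parameters reverses the output", {
  cfg <- tiny_config(encoding = "onehot", L = 5L, H = 2L, k = 1L)
  state <- init_model(cfg)
  ch <- labeled_chain("r1", "H", "ACDWY", "00000")
  rev_ch <- labeled_chain("r1", "H", "YWDCA", "00000")
  b1 <- encode_batch(list(pad_and_mask(ch, 5L)), "onehot")
  b2 <- encode_batch(list(pad_and_mask(rev_ch, 5L)), "onehot")
  swapped <- state
  swapped$params[c("lf_Wx", "lf_Wh", "lf_b", "lb_Wx", "lb_Wh", "lb_b")] <-
    state$params[c("lb_Wx", "lb_Wh", "lb_b", "lf_Wx", "lf_Wh", "lf_b")]
  h_fwd <- bilstm_contextualize(state, b1)
  h_rev <- bilstm_contextualize(swapped, b2)
  # position-reversed, half-swapped equality
  H <- cfg$hidden_size
  for (t in 1:5) {
    expect_equal(h_fwd[1, t, 1:H], h_rev[1, 6 - t, H + 1:H], tolerance = 1e-12)
    expect_equal(h_fwd[1, t, H + 1:H], h_rev[1, 6 - t, 1:H], tolerance = 1e-12)
  }
})

test_that("full forward pass yields probabilities in (0,1) matching the sigmoid of logits", {
  state <- init_model(tiny_config(encoding = "embedding"))
  batch <- tiny_batch("embedding")
  out <- predict_residues(state, batch)
  expect_identical(dim(out$probs), c(2L, 6L))
  expect_true(all(out$probs > 0 & out$probs < 1))
  expect_equal(out$probs, 1 / (1 + exp(-out$logits)))
  # probability strictly increasing in logit
  o <- order(out$logits)
  expect_true(all(diff(out$probs[o]) >= 0))
})

test_that("with dropout 0 the training and eval forward passes coincide", {
  state <- init_model(tiny_config(encoding = "onehot", dropout = 0))
  batch <- tiny_batch("onehot")
  a <- predict_residues(state, batch, training = TRUE)
  b <- predict_residues(state, batch, training = FALSE)
  expect_identical(a$probs, b$probs)
})

test_that("a single kernel equals the degenerate multi-kernel concatenation", {
  c1 <- tiny_config(encoding = "onehot", L = 6L, k = 3L)
  c2 <- c1
  c2$kernel_sizes <- c(3L)
  s1 <- init_model(c1)
  s2 <- init_model(c2)
  expect_identical(predict_residues(s1, tiny_batch("onehot"))$probs,
                   predict_residues(s2, tiny_batch("onehot"))$probs)
})

test_that("permuting the batch permutes outputs identically (no cross-example leakage)", {
  state <- init_model(tiny_config(encoding = "embedding"))
  ch <- lapply(1:4, function(i) pad_and_mask(random_chain(paste0("perm", i), "H", 5L), 6L))
  full <- encode_batch(ch, "embedding")
  perm <- c(3L, 1L, 4L, 2L)
  out_full <- predict_residues(state, full)$probs
  out_perm <- predict_residues(state, subset_batch(full, perm))$probs
  expect_equal(out_perm, out_full[perm, ], tolerance = 1e-12)
})

test_that("checkpoints round-trip eval-mode predictions bit-exactly", {
  state <- init_model(tiny_config(encoding = "embedding"))
  batch <- tiny_batch("embedding")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(state, path)
  back <- load_checkpoint(path)
  expect_identical(predict_residues(back, batch)$probs,
                   predict_residues(state, batch)$probs)
  expect_identical(back$config$kernel_sizes, state$config$kernel_sizes)
})

test_that("encoding and length mismatches between model and batch are rejected", {
  state <- init_model(tiny_config(encoding = "onehot"))
  expect_error(predict_residues(state, tiny_batch("embedding")), "encoding")
  long_batch <- encode_batch(list(pad_and_mask(random_chain("LL", "H", 5L), 8L)), "onehot")
  expect_error(predict_residues(state, long_batch), "padded length")
})
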