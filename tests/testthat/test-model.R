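test_that("embedding is a word+position lookup with range checks", {
  model <- tiny_transformer()
  # zero tables -> zero output
  m0 <- model
  m0$params$word[] <- 0; m0$params$pos[] <- 0
  expect_true(all(embed_sentence(rep(0L, 6), m0) == 0))
  # one-hot word rows, zero positions -> row i selects word row ids[i]
  m1 <- model
  m1$params$word <- diag(10)[, seq_len(8)] * 0
  m1$params$word <- matrix(0, 10, 8)
  m1$params$word[cbind(1:10, rep(1:8, length.out = 10))] <- 1:10
  m1$params$pos[] <- 0
  ids <- c(0L, 3L, 9L, 1L, 1L, 7L)
  X <- embed_sentence(ids, m1)
  expect_equal(X, m1$params$word[ids + 1L, ])
  # out-of-range id names the position
  expect_error(embed_sentence(c(0L, 99L, 0L, 0L, 0L, 0L), model),
               "position 2")
})

test_that("attention: L=1 passthrough, zero-QK uniformity, row sums", {
  m <- tiny_transformer(L = 1L)
  X <- matrix(rnorm(8), 1, 8)
  res <- multi_head_attention(X, m, return_attention = TRUE)
  for (k in seq_along(res$attention)) {
    expect_equal(res$attention[[k]], matrix(1, 1, 1))
    # Z_i = V exactly when alpha = [[1]]
    V <- X %*% m$params$Wv[, , k]
    expect_equal(res$Z[, (k - 1) * 4 + 1:4, drop = FALSE], V)
  }

  # Q = K = 0 -> uniform attention, Z_i rows = column means of V
  m2 <- tiny_transformer()
  m2$params$Wq[] <- 0; m2$params$Wk[] <- 0
  X2 <- matrix(rnorm(48), 6, 8)
  r2 <- multi_head_attention(X2, m2, return_attention = TRUE)
  for (k in 1:2) {
    expect_equal(r2$attention[[k]], matrix(1 / 6, 6, 6))
    V <- X2 %*% m2$params$Wv[, , k]
    expect_equal(r2$Z[, (k - 1) * 4 + 1:4],
                 matrix(colMeans(V), 6, 4, byrow = TRUE))
  }

  # random inputs: rows sum to 1 within 1e-6, output shape L x d_model
  set.seed(61)
  m3 <- tiny_transformer(L = 12L, d_model = 16L, heads = 8L, vocab = 20L)
  X3 <- matrix(rnorm(12 * 16), 12, 16)
  r3 <- multi_head_attention(X3, m3, return_attention = TRUE)
  expect_equal(dim(r3$Z), c(12L, 16L))
  for (A in r3$attention) {
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  }
})

test_that("classifier head: sigmoid(b) at zero weights, flat length, open interval", {
  m <- tiny_transformer()
  m$params$W1[] <- 0; m$params$b1[] <- 0; m$params$w2[] <- 0
  m$params$b2 <- 0.7
  Z <- matrix(rnorm(48), 6, 8)
  expect_equal(classify_head(Z, m), stats::plogis(0.7))
  expect_equal(m$config$flat_len, 6L * 8L)
  # probabilities strictly inside (0, 1)
  set.seed(62)
  m2 <- tiny_transformer()
  p <- classify_head(matrix(rnorm(48, sd = 50), 6, 8), m2)
  expect_gt(p, 0); expect_lt(p, 1)
})

test_that("flattened length is L * d_model across the published schemes", {
  for (L in c(350L, 400L, 1000L)) {
    cfg <- transformer_config(sentence_len = L, vocab_size = 10L,
                              d_model = 512L)
    expect_equal(cfg$flat_len, L * 512L)
  }
})

test_that("class weights follow max(N_p, N_c)/N_i", {
  expect_equal(class_weights(10, 10), c(plasmid = 1, chromosome = 1))
  expect_equal(class_weights(100, 25), c(plasmid = 1, chromosome = 4))
  # published training-set counts: 26451 plasmids, 3530 chromosomes
  w <- class_weights(26451, 3530)
  expect_equal(unname(w["plasmid"]), 1)
  expect_equal(unname(w["chromosome"]), 26451 / 3530, tolerance = 1e-12)
  expect_equal(unname(w["chromosome"]), 7.493, tolerance = 1e-3)
  expect_error(class_weights(0, 5), "both classes")
})

test_that("analytic gradients match numerical gradients on a tiny config", {
  model <- tiny_transformer(seed = 9L)
  set.seed(10)
  sent <- matrix(sample(0:9, 12, TRUE), 2, 6)
  err <- max_grad_error(model, sent, y = c(1, 0), w = c(1.5, 1))
  expect_lt(err, 1e-4)
})

test_that("gradients are correct under sqrt scaling and key masking too", {
  m <- tiny_transformer(seed = 12L, attention_scale = "sqrt_d_k",
                        mask_padding = TRUE)
  set.seed(13)
  sent <- rbind(c(0L, 0L, sample(2:9, 4, TRUE)),
                c(sample(2:9, 5, TRUE), 0L))
  err <- max_grad_error(m, sent, y = c(0, 1), w = c(1, 2))
  expect_lt(err, 1e-4)
})

test_that("training separates synthetic PC usage and is deterministic", {
  set.seed(70)
  L <- 20L
  mkrow <- function(cls) {
    k <- sample(4:8, 1)
    ids <- if (cls == 1) sample(2:6, k, TRUE) else sample(7:11, k, TRUE)
    c(ids, rep(0L, L - k))
  }
  lab <- rep(c(1, 0), each = 100)
  sm <- t(vapply(lab, mkrow, integer(L)))
  cfg <- transformer_config(sentence_len = L, vocab_size = 12L,
                            d_model = 16L, heads = 4L, fc_hidden = 16L,
                            batch_size = 32L, epochs = 2L, seed = 5L)
  fit <- train_transformer(init_transformer(cfg), sm, lab)
  acc <- mean((predict_proba(fit, sm) > 0.5) == (lab == 1))
  expect_gte(acc, 0.95)
  tr <- fit$loss_trace
  expect_true(all(tr$loss > 0))
  expect_lte(mean(tr$loss[tr$epoch == 2]), mean(tr$loss[tr$epoch == 1]))
  # same seed + data -> identical final loss
  fit2 <- train_transformer(init_transformer(cfg), sm, lab)
  expect_identical(utils::tail(fit$loss_trace$loss, 1),
                   utils::tail(fit2$loss_trace$loss, 1))
  # single-class data refused
  expect_error(train_transformer(init_transformer(cfg),
                                 sm[lab == 1, ], lab[lab == 1]),
               "both classes")
})

test_that("augmentation yields original plus per-window samples with labels", {
  s <- c(plas1 = random_dna(4000, seed = 77))
  aug <- augment_training_set(s, "plasmid",
                              windows = c(200L, 400L, 600L, 800L, 1000L,
                                          2000L, 4000L))
  expect_true(all(aug$label == "plasmid"))
  # exactly divisible windows: 20x200, 10x400, 4x1000, 2x2000, 1x4000
  counts <- table(aug$window, useNA = "ifany")
  expect_equal(unname(counts[["200"]]), 20L)
  expect_equal(unname(counts[["400"]]), 10L)
  expect_equal(unname(counts[["1000"]]), 4L)
  expect_equal(unname(counts[["2000"]]), 2L)
  expect_equal(unname(counts[["4000"]]), 1L)
  expect_equal(sum(is.na(aug$window)), 1L)
  # every segment reconstructs from its source
  for (w in c(200L, 2000L)) {
    segs <- aug$seq[!is.na(aug$window) & aug$window == w]
    expect_identical(paste(segs, collapse = ""), unname(s))
  }
  # window larger than the sequence is not duplicated
  s2 <- c(short = random_dna(900, seed = 78))
  aug2 <- augment_training_set(s2, "plasmid", windows = c(2000L))
  expect_equal(nrow(aug2), 1L)
  expect_true(is.na(aug2$window))
})

test_that("model checkpoints round-trip", {
  m <- tiny_transformer(seed = 21L)
  path <- tempfile(fileext = ".rds")
  save_transformer(m, path)
  back <- load_transformer(path)
  expect_identical(back$params, m$params)
  expect_true(file.exists(paste0(path, ".json")))
})
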