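test_that("the learning-rate schedule halves every 20 epochs", {
  cfg <- train_config()
  expect_equal(learning_rate_at(cfg, c(0, 19, 20, 39, 40, 60)),
               c(0.005, 0.005, 0.0025, 0.0025, 0.00125, 0.000625))
  cfg2 <- train_config(initial_lr = 0.1, lr_halving_period_epochs = 5)
  expect_equal(learning_rate_at(cfg2, 0:11),
               0.1 * 0.5^(0:11 %/% 5))
})

test_that("the regularised cross-entropy loss matches closed forms", {
  # perfect one-hot predictions with zero weights: loss 0
  p <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(as.numeric(classification_loss(p, c(0, 1), rep(0, 10),
                                              1e-4)), 0, tolerance = 1e-12)
  # maximally uncertain single sample: ln 2
  expect_equal(as.numeric(classification_loss(c(0.5, 0.5), 1L)), log(2),
               tolerance = 1e-12)
  # l2 term: lambda * sum(w^2) with unit weights
  expect_equal(as.numeric(classification_loss(c(0, 1), 1L, rep(1, 100),
                                              1e-4)), 0.01,
               tolerance = 1e-12)
  # zero probability at the true class is clipped and flagged
  l <- classification_loss(c(1, 0), 1L)
  expect_true(is.finite(l))
  expect_identical(attr(l, "n_clipped"), 1L)
  # nested model parameters enter the penalty (conv/dense weights only)
  m <- build_hybrid_model(seed = 1)
  l2 <- as.numeric(classification_loss(c(0, 1), 1L, m$params, 1e-4))
  expect_gt(l2, 0)
  expect_error(classification_loss(p, c(0, 1, 1)), "disagree")
})

test_that("training rejects degenerate inputs", {
  hy <- tiny_hybrids(n_per_class = 3)
  one_class <- hy[1:3]
  expect_error(train_model(one_class, train_config(seed = 1), epochs = 1),
               "both classes")
  unl <- hy
  unl[[1]]$label <- NA_character_
  expect_error(train_model(unl, train_config(seed = 1), epochs = 1),
               "labeled")
})

test_that("training is bit-deterministic under a fixed seed", {
  hy <- tiny_hybrids(n_per_class = 3)
  cfg <- train_config(seed = 17)
  r1 <- train_model(hy, cfg, branches = c("raw", "dft"), epochs = 3)
  r2 <- train_model(hy, cfg, branches = c("raw", "dft"), epochs = 3)
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$model$params, r2$model$params)
  r3 <- train_model(hy, train_config(seed = 18), branches = c("raw", "dft"),
                    epochs = 3)
  expect_false(identical(r1$loss, r3$loss))
})

test_that("the hybrid model separates a two-tone toy within the budget", {
  # two classes of pure sinusoids at well-separated frequencies
  make_tone <- function(freq, i) {
    eeg_segment(sin(2 * pi * freq * (0:511) / 173.61 + i / 7),
                label = if (freq < 10) "normal" else "epileptic")
  }
  segs <- c(lapply(1:5, function(i) make_tone(5, i)),
            lapply(1:5, function(i) make_tone(20, i)))
  hy <- make_hybrid_set(segs)
  rec <- train_model(hy, train_config(seed = 2), epochs = 40)
  expect_identical(rec$lr, learning_rate_at(train_config(), 0:39))
  expect_equal(rec$train_accuracy[length(rec$train_accuracy)], 1)
  # sanity descent: final loss below the initial loss
  expect_lt(rec$loss[length(rec$loss)], rec$loss[1])
  expect_true(all(is.finite(rec$loss)))
  # the l2 term keeps the loss strictly above the pure data term
  final_probs <- predict_proba(rec$model, hy)
  ce_only <- as.numeric(classification_loss(
    final_probs, vapply(hy, `[[`, "", "label")))
  expect_gte(rec$loss[length(rec$loss)], 0)
  expect_gt(as.numeric(classification_loss(final_probs,
                                           vapply(hy, `[[`, "", "label"),
                                           rec$model$params, 1e-4)),
            ce_only)
})
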