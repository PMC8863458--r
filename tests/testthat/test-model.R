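# Direct-summation oracle for the two-stage factored convolution: depthwise
# per-channel convolution followed by 1x1 cross-channel mixing, written as
# explicit loops with "same" zero padding.
ds_conv_oracle <- function(input, depthwise, pointwise, kernel) {
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]
  kh <- kernel[1]; kw <- kernel[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  dwise <- array(0, c(H, W, C))
  for (c in seq_len(C)) {
    for (h in seq_len(H)) for (w in seq_len(W)) {
      acc <- 0
      for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
        hi <- h + dh - 1 - ph; wi <- w + dw - 1 - pw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + input[hi, wi, c] * depthwise[dh + (dw - 1) * kh, c]
        }
      }
      dwise[h, w, c] <- acc
    }
  }
  out <- array(0, c(H, W, ncol(pointwise)))
  for (m in seq_len(ncol(pointwise))) {
    for (c in seq_len(C)) {
      out[, , m] <- out[, , m] + dwise[, , c] * pointwise[c, m]
    }
  }
  out
}

test_that("depthwise separable convolution matches the two-stage oracle", {
  set.seed(71)
  # identity construction: depthwise unit impulses + pointwise identity
  x <- array(rnorm(8 * 1 * 3), c(8, 1, 3))
  dw_id <- matrix(0, 3, 3); dw_id[2, ] <- 1   # centre tap of a 3x1 kernel
  pw_id <- diag(3)
  expect_equal(depthwise_separable_conv(x, dw_id, pw_id, kernel = c(3, 1)),
               x, tolerance = 1e-12)

  # random 3-channel length-8 input, random kernels, 1-D
  dw <- matrix(rnorm(9), 3, 3)
  pw <- matrix(rnorm(3 * 5), 3, 5)
  expect_equal(depthwise_separable_conv(x, dw, pw, kernel = c(3, 1)),
               ds_conv_oracle(x, dw, pw, c(3, 1)), tolerance = 1e-6)

  # 2-D case with a 3x3 kernel
  x2 <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  dw2 <- matrix(rnorm(9 * 2), 9, 2)
  pw2 <- matrix(rnorm(2 * 4), 2, 4)
  expect_equal(depthwise_separable_conv(x2, dw2, pw2, kernel = c(3, 3)),
               ds_conv_oracle(x2, dw2, pw2, c(3, 3)), tolerance = 1e-6)

  expect_error(depthwise_separable_conv(x, dw, matrix(0, 4, 2),
                                        kernel = c(3, 1)), "pointwise")
})

test_that("parameter counts follow the separable-convolution formulas", {
  # depthwise separable 3x1, 16 -> 32: 16*3 + 16*32 = 560 weights,
  # versus 3*16*32 = 1536 for the standard convolution
  spec_ds <- branch_spec("raw_1d")
  b_ds <- build_branch(spec_ds, seed = 1)
  s3 <- b_ds$params$s3
  expect_identical(length(s3$Wd) + length(s3$Wp), 560L)
  expect_identical(3L * 16L * 32L, 1536L)

  spec_std <- branch_spec("raw_1d", separable = FALSE)
  b_std <- build_branch(spec_std, seed = 1)
  expect_gt(count_parameters(b_std)$total, count_parameters(b_ds)$total)

  # additivity over branches and head
  m <- build_hybrid_model(seed = 1)
  pc <- count_parameters(m)
  expect_identical(pc$total, sum(pc$breakdown))
  # a 1x1 pointwise mixing 16 -> 32 with no bias carries 512 weights
  expect_identical(length(build_branch(branch_spec("dft_1d"),
                                       seed = 2)$params$s3$Wp), 512L)
})

test_that("branch specs enforce the five-stage lightweight structure", {
  expect_error(branch_spec("raw_1d", channels = c(16, 16, 32)), "5 conv")
  expect_error(branch_spec("raw_1d", channels = c(16, 16, 64, 32, 32)),
               "16 or 32")
  expect_error(branch_spec("raw_1d", channels = c(32, 16, 32, 32, 32)),
               "first stage")
  expect_error(branch_spec("raw_1d", first_kernel = c(31, 3)), "Nx1")
  spec <- branch_spec("stft_2d")
  expect_identical(spec$stages[[1]]$kernel, c(15L, 7L))
  expect_identical(branch_spec("raw_1d")$stages[[1]]$kernel, c(31L, 1L))
  expect_identical(spec$stages[[2]]$kernel, c(3L, 1L))
})

test_that("every branch emits a 32-dimensional feature for any batch", {
  set.seed(81)
  cases <- list(
    raw_1d = matrix(rnorm(512 * 3), 512, 3),
    dft_1d = matrix(rnorm(257 * 3), 257, 3),
    dwt_1d = matrix(rnorm(515 * 3), 515, 3),
    stft_2d = array(rnorm(65 * 49 * 3), c(65, 49, 3))
  )
  for (kind in names(cases)) {
    br <- build_branch(branch_spec(kind), seed = 5)
    f <- branch_features(br, cases[[kind]])
    expect_identical(dim(f), c(3L, 32L))
    expect_true(all(is.finite(f)))
  }
  # seeded determinism of initialisation
  b1 <- build_branch(branch_spec("raw_1d"), seed = 9)
  b2 <- build_branch(branch_spec("raw_1d"), seed = 9)
  expect_identical(b1$params, b2$params)
  b3 <- build_branch(branch_spec("raw_1d"), seed = 10)
  expect_false(identical(b1$params$s1$W, b3$params$s1$W))
})

test_that("feature fusion concatenates the four branch features in order", {
  f <- lapply(1:4, function(i) rep(i, 32))
  fused <- fuse(f[[1]], f[[2]], f[[3]], f[[4]])
  expect_length(fused, 128)
  expect_equal(fused, rep(1:4, each = 32))

  # placement: a single nonzero branch occupies exactly its slot
  z <- rep(0, 32)
  fused2 <- fuse(rep(1, 32), z, z, z)
  expect_true(all(fused2[1:32] == 1) && all(fused2[33:128] == 0))

  # distinct inputs give distinct outputs
  expect_false(identical(fuse(f[[1]], f[[2]], f[[3]], f[[4]]),
                         fuse(f[[2]], f[[1]], f[[3]], f[[4]])))

  # batched form
  fm <- lapply(1:4, function(i) matrix(i, 2, 32))
  expect_identical(dim(fuse(fm[[1]], fm[[2]], fm[[3]], fm[[4]])), c(2L, 128L))
  expect_error(fuse(rep(1, 32), rep(1, 16), rep(1, 32), rep(1, 32)),
               "equal dimension")
})

test_that("the softmax head normalises and follows Eq.-style closed forms", {
  head <- fusion_head(4, 2, seed = 1)
  head$W[] <- 0; head$b <- c(0, 0)
  p <- classify(rep(1, 4), head)
  expect_equal(as.numeric(p), c(0.5, 0.5), tolerance = 1e-12)

  # logits (2, 0): probabilities (e^2, 1) / (e^2 + 1)
  head$b <- c(2, 0)
  p <- classify(rep(0, 4), head)
  expect_equal(as.numeric(p), c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-9)

  set.seed(91)
  head2 <- fusion_head(128, 2, seed = 2)
  pm <- classify(matrix(rnorm(6 * 128), 6, 128), head2)
  expect_equal(rowSums(pm), rep(1, 6), tolerance = 1e-9)
  expect_true(all(pm > 0 & pm < 1))

  expect_error(classify(rep(1, 64), head2), "does not match")
  expect_error(classify(matrix(c(Inf, 1), 1, 2),
                        fusion_head(2, 2, seed = 3)), "non-finite")

  # tie-break: equal probabilities are called epileptic
  expect_identical(predict_classes(matrix(c(0.5, 0.7, 0.5, 0.3), 2, 2)),
                   c("epileptic", "normal"))
})

test_that("the hybrid model fuses four 32-d features into a 128-d head", {
  m <- build_hybrid_model(seed = 4)
  expect_identical(m$head_dim, 128L)
  expect_identical(names(m$branches), c("raw", "dft", "stft", "dwt"))
  expect_identical(dim(m$params$head$W), c(128L, 2L))

  m1 <- build_hybrid_model("raw", seed = 4)
  expect_identical(m1$head_dim, 32L)
  expect_identical(dim(m1$params$head$W), c(32L, 2L))

  hy <- tiny_hybrids(n_per_class = 2)
  inputs <- eegfuse:::model_inputs(m, hy, 1:3)
  fw <- eegfuse:::model_forward(m, inputs, training = FALSE)
  expect_identical(dim(fw$fused), c(3L, 128L))
  expect_identical(dim(fw$probs), c(3L, 2L))
})

test_that("inference is independent of batch composition and ordering", {
  hy <- tiny_hybrids(n_per_class = 3)
  m <- build_hybrid_model(seed = 6)
  p_all <- predict_proba(m, hy)
  p_one <- predict_proba(m, hy[4])
  expect_equal(p_all[4, ], p_one[1, ], tolerance = 1e-5,
               ignore_attr = TRUE)
  p_rev <- predict_proba(m, rev(hy))
  expect_equal(p_rev[nrow(p_rev):1, ], p_all, tolerance = 1e-5,
               ignore_attr = TRUE)
})
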