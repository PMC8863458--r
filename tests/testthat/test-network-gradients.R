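# The network has two independent implementations: the modular
# double-precision reference path (src/kernels.cpp, one operation per call)
# and the fused single-precision fast path (src/fused.cpp).  These tests pin
# them against each other and against finite differences.

test_that("fused and reference forward passes agree for all branch kinds", {
  hy <- tiny_hybrids(n_per_class = 3)
  m <- build_hybrid_model(seed = 7)
  for (br in names(m$branches)) {
    spec <- m$branches[[br]]
    arr <- eegfuse:::hybrid_batch_arrays(hy, 1:4, br)[[br]]
    ref <- eegfuse:::branch_forward_pass(spec, m$params[[br]],
                                         m$state[[br]], arr$x, arr$H,
                                         arr$W, 4L, training = FALSE)$feat
    inp <- eegfuse:::hybrid_branch_cols(spec, hy, 1:4, paste0("tst.", br))
    fus <- eegfuse:::fused_branch_forward(spec, m$params[[br]],
                                          m$state[[br]], inp,
                                          training = FALSE,
                                          tag = paste0("tst.", br))$feat
    expect_equal(fus, ref, tolerance = 1e-4)
  }
})

test_that("fused and reference backward passes agree", {
  set.seed(101)
  spec <- branch_spec("stft_2d")
  b <- build_branch(spec, seed = 1)
  H <- 33L; W <- 40L; B <- 3L
  xs <- lapply(seq_len(B), function(i) rnorm(H * W))
  dfeat <- matrix(rnorm(B * 32), B, 32)

  eegfuse:::nn_im2col_set(xs, H, W, 15L, 7L, "gt")
  inp <- list(set = "gt", sel = seq_len(B), H = H, W = W, B = B)
  fwf <- eegfuse:::fused_branch_forward(spec, b$params, b$state, inp,
                                        training = TRUE, tag = "gt")
  grf <- eegfuse:::fused_branch_backward(spec, b$params, inp, fwf$metas,
                                         dfeat, tag = "gt")

  x <- array(unlist(xs), c(H * W, B, 1L))
  fwr <- eegfuse:::branch_forward_pass(spec, b$params, b$state, x, H, W, B,
                                       training = TRUE)
  grr <- eegfuse:::branch_backward_pass(spec, b$params, fwr$caches,
                                        fwr$gap_dims, dfeat, B)
  expect_equal(fwf$feat, fwr$feat, tolerance = 1e-5)
  for (sid in names(grr)) {
    for (leaf in names(grr[[sid]])) {
      expect_equal(grf[[sid]][[leaf]], grr[[sid]][[leaf]],
                   tolerance = 1e-4, ignore_attr = TRUE)
    }
  }
})

test_that("reference gradients agree with central finite differences", {
  # eps = 1e-4 sits above the max-pool argmax-switching noise floor; the
  # analytic gradient accounts for batch-norm statistics' dependence on the
  # weights, which the check would expose if dropped.
  set.seed(102)
  spec <- branch_spec("raw_1d")
  b <- build_branch(spec, seed = 2)
  H <- 64L; B <- 3L
  x <- array(rnorm(H * B), c(H, B, 1L))
  dfeat <- matrix(rnorm(B * 32), B, 32)
  loss_of <- function(params) {
    f <- eegfuse:::branch_forward_pass(spec, params, b$state, x, H, 1L, B,
                                       training = TRUE)
    sum(f$feat * dfeat)
  }
  fwr <- eegfuse:::branch_forward_pass(spec, b$params, b$state, x, H, 1L, B,
                                       training = TRUE)
  grr <- eegfuse:::branch_backward_pass(spec, b$params, fwr$caches,
                                        fwr$gap_dims, dfeat, B)
  eps <- 1e-4
  for (sid in c("s1", "s2", "s5")) {
    for (leaf in names(grr[[sid]])) {
      p <- b$params[[sid]][[leaf]]
      for (k in sample(length(p), min(3, length(p)))) {
        pp <- b$params; pp[[sid]][[leaf]][k] <- p[k] + eps
        pm <- b$params; pm[[sid]][[leaf]][k] <- p[k] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(grr[[sid]][[leaf]][k], num, tolerance = 2e-2,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("the reference standard convolution matches a direct summation", {
  set.seed(103)
  H <- 10L; W <- 6L; B <- 2L; Cin <- 2L; Cout <- 3L
  kh <- 3L; kw <- 3L
  x <- array(rnorm(H * W * B * Cin), c(H * W, B, Cin))
  wt <- array(rnorm(kh * kw * Cin * Cout), c(kh, kw, Cin, Cout))
  y <- eegfuse:::nn_conv_fw(x, H, W, B, Cin,
                            matrix(wt, kh * kw * Cin, Cout), kh, kw,
                            FALSE)$y
  for (b in seq_len(B)) for (co in seq_len(Cout)) {
    ref <- matrix(0, H, W)
    for (ci in seq_len(Cin)) {
      xm <- matrix(x[, b, ci], H, W)
      for (dh in 1:kh) for (dw in 1:kw) {
        sh <- dh - 2L; sw <- dw - 2L
        shifted <- matrix(0, H, W)
        hs <- max(1, 1 + sh):min(H, H + sh)
        ws <- max(1, 1 + sw):min(W, W + sw)
        shifted[hs - sh, ws - sw] <- xm[hs, ws]
        ref <- ref + shifted * wt[dh, dw, ci, co]
      }
    }
    expect_equal(matrix(y[, b, co], H, W), ref, tolerance = 1e-5)
  }
})
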