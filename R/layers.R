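# Internal layer mechanics for the branch networks.
#
# Activations are numeric arrays with dim (H*W, B, C); see src/kernels.cpp
# for the layout contract.  Each branch stage is
#   convolution (standard or depthwise separable) -> batch norm -> ReLU
# followed by a stride-2 max pool (stages 1-4) or global average pooling
# (final stage).

he_uniform <- function(n, fan_in) {
  limit <- sqrt(6 / fan_in)
  stats::runif(n, -limit, limit)
}

# Parameter initialisation for one stage.  Standard conv stages carry a
# (kh, kw, cin, cout) kernel tensor; depthwise separable stages a per-channel
# depthwise kernel matrix (kh*kw, cin) and a pointwise mixing matrix
# (cin, cout).  Convolutions have no bias: batch norm's shift follows.
init_stage_params <- function(stage) {
  kh <- stage$kernel[1]; kw <- stage$kernel[2]
  cin <- stage$cin; cout <- stage$cout
  p <- list()
  if (stage$kind == "conv") {
    p$W <- array(he_uniform(kh * kw * cin * cout, kh * kw * cin),
                 dim = c(kh, kw, cin, cout))
  } else {
    p$Wd <- matrix(he_uniform(kh * kw * cin, kh * kw), kh * kw, cin)
    p$Wp <- matrix(he_uniform(cin * cout, cin), cin, cout)
  }
  p$g <- rep(1, cout)
  p$b <- rep(0, cout)
  p
}

init_stage_state <- function(stage) {
  list(rm = rep(0, stage$cout), rv = rep(1, stage$cout))
}

# Pointwise (1x1) convolution is a channel-mixing matrix product; with the
# (HW, B, C) layout the batch collapses into the GEMM for free.
pointwise_fw <- function(x, Wp) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% Wp
  dim(y) <- c(d[1], d[2], ncol(Wp))
  y
}

pointwise_bw <- function(x, dy, Wp) {
  d <- dim(x); dd <- dim(dy)
  xm <- matrix(x, d[1] * d[2], d[3])
  dym <- matrix(dy, dd[1] * dd[2], dd[3])
  dx <- dym %*% t(Wp)
  dim(dx) <- d
  list(dx = dx, dWp = crossprod(xm, dym))
}

# Forward through one stage.  Returns the output, its spatial dims, a cache
# for backprop (training only), and batch-norm statistics updates.
stage_forward <- function(stage, params, state, x, H, W, B, training,
                          bn_eps, bn_momentum) {
  cache <- if (training) list(x = x, H = H, W = W) else NULL
  if (stage$kind == "conv") {
    wm <- matrix(params$W, prod(stage$kernel) * stage$cin, stage$cout)
    cf <- nn_conv_fw(x, H, W, B, stage$cin, wm, stage$kernel[1],
                     stage$kernel[2], training)
    z <- cf$y
    if (training) cache$conv_cache <- cf$cache
  } else {
    zd <- nn_dwconv_fw(x, H, W, B, stage$cin, params$Wd, stage$kernel[1],
                       stage$kernel[2])
    z <- pointwise_fw(zd, params$Wp)
    if (training) cache$zd <- zd
  }
  bn <- nn_bn_relu_fw(z, H * W * B, stage$cout, params$g, params$b,
                      state$rm, state$rv, use_given = !training, eps = bn_eps)
  y <- bn$y
  state_update <- NULL
  if (training) {
    cache$z <- z
    cache$y_bn <- y
    cache$bn_mean <- bn$mean
    cache$bn_var <- bn$var
    state_update <- list(
      rm = bn_momentum * state$rm + (1 - bn_momentum) * bn$mean,
      rv = bn_momentum * state$rv + (1 - bn_momentum) * bn$var
    )
  }
  H2 <- H; W2 <- W
  if (stage$pool) {
    ph <- stage$pool_dims[1]; pw <- stage$pool_dims[2]
    mp <- nn_maxpool_fw(y, H, W, B, stage$cout, ph, pw)
    y <- mp$y
    H2 <- H %/% ph; W2 <- W %/% pw
    if (training) cache$pool_idx <- mp$idx
  }
  list(y = y, H = H2, W = W2, cache = cache, state_update = state_update)
}

# Backward through one stage; `want_dx` is FALSE for the input stage.
stage_backward <- function(stage, params, cache, dy, B, bn_eps, want_dx) {
  H <- cache$H; W <- cache$W
  if (stage$pool) {
    ph <- stage$pool_dims[1]; pw <- stage$pool_dims[2]
    dy <- nn_maxpool_bw(dy, cache$pool_idx, H, W, B, stage$cout,
                        H %/% ph, W %/% pw)
  }
  bnb <- nn_bn_relu_bw(cache$z, cache$y_bn, dy, H * W * B, stage$cout,
                       params$g, cache$bn_mean, cache$bn_var, bn_eps)
  dz <- bnb$dx
  grads <- list(g = bnb$dgamma, b = bnb$dbeta)
  if (stage$kind == "conv") {
    wm <- matrix(params$W, prod(stage$kernel) * stage$cin, stage$cout)
    cb <- nn_conv_bw(cache$conv_cache, dz, H, W, B, stage$cin, wm,
                     stage$kernel[1], stage$kernel[2], want_dx)
    grads$W <- array(cb$dW, dim = dim(params$W))
    dx <- if (want_dx) cb$dx else NULL
  } else {
    pb <- pointwise_bw(cache$zd, dz, params$Wp)
    grads$Wp <- pb$dWp
    db <- nn_dwconv_bw(cache$x, pb$dx, H, W, B, stage$cin, params$Wd,
                       stage$kernel[1], stage$kernel[2])
    grads$Wd <- db$dW
    dx <- if (want_dx) db$dx else NULL
  }
  list(dx = dx, grads = grads)
}

gap_forward <- function(x, H, W, B, C) {
  f <- colMeans(matrix(x, H * W, B * C))
  dim(f) <- c(B, C)
  f
}

gap_backward <- function(df, H, W, B, C) {
  dx <- rep(as.vector(df) / (H * W), each = H * W)
  dim(dx) <- c(H * W, B, C)
  dx
}
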