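#' Declarative specification of one CNN branch
#'
#' Each branch is a five-stage lightweight CNN: a standard convolution with a
#' large receptive field (31x1 for 1-D inputs, 15x7 for the 2-D spectrogram)
#' followed by four depthwise separable convolutions with 3x1 kernels.  Every
#' convolution is followed by batch normalization and ReLU; a stride-2 max
#' pool follows each of the first four stages, and global average pooling
#' reduces the final 32-channel feature map to a 32-dimensional feature
#' vector regardless of input size.
#'
#' @param input_kind One of `"raw_1d"`, `"dft_1d"`, `"dwt_1d"`, `"stft_2d"`.
#' @param channels Kernel counts for the five stages; each must be 16 or 32
#'   and the first must be 16 (default `c(16, 16, 32, 32, 32)`).
#' @param first_kernel Kernel extent `(kh, kw)` of the first (standard)
#'   convolution; defaults to `c(31, 1)` for 1-D kinds and `c(15, 7)` for
#'   `"stft_2d"`.
#' @param later_kernel Kernel extent of stages 2-5 (default `c(3, 1)`,
#'   applied to the 2-D branch as well; set `c(3, 3)` for square kernels).
#' @param separable If `TRUE` (default) stages 2-5 are depthwise separable;
#'   `FALSE` swaps in standard convolutions of the same extent (ablation).
#' @param bn_momentum Batch-norm running-statistics momentum (default 0.9).
#' @param bn_eps Batch-norm variance floor (default 1e-5).
#' @return A list of class `branch_spec` with a `stages` element describing
#'   the five convolution stages.
#' @export
branch_spec <- function(input_kind = c("raw_1d", "dft_1d", "dwt_1d",
                                       "stft_2d"),
                        channels = c(16L, 16L, 32L, 32L, 32L),
                        first_kernel = NULL, later_kernel = c(3L, 1L),
                        separable = TRUE, bn_momentum = 0.9,
                        bn_eps = 1e-5) {
  input_kind <- match.arg(input_kind)
  channels <- as.integer(channels)
  if (length(channels) != 5L) stopf("a branch has exactly 5 conv stages")
  if (!all(channels %in% c(16L, 32L))) {
    stopf("kernel counts must be 16 or 32")
  }
  if (channels[1] != 16L) stopf("the first stage uses 16 kernels")
  is_2d <- input_kind == "stft_2d"
  if (is.null(first_kernel)) {
    first_kernel <- if (is_2d) c(15L, 7L) else c(31L, 1L)
  }
  first_kernel <- as.integer(first_kernel)
  later_kernel <- as.integer(later_kernel)
  if (any(c(first_kernel, later_kernel) %% 2L == 0L)) {
    stopf("kernel extents must be odd (same padding)")
  }
  if (!is_2d && (first_kernel[2] != 1L || later_kernel[2] != 1L)) {
    stopf("1-D branches require Nx1 kernels")
  }
  if (bn_momentum <= 0 || bn_momentum >= 1) {
    stopf("bn_momentum must be in (0, 1)")
  }
  pool_dims <- if (is_2d) c(2L, 2L) else c(2L, 1L)
  stages <- vector("list", 5L)
  cin <- 1L
  for (i in 1:5) {
    stages[[i]] <- list(
      kind = if (i == 1L || !separable) "conv" else "ds",
      kernel = if (i == 1L) first_kernel else later_kernel,
      cin = cin, cout = channels[i],
      pool = i < 5L, pool_dims = pool_dims
    )
    cin <- channels[i]
  }
  structure(
    list(input_kind = input_kind, channels = channels, stages = stages,
         feature_dim = channels[5], separable = separable,
         bn_momentum = bn_momentum, bn_eps = bn_eps),
    class = "branch_spec"
  )
}

branch_kind_for <- c(raw = "raw_1d", dft = "dft_1d", stft = "stft_2d",
                     dwt = "dwt_1d")

#' Build one branch network
#'
#' Instantiates the parameters of a [branch_spec()] with seeded uniform
#' fan-in (He) initialisation.  The returned branch is a callable description
#' used by the model forward/backward machinery; apply it to a batch with
#' [branch_features()].
#'
#' @param spec A [branch_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `eeg_branch` with `spec`, `params` (named list of
#'   stage parameters), and `state` (batch-norm running statistics).
#' @export
build_branch <- function(spec, seed = 0L) {
  if (!inherits(spec, "branch_spec")) stopf("expected a branch_spec")
  params <- list()
  state <- list()
  with_seed(derive_seed(seed, 11L), {
    for (i in seq_along(spec$stages)) {
      id <- paste0("s", i)
      params[[id]] <- init_stage_params(spec$stages[[i]])
      state[[id]] <- init_stage_state(spec$stages[[i]])
    }
  })
  structure(list(spec = spec, params = params, state = state),
            class = "eeg_branch")
}

# Forward pass of one branch over a batch.
# x: array (H*W, B, 1); returns the (B, 32) feature matrix, caches, and
# batch-norm state updates (training mode).
branch_forward_pass <- function(spec, params, state, x, H, W, B, training) {
  caches <- vector("list", length(spec$stages))
  updates <- list()
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    id <- paste0("s", i)
    out <- stage_forward(st, params[[id]], state[[id]], x, H, W, B,
                         training, spec$bn_eps, spec$bn_momentum)
    x <- out$y; H <- out$H; W <- out$W
    caches[[i]] <- out$cache
    if (!is.null(out$state_update)) updates[[id]] <- out$state_update
  }
  feat <- gap_forward(x, H, W, B, spec$stages[[5]]$cout)
  list(feat = feat, caches = caches, gap_dims = c(H, W),
       state_updates = updates)
}

branch_backward_pass <- function(spec, params, caches, gap_dims, dfeat, B) {
  C <- spec$stages[[5]]$cout
  dy <- gap_backward(dfeat, gap_dims[1], gap_dims[2], B, C)
  grads <- list()
  for (i in rev(seq_along(spec$stages))) {
    st <- spec$stages[[i]]
    bw <- stage_backward(st, params[[paste0("s", i)]], caches[[i]], dy, B,
                         spec$bn_eps, want_dx = i > 1L)
    grads[[paste0("s", i)]] <- bw$grads
    dy <- bw$dx
  }
  grads
}

#' Extract branch features for a batch of inputs
#'
#' Runs a built branch in inference mode (batch-norm running statistics) and
#' returns the per-sample feature vectors produced by global average pooling.
#'
#' @param branch An `eeg_branch` from [build_branch()].
#' @param x Input batch: a numeric matrix (length x B) for 1-D branches, or
#'   a 3-D array (bins, frames, B) / list of matrices for the 2-D branch.
#' @return A B x 32 feature matrix.
#' @export
branch_features <- function(branch, x) {
  ar <- as_branch_array(branch$spec$input_kind, x)
  if (branch_is_fused(branch$spec)) {
    k <- branch$spec$stages[[1]]$kernel
    xs <- lapply(seq_len(ar$B), function(b) as.numeric(ar$x[, b, 1L]))
    set_tag <- paste0("feat.", branch$spec$input_kind)
    nn_im2col_set(xs, ar$H, ar$W, k[1], k[2], set_tag)
    input <- list(set = set_tag, sel = seq_len(ar$B), H = ar$H, W = ar$W,
                  B = ar$B)
    return(fused_branch_forward(branch$spec, branch$params, branch$state,
                                input, training = FALSE,
                                tag = paste0("feat.",
                                             branch$spec$input_kind))$feat)
  }
  branch_forward_pass(branch$spec, branch$params, branch$state, ar$x,
                      ar$H, ar$W, ar$B, training = FALSE)$feat
}

# Normalise user input shapes to the internal (HW, B, 1) layout.
as_branch_array <- function(input_kind, x) {
  if (input_kind == "stft_2d") {
    if (is.list(x)) x <- simplify2array(x)
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    d <- dim(x)
    H <- d[1]; W <- d[2]; B <- d[3]
    dim(x) <- c(H * W, B, 1L)
  } else {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    H <- nrow(x); W <- 1L; B <- ncol(x)
    dim(x) <- c(H, B, 1L)
  }
  list(x = x, H = H, W = W, B = B)
}

#' Depthwise separable convolution of a channel-stacked feature map
#'
#' Two-stage factored convolution: first each input channel is convolved
#' ("same" zero padding) with its own depthwise kernel, then a pointwise
#' (1x1) convolution mixes channels.  For `cin` channels, `cout` outputs and
#' kernel extent `k`, the layer carries `cin * k + cin * cout` weights versus
#' `k * cin * cout` for a standard convolution.
#'
#' @param input 3-D numeric array `(H, W, C)`: one channel-stacked map.
#' @param depthwise Matrix `(kh * kw, C)` of per-channel kernels, or a 3-D
#'   array `(kh, kw, C)`.
#' @param pointwise Matrix `(C, C_out)` of 1x1 mixing weights.
#' @param kernel Integer extent `(kh, kw)` of the depthwise kernels
#'   (required when `depthwise` is a matrix with ambiguous extent).
#' @return Array `(H, W, C_out)`.
#' @export
depthwise_separable_conv <- function(input, depthwise, pointwise,
                                     kernel = NULL) {
  d <- dim(input)
  if (length(d) != 3L) stopf("input must be a (H, W, C) array")
  H <- d[1]; W <- d[2]; C <- d[3]
  if (length(dim(depthwise)) == 3L) {
    kernel <- dim(depthwise)[1:2]
    depthwise <- matrix(depthwise, prod(kernel), dim(depthwise)[3])
  }
  if (is.null(kernel)) stopf("kernel extent required")
  kernel <- as.integer(kernel)
  if (ncol(depthwise) != C) {
    stopf("depthwise stage needs one kernel per input channel (%d != %d)",
          ncol(depthwise), C)
  }
  if (nrow(pointwise) != C) {
    stopf("pointwise stage expects %d input channels, got %d", nrow(pointwise),
          C)
  }
  x <- input
  dim(x) <- c(H * W, 1L, C)
  zd <- nn_dwconv_fw(x, H, W, 1L, C, depthwise, kernel[1], kernel[2])
  y <- pointwise_fw(zd, pointwise)
  dim(y) <- c(H, W, ncol(pointwise))
  y
}

#' Fuse per-branch feature vectors by concatenation
#'
#' Stacks the four 32-dimensional branch features (order: raw, DFT, STFT,
#' DWT) into one 128-dimensional syncretic feature.  Accepts vectors (one
#' sample) or B x 32 matrices (a batch).
#'
#' @param f1,f2,f3,f4 Feature vectors or matrices of equal leading dimension.
#' @return The concatenated feature vector (or B x 128 matrix).
#' @export
fuse <- function(f1, f2, f3, f4) {
  feats <- list(f1, f2, f3, f4)
  if (is.null(dim(f1))) {
    dims <- lengths(feats)
    if (length(unique(dims)) != 1L) {
      stopf("branch features must have equal dimension")
    }
    return(c(f1, f2, f3, f4))
  }
  if (length(unique(vapply(feats, nrow, 1L))) != 1L) {
    stopf("branch feature batches must align")
  }
  do.call(cbind, feats)
}

#' Classification head: dense layer + softmax
#'
#' @param input_dim Fused feature dimension (128 for the four-branch model).
#' @param n_classes Number of classes (2).
#' @param seed Seed for weight initialisation.
#' @return List of class `fusion_head` with weight matrix `W`
#'   (`input_dim x n_classes`) and bias `b`.
#' @export
fusion_head <- function(input_dim = 128L, n_classes = 2L, seed = 0L) {
  with_seed(derive_seed(seed, 13L), {
    limit <- sqrt(6 / (input_dim + n_classes))
    W <- matrix(stats::runif(input_dim * n_classes, -limit, limit),
                input_dim, n_classes)
  })
  structure(list(W = W, b = rep(0, n_classes)), class = "fusion_head")
}

softmax_rows <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (!all(is.finite(logits))) stopf("non-finite logits")
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities from a fused feature
#'
#' Applies the dense classification head and softmax normalisation.  By
#' convention class 1 is "normal" and class 2 "epileptic"; the predicted
#' label is "normal" iff `p[1] > p[2]` (ties are called epileptic).
#'
#' @param fused Fused feature vector, or B x D matrix.
#' @param head A [fusion_head()].
#' @return B x 2 matrix of probabilities (rows sum to 1).
#' @export
classify <- function(fused, head) {
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
  if (ncol(fused) != nrow(head$W)) {
    stopf("fused dimension %d does not match head input %d", ncol(fused),
          nrow(head$W))
  }
  logits <- fused %*% head$W + rep(head$b, each = nrow(fused))
  p <- softmax_rows(logits)
  colnames(p) <- c("normal", "epileptic")
  p
}

#' Map class probabilities to labels
#'
#' @param probs B x 2 probability matrix from [classify()].
#' @return Character vector of `"normal"` / `"epileptic"`; ties go to
#'   `"epileptic"` (the clinically conservative call).
#' @export
predict_classes <- function(probs) {
  ifelse(probs[, 1L] > probs[, 2L], "normal", "epileptic")
}

#' Build the hybrid (or single-input) seizure detection model
#'
#' Constructs one CNN branch per requested representation plus the shared
#' classification head.  With all four branches the fused feature entering
#' the head is 128-dimensional (4 x 32); single-input ablations get a
#' 32-dimensional head.
#'
#' @param branches Representations to include, a subset of
#'   `c("raw", "dft", "stft", "dwt")` in that order.
#' @param seed Seed for all weight initialisation.
#' @param l2_lambda l2 penalty weight on convolution and dense weights
#'   (default 1e-4).
#' @param later_kernel,separable Passed to [branch_spec()].
#' @return A list of class `hybrid_model` with `branches` (named
#'   `branch_spec`s), `params`, `state`, `head_dim`, `l2_lambda`, `seed`.
#' @examples
#' m <- build_hybrid_model(seed = 1)
#' count_parameters(m)$total
#' @export
build_hybrid_model <- function(branches = c("raw", "dft", "stft", "dwt"),
                               seed = 0L, l2_lambda = 1e-4,
                               later_kernel = c(3L, 1L), separable = TRUE) {
  branches <- match.arg(branches, c("raw", "dft", "stft", "dwt"),
                        several.ok = TRUE)
  specs <- list()
  params <- list()
  state <- list()
  for (br in branches) {
    spec <- branch_spec(branch_kind_for[[br]], later_kernel = later_kernel,
                        separable = separable)
    built <- build_branch(spec, seed = derive_seed(seed, match(br, names(branch_kind_for))))
    specs[[br]] <- spec
    params[[br]] <- built$params
    state[[br]] <- built$state
  }
  head_dim <- sum(vapply(specs, `[[`, 1L, "feature_dim"))
  head <- fusion_head(head_dim, 2L, seed = derive_seed(seed, 17L))
  params$head <- list(W = head$W, b = head$b)
  structure(
    list(branches = specs, params = params, state = state,
         head_dim = head_dim, l2_lambda = l2_lambda, seed = seed),
    class = "hybrid_model"
  )
}

#' @export
print.hybrid_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<hybrid_model> branches: %s | fused dim %d | %d parameters\n",
              paste(names(x$branches), collapse = ", "), x$head_dim,
              pc$total))
  invisible(x)
}

# Assemble the (HW, B, 1) input arrays for a batch of hybrid inputs.
hybrid_batch_arrays <- function(hybrids, idx, branch_names) {
  B <- length(idx)
  out <- list()
  for (br in branch_names) {
    if (br == "stft") {
      mats <- lapply(hybrids[idx], `[[`, "stft")
      H <- nrow(mats[[1L]]); W <- ncol(mats[[1L]])
      x <- array(unlist(mats, use.names = FALSE), dim = c(H * W, B, 1L))
    } else {
      vecs <- lapply(hybrids[idx], `[[`, br)
      H <- length(vecs[[1L]]); W <- 1L
      x <- array(unlist(vecs, use.names = FALSE), dim = c(H, B, 1L))
    }
    out[[br]] <- list(x = x, H = H, W = W, B = B)
  }
  out
}

# Assemble inputs for all branches of a model; fused-capable branches get
# per-sample im2col pointer lists, others plain arrays.
model_inputs <- function(model, hybrids, idx, tag = "pred") {
  out <- list()
  for (br in names(model$branches)) {
    spec <- model$branches[[br]]
    out[[br]] <- if (branch_is_fused(spec)) {
      hybrid_branch_cols(spec, hybrids, idx, paste0(tag, ".", br))
    } else {
      hybrid_batch_arrays(hybrids, idx, br)[[br]]
    }
  }
  out
}

# Full model forward.  Returns probabilities plus (in training mode) all the
# caches needed for the backward pass.
model_forward <- function(model, inputs, training = FALSE) {
  feats <- list()
  caches <- list()
  for (br in names(model$branches)) {
    inp <- inputs[[br]]
    fw <- if (!is.null(inp$set)) {
      fused_branch_forward(model$branches[[br]], model$params[[br]],
                           model$state[[br]], inp, training, tag = br)
    } else {
      branch_forward_pass(model$branches[[br]], model$params[[br]],
                          model$state[[br]], inp$x, inp$H, inp$W, inp$B,
                          training)
    }
    feats[[br]] <- fw$feat
    if (training) {
      fw$input <- inp
      caches[[br]] <- fw
    }
  }
  fused <- do.call(cbind, feats)
  logits <- fused %*% model$params$head$W +
    rep(model$params$head$b, each = nrow(fused))
  probs <- softmax_rows(logits)
  list(probs = probs, fused = fused, caches = caches)
}

# Predict probabilities for a list of hybrid inputs, in inference mode.
#' Predict class probabilities for hybrid inputs
#'
#' @param model A trained [build_hybrid_model()].
#' @param hybrids A list of `hybrid_input` objects (see [make_hybrid_set()]).
#' @param batch_size Samples per forward batch.
#' @return N x 2 probability matrix.
#' @export
predict_proba <- function(model, hybrids, batch_size = 20L) {
  n <- length(hybrids)
  probs <- matrix(NA_real_, n, 2L)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    inputs <- model_inputs(model, hybrids, idx)
    probs[idx, ] <- model_forward(model, inputs, training = FALSE)$probs
  }
  colnames(probs) <- c("normal", "epileptic")
  probs
}

#' Count trainable parameters
#'
#' @param model A [build_hybrid_model()] (or a single `eeg_branch`).
#' @return List with `total` and a named `breakdown` per branch and head.
#'   Batch-norm scale/shift parameters are trainable and included; running
#'   statistics are not.
#' @export
count_parameters <- function(model) {
  count_tree <- function(x) {
    if (is.list(x)) return(sum(vapply(x, count_tree, 0)))
    length(x)
  }
  if (inherits(model, "eeg_branch")) {
    n <- count_tree(model$params)
    return(list(total = n, breakdown = c(branch = n)))
  }
  breakdown <- vapply(model$params, count_tree, 0)
  list(total = sum(breakdown), breakdown = breakdown)
}
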