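# Fast branch execution path over the fused single-precision kernels
# (src/fused.cpp): the whole five-stage branch runs forward/backward in one
# C++ call per direction, with intermediates cached in a persistent
# workspace.  Applicable whenever the branch has the standard shape: stage 1
# a single-channel standard convolution, stages 2-5 depthwise separable.
# The reference path in layers.R implements the same semantics one
# operation at a time and is used for the non-separable ablation and as the
# oracle in equivalence tests.

branch_is_fused <- function(spec) {
  spec$stages[[1]]$kind == "conv" && spec$stages[[1]]$cin == 1L &&
    all(vapply(spec$stages[-1], `[[`, "", "kind") == "ds")
}

rep_field <- c(raw_1d = "raw", dft_1d = "dft", stft_2d = "stft",
               dwt_1d = "dwt")

# Integer stage descriptor consumed by the C++ kernels:
# kind, kh, kw, cin, cout, ph, pw per row (ph = pw = 1: no pooling).
branch_spec_matrix <- function(spec) {
  t(vapply(spec$stages, function(st) {
    pd <- if (st$pool) st$pool_dims else c(1L, 1L)
    c(if (st$kind == "conv") 0L else 1L, st$kernel, st$cin, st$cout, pd)
  }, integer(7)))
}

# Build the fused-path input for one branch over a set of hybrid inputs:
# one contiguous im2col "set" holding every sample's first-layer receptive
# fields, plus the sample selector.  The first layer's input never changes,
# so a training fold computes this once and batches subset `sel`.
hybrid_branch_cols <- function(spec, hybrids, idx, set_tag) {
  field <- rep_field[[spec$input_kind]]
  xs <- lapply(hybrids[idx], function(h) as.numeric(h[[field]]))
  first <- hybrids[[idx[1L]]][[field]]
  if (spec$input_kind == "stft_2d") {
    H <- nrow(first); W <- ncol(first)
  } else {
    H <- length(first); W <- 1L
  }
  k <- spec$stages[[1]]$kernel
  nn_im2col_set(xs, H, W, k[1], k[2], set_tag)
  list(set = set_tag, sel = seq_along(idx), H = H, W = W,
       B = length(idx))
}

# Input object for a batch drawn from a cached branch input.
subset_branch_input <- function(input, sel) {
  list(set = input$set, sel = sel, H = input$H, W = input$W,
       B = length(sel))
}

fused_branch_forward <- function(spec, params, state, input, training, tag) {
  out <- nn_branch_fw(input$set, input$sel, branch_spec_matrix(spec),
                      unname(params), unname(state), spec$bn_eps, training,
                      input$H, input$W, paste0(tag, ".b", input$B))
  updates <- NULL
  if (training) {
    mom <- spec$bn_momentum
    updates <- lapply(seq_along(spec$stages), function(i) {
      s <- state[[paste0("s", i)]]
      list(rm = mom * s$rm + (1 - mom) * out$means[[i]],
           rv = mom * s$rv + (1 - mom) * out$vars[[i]])
    })
    names(updates) <- paste0("s", seq_along(spec$stages))
  }
  list(feat = out$feat, metas = list(means = out$means, vars = out$vars),
       state_updates = updates)
}

fused_branch_backward <- function(spec, params, input, metas, dfeat, tag) {
  grads <- nn_branch_bw(input$set, input$sel, branch_spec_matrix(spec),
                        unname(params), metas$means, metas$vars,
                        as.matrix(dfeat), spec$bn_eps, input$H, input$W,
                        paste0(tag, ".b", input$B))
  names(grads) <- paste0("s", seq_along(spec$stages))
  grads
}
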