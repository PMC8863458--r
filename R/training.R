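#' Training configuration
#'
#' Defaults follow the published few-shot schedule: Adam with initial
#' learning rate 0.005 halved every 20 epochs, batch size 6, at most 100
#' epochs, and an l2 penalty of 1e-4 on convolution and dense weights.
#'
#' @param batch_size Samples per optimisation step (default 6; the last
#'   incomplete batch of an epoch is kept).
#' @param max_epochs Training epochs (default 100).
#' @param initial_lr Initial learning rate (default 0.005).
#' @param lr_halving_period_epochs Epoch period after which the learning
#'   rate halves (default 20).
#' @param l2_lambda l2 penalty weight (default 1e-4).  Applied to
#'   convolutional and dense weights only; batch-norm scale/shift and the
#'   head bias are exempt.
#' @param optimizer Only `"adam"` is implemented.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon
#'   (conventional defaults).
#' @param seed Run seed: drives weight initialisation and epoch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 6L, max_epochs = 100L,
                         initial_lr = 0.005, lr_halving_period_epochs = 20L,
                         l2_lambda = 1e-4, optimizer = "adam",
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-7, seed = 0L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, initial_lr > 0,
            lr_halving_period_epochs >= 1, l2_lambda >= 0)
  if (!identical(optimizer, "adam")) stopf("only the adam optimizer is implemented")
  structure(
    list(batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), initial_lr = initial_lr,
         lr_halving_period_epochs = as.integer(lr_halving_period_epochs),
         l2_lambda = l2_lambda, optimizer = optimizer,
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given (0-based) epoch
#'
#' Piecewise-constant halving schedule:
#' `initial_lr * 0.5 ^ floor(epoch / period)`.
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index (vectorised).
#' @return Learning rate(s).
#' @export
learning_rate_at <- function(config, epoch) {
  config$initial_lr * 0.5^(epoch %/% config$lr_halving_period_epochs)
}

# Names of parameters the l2 penalty applies to.
is_regularized_param <- function(leaf_name) {
  leaf_name %in% c("W", "Wd", "Wp")
}

# Sum of squares of regularized weights; walks the nested parameter list.
l2_penalty_sum <- function(params) {
  total <- 0
  for (grp in names(params)) {
    for (leaf in names(params[[grp]])) {
      if (grp == "head") {
        if (leaf == "W") total <- total + sum(params$head$W^2)
      } else {
        for (nm in names(params[[grp]][[leaf]])) {
          if (is_regularized_param(nm)) {
            total <- total + sum(params[[grp]][[leaf]][[nm]]^2)
          }
        }
      }
    }
  }
  total
}

#' Regularised cross-entropy classification loss
#'
#' Mean cross-entropy over the batch plus `l2_lambda` times the sum of
#' squared weights.  Probabilities at the true class are clipped at 1e-12
#' before the log; the number of clipped samples is reported via the
#' `"n_clipped"` attribute.
#'
#' @param probabilities B x 2 matrix of predicted class probabilities (rows
#'   summing to 1), or a length-2 vector for a single sample.
#' @param labels Integer class indices in `{0, 1}` (0 = normal,
#'   1 = epileptic), or a character vector of labels.
#' @param weights Optional model parameters (the nested `params` list of a
#'   `hybrid_model`, or a plain numeric vector) entering the l2 term.
#' @param l2_lambda Penalty weight.
#' @return Scalar loss with attribute `n_clipped`.
#' @examples
#' classification_loss(c(0.5, 0.5), 1L)  # log(2)
#' @export
classification_loss <- function(probabilities, labels, weights = NULL,
                                l2_lambda = 0) {
  if (is.null(dim(probabilities))) {
    probabilities <- matrix(probabilities, nrow = 1L)
  }
  labels <- as_class_index(labels)
  if (nrow(probabilities) != length(labels)) {
    stopf("probabilities and labels disagree in length")
  }
  p_true <- probabilities[cbind(seq_along(labels), labels + 1L)]
  n_clipped <- sum(p_true < 1e-12)
  ce <- -mean(log(pmax(p_true, 1e-12)))
  l2 <- 0
  if (!is.null(weights) && l2_lambda > 0) {
    l2 <- l2_lambda * if (is.numeric(weights)) sum(weights^2) else
      l2_penalty_sum(weights)
  }
  structure(ce + l2, n_clipped = n_clipped)
}

as_class_index <- function(labels) {
  if (is.character(labels)) {
    bad <- !labels %in% c("normal", "epileptic")
    if (any(bad)) stopf("unknown label '%s'", labels[which(bad)[1L]])
    return(ifelse(labels == "epileptic", 1L, 0L))
  }
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stopf("class indices must be 0 or 1")
  labels
}

# ---- flat parameter traversal helpers (Adam bookkeeping) -------------------

flatten_params <- function(params) {
  out <- list()
  for (grp in names(params)) {
    for (leaf in names(params[[grp]])) {
      node <- params[[grp]][[leaf]]
      if (is.list(node)) {
        for (nm in names(node)) {
          out[[paste(grp, leaf, nm, sep = ".")]] <- node[[nm]]
        }
      } else {
        out[[paste(grp, leaf, sep = ".")]] <- node
      }
    }
  }
  out
}

unflatten_into <- function(params, flat, paths = NULL) {
  if (is.null(paths)) {
    paths <- lapply(names(flat), strsplit, split = ".", fixed = TRUE)
    paths <- lapply(paths, `[[`, 1L)
  }
  for (i in seq_along(flat)) {
    path <- paths[[i]]
    if (length(path) == 2L) {
      params[[path[1]]][[path[2]]] <- flat[[i]]
    } else {
      params[[path[1]]][[path[2]]][[path[3]]] <- flat[[i]]
    }
  }
  params
}

# One Adam update; m/v/t live in `opt`.
adam_step <- function(opt, flat_params, flat_grads, lr, config) {
  opt$t <- opt$t + 1L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (key in names(flat_params)) {
    g <- flat_grads[[key]]
    opt$m[[key]] <- b1 * opt$m[[key]] + (1 - b1) * g
    opt$v[[key]] <- b2 * opt$v[[key]] + (1 - b2) * g * g
    flat_params[[key]] <- flat_params[[key]] -
      lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + config$adam_eps)
  }
  list(opt = opt, params = flat_params)
}

#' Train a hybrid (or single-input) model
#'
#' End-to-end joint optimisation of all branches and the classification head
#' with Adam under the halving learning-rate schedule, minimising mean
#' cross-entropy plus the l2 penalty.  Deterministic given
#' `config$seed` (single-threaded BLAS assumed for bit-identical repeats).
#'
#' @param train_set List of labeled `hybrid_input` objects
#'   ([make_hybrid_set()]).
#' @param config A [train_config()].
#' @param branches Representations to train on (subset of
#'   `c("raw", "dft", "stft", "dwt")`).
#' @param model Optional pre-built [build_hybrid_model()]; by default one is
#'   built with seed `config$seed`.
#' @param epochs Optional override of `config$max_epochs` (reduced training
#'   budgets).
#' @return A `train_record`: list with the trained `model`, per-epoch `loss`,
#'   `train_accuracy`, `lr`, `n_clipped`, and the `config` snapshot.
#' @export
train_model <- function(train_set, config = train_config(),
                        branches = c("raw", "dft", "stft", "dwt"),
                        model = NULL, epochs = NULL) {
  labels_chr <- vapply(train_set, `[[`, "", "label")
  if (anyNA(labels_chr)) stopf("all training samples must be labeled")
  y <- as_class_index(labels_chr)
  if (length(unique(y)) < 2L) {
    stopf("training set must contain both classes")
  }
  if (is.null(model)) {
    model <- build_hybrid_model(branches, seed = derive_seed(config$seed, 1L),
                                l2_lambda = config$l2_lambda)
  }
  n_epochs <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
  n <- length(train_set)
  flat <- flatten_params(model$params)
  opt <- list(t = 0L,
              m = lapply(flat, function(p) p * 0),
              v = lapply(flat, function(p) p * 0))
  param_paths <- lapply(strsplit(names(flat), ".", fixed = TRUE), identity)
  reg_mask <- vapply(param_paths, function(path) {
    if (path[1] == "head") path[2] == "W" else
      is_regularized_param(path[length(path)])
  }, TRUE)
  epoch_loss <- numeric(n_epochs)
  epoch_acc <- numeric(n_epochs)
  epoch_lr <- numeric(n_epochs)
  total_clipped <- 0L
  lambda <- config$l2_lambda
  # first-layer inputs never change during training: cache each sample's
  # im2col once per fused-capable branch
  cols_cache <- list()
  for (br in names(model$branches)) {
    if (branch_is_fused(model$branches[[br]])) {
      cols_cache[[br]] <- hybrid_branch_cols(model$branches[[br]],
                                             train_set, seq_len(n),
                                             paste0("train.", br))
    }
  }
  batch_inputs <- function(idx) {
    out <- list()
    for (br in names(model$branches)) {
      if (!is.null(cols_cache[[br]])) {
        out[[br]] <- subset_branch_input(cols_cache[[br]], idx)
      } else {
        out[[br]] <- hybrid_batch_arrays(train_set, idx, br)[[br]]
      }
    }
    out
  }
  for (epoch in seq_len(n_epochs) - 1L) {
    lr <- learning_rate_at(config, epoch)
    order <- with_seed(derive_seed(config$seed, 2L, epoch), sample.int(n))
    batch_starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(batch_starts))
    correct <- 0L
    for (bi in seq_along(batch_starts)) {
      idx <- order[batch_starts[bi]:min(batch_starts[bi] +
                                          config$batch_size - 1L, n)]
      B <- length(idx)
      yb <- y[idx]
      inputs <- batch_inputs(idx)
      fw <- model_forward(model, inputs, training = TRUE)
      # batch-norm running statistics
      for (br in names(fw$caches)) {
        for (id in names(fw$caches[[br]]$state_updates)) {
          model$state[[br]][[id]] <- fw$caches[[br]]$state_updates[[id]]
        }
      }
      loss <- classification_loss(fw$probs, yb, model$params, lambda)
      if (!is.finite(loss)) {
        stopf("non-finite loss at epoch %d, batch %d", epoch, bi)
      }
      total_clipped <- total_clipped + attr(loss, "n_clipped")
      losses[bi] <- as.numeric(loss)
      correct <- correct + sum((fw$probs[, 2L] >= fw$probs[, 1L]) == (yb == 1L))
      # backward
      onehot <- matrix(0, B, 2L)
      onehot[cbind(seq_len(B), yb + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / B
      headW <- model$params$head$W
      grads <- list(head = list(W = crossprod(fw$fused, dlogits),
                                b = colSums(dlogits)))
      dfused <- dlogits %*% t(headW)
      off <- 0L
      for (br in names(model$branches)) {
        fd <- model$branches[[br]]$feature_dim
        dfeat <- dfused[, (off + 1L):(off + fd), drop = FALSE]
        off <- off + fd
        cache <- fw$caches[[br]]
        grads[[br]] <- if (!is.null(cache$metas)) {
          fused_branch_backward(model$branches[[br]], model$params[[br]],
                                cache$input, cache$metas, dfeat, tag = br)
        } else {
          branch_backward_pass(model$branches[[br]], model$params[[br]],
                               cache$caches, cache$gap_dims, dfeat, B)
        }
      }
      flat <- flatten_params(model$params)
      flat_grads <- flatten_params(grads)[names(flat)]
      if (lambda > 0) {
        for (k in names(flat)[reg_mask]) {
          flat_grads[[k]] <- flat_grads[[k]] + 2 * lambda * flat[[k]]
        }
      }
      upd <- adam_step(opt, flat, flat_grads, lr, config)
      opt <- upd$opt
      model$params <- unflatten_into(model$params, upd$params, param_paths)
    }
    epoch_loss[epoch + 1L] <- mean(losses)
    epoch_acc[epoch + 1L] <- correct / n
    epoch_lr[epoch + 1L] <- lr
  }
  structure(
    list(model = model, loss = epoch_loss, train_accuracy = epoch_acc,
         lr = epoch_lr, n_clipped = total_clipped, config = config,
         branches = names(model$branches)),
    class = "train_record"
  )
}
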