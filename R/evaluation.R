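#' Inverted stratified cross-validation fold plan
#'
#' Partitions the samples into `n_folds` class-stratified folds.  Under the
#' inverted (few-shot) protocol, fold `f`'s *training* split is exactly the
#' members of fold `f` and its validation split is all remaining samples —
#' so 200 samples with 5 folds give 40 training / 160 validation per fold,
#' and 10 folds give 20 / 180.  Standard cross-validation (train on the
#' other `N - 1` folds) is available behind `inverted = FALSE`.
#'
#' @param labels Character vector of per-sample labels, or a list of labeled
#'   segments/hybrid inputs.
#' @param n_folds Number of folds; each class count must be divisible by it.
#' @param seed Seed for the random stratified assignment.
#' @param task Optional task tag (e.g. `"A_vs_E"`), stored as metadata.
#' @param inverted Use the inverted protocol (default `TRUE`).
#' @return A `fold_plan`: list with `n_folds`, `assignments` (per-sample fold
#'   index), `train_size`, `validation_size`, `task`, `inverted`.
#' @export
make_fold_plan <- function(labels, n_folds, seed = 0L, task = NULL,
                           inverted = TRUE) {
  if (is.list(labels)) labels <- vapply(labels, `[[`, "", "label")
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("need at least 2 folds")
  counts <- table(labels)
  if (any(counts %% n_folds != 0L)) {
    stopf("per-class counts (%s) must be divisible by n_folds = %d",
          paste(counts, collapse = ", "), n_folds)
  }
  assignments <- integer(n)
  for (cls in names(counts)) {
    idx <- which(labels == cls)
    idx <- with_seed(derive_seed(seed, 5L, match(cls, names(counts))),
                     sample(idx))
    assignments[idx] <- rep(seq_len(n_folds), each = length(idx) / n_folds)
  }
  train_size <- if (inverted) n %/% n_folds else n - n %/% n_folds
  structure(
    list(n_folds = n_folds, assignments = assignments,
         train_size = train_size, validation_size = n - train_size,
         task = task, inverted = inverted, seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' Indices of the training and validation splits of one fold
#'
#' @param plan A [make_fold_plan()].
#' @param fold Fold index in `1..n_folds`.
#' @return List with integer vectors `train` and `validation`.
#' @export
fold_split <- function(plan, fold) {
  members <- which(plan$assignments == fold)
  rest <- which(plan$assignments != fold)
  if (plan$inverted) {
    list(train = members, validation = rest)
  } else {
    list(train = rest, validation = members)
  }
}

#' Classification accuracy
#'
#' @param predictions,labels Equal-length vectors of class labels or indices.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stopf("predictions and labels must have equal length")
  }
  if (!length(labels)) stopf("empty input")
  mean(as.character(predictions) == as.character(labels))
}

#' Summarise per-fold accuracies
#'
#' Computes the cross-validation summary statistics used throughout the
#' reporting: the arithmetic mean of the per-fold accuracies and their
#' sample standard deviation (divisor `n - 1`) as the dispersion measure.
#' Reported values are rounded to 4 decimals; full-precision statistics are
#' kept alongside.
#'
#' @param per_fold_accuracy Numeric vector of at least 2 fold accuracies.
#' @param method_label Text tag for reporting (e.g. `"Hybrid"`).
#' @return A `fold_report`: list with `per_fold_accuracy`, `mean_accuracy`,
#'   `dispersion` (full precision), `reported` (4-decimal mean and
#'   dispersion), `method_label`.
#' @examples
#' summarize_folds(c(0.9875, 0.9937, 0.9937, 0.9937, 0.9875))$reported
#' @export
summarize_folds <- function(per_fold_accuracy, method_label = "") {
  if (length(per_fold_accuracy) < 2L) stopf("need at least 2 folds")
  if (any(per_fold_accuracy < 0 | per_fold_accuracy > 1)) {
    stopf("accuracies must lie in [0, 1]")
  }
  m <- mean(per_fold_accuracy)
  s <- stats::sd(per_fold_accuracy)
  structure(
    list(per_fold_accuracy = per_fold_accuracy, mean_accuracy = m,
         dispersion = s,
         reported = c(mean = round(m, 4L), dispersion = round(s, 4L)),
         method_label = method_label),
    class = "fold_report"
  )
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report> %s: folds [%s]  mean %.4f  dispersion %.4f\n",
              ifelse(nzchar(x$method_label), x$method_label, "<unnamed>"),
              paste(sprintf("%.4f", x$per_fold_accuracy), collapse = ", "),
              x$mean_accuracy, x$dispersion))
  invisible(x)
}

method_branches <- list(
  EEG = "raw", FFT = "dft", STFT = "stft", DWT = "dwt",
  Hybrid = c("raw", "dft", "stft", "dwt")
)

#' Run one cross-validated few-shot experiment
#'
#' For a labeled segment set, builds the model variant for `method` (one
#' branch for the single-input baselines `EEG`, `FFT`, `STFT`, `DWT`; all
#' four for `Hybrid`), trains it from scratch on each fold's training split
#' under the inverted protocol, evaluates on that fold's validation split,
#' and summarises the per-fold accuracies.
#'
#' @param samples List of labeled [eeg_segment]s, or an already transformed
#'   `hybrid_set`.
#' @param method One of `"EEG"`, `"FFT"`, `"STFT"`, `"DWT"`, `"Hybrid"`.
#' @param n_folds Number of folds.
#' @param train_cfg A [train_config()].
#' @param seed Master seed; fold assignment and per-fold model seeds derive
#'   from it.
#' @param transform_cfg A [transform_config()] (used when `samples` are raw
#'   segments).
#' @param epochs Optional reduced epoch budget passed to [train_model()].
#' @param inverted Inverted-CV semantics (default) or standard CV.
#' @return A `fold_report` (see [summarize_folds()]) with the per-fold
#'   details in attribute `"folds"`.
#' @export
run_experiment <- function(samples, method = "Hybrid", n_folds = 5L,
                           train_cfg = train_config(), seed = 0L,
                           transform_cfg = transform_config(),
                           epochs = NULL, inverted = TRUE) {
  method <- match.arg(method, names(method_branches))
  branches <- method_branches[[method]]
  hybrids <- if (inherits(samples, "hybrid_set")) samples else
    make_hybrid_set(samples, transform_cfg)
  labels <- vapply(hybrids, `[[`, "", "label")
  plan <- make_fold_plan(labels, n_folds, seed = derive_seed(seed, 7L),
                         inverted = inverted)
  per_fold <- numeric(n_folds)
  details <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sp <- fold_split(plan, f)
    cfg <- train_cfg
    cfg$seed <- derive_seed(seed, 9L, f)
    rec <- tryCatch(
      train_model(hybrids[sp$train], cfg, branches = branches,
                  epochs = epochs),
      error = function(e) stopf("fold %d: %s", f, conditionMessage(e))
    )
    probs <- predict_proba(rec$model, hybrids[sp$validation])
    preds <- predict_classes(probs)
    per_fold[f] <- accuracy(preds, labels[sp$validation])
    details[[f]] <- list(train_size = length(sp$train),
                         validation_size = length(sp$validation),
                         final_loss = rec$loss[length(rec$loss)],
                         train_accuracy = rec$train_accuracy[length(rec$train_accuracy)])
  }
  report <- summarize_folds(per_fold, method_label = method)
  attr(report, "folds") <- details
  attr(report, "plan") <- plan
  report
}
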