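#' Write fold reports as a cross-validation results table
#'
#' Emits a CSV shaped like the published performance tables: one row per
#' method with columns `Method`, `K1 ... KN`, `Mean`, `Variance`, all
#' numeric cells formatted to 4 decimals.  (`Variance` holds the
#' sample-standard-deviation dispersion statistic of [summarize_folds()].)
#'
#' @param reports A `fold_report` or list of them (equal fold counts).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "fold_report")) reports <- list(reports)
  n_folds <- length(reports[[1L]]$per_fold_accuracy)
  rows <- lapply(reports, function(r) {
    if (length(r$per_fold_accuracy) != n_folds) {
      stopf("all reports must have the same fold count")
    }
    c(Method = r$method_label,
      stats::setNames(sprintf("%.4f", r$per_fold_accuracy),
                      paste0("K", seq_len(n_folds))),
      Mean = sprintf("%.4f", r$mean_accuracy),
      Variance = sprintf("%.4f", r$dispersion))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stopf("cannot write '%s': %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

#' Read a results table written by [write_report()]
#'
#' @param path CSV path.
#' @return Data frame with `Method` (character) and numeric fold/summary
#'   columns.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "Method")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Assemble a reproducibility manifest for a run
#'
#' Captures everything needed to reproduce a run under the determinism
#' contract: the full configuration, the master seed and derived per-fold
#' seeds, artifact paths, and the package version.
#'
#' @param seed Master seed.
#' @param n_folds Fold count (per-fold seeds are derived as in
#'   [run_experiment()]).
#' @param transform_cfg,train_cfg,synth_cfg Configuration objects (optional).
#' @param artifacts Named character vector/list of output paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seed, n_folds = NULL, transform_cfg = NULL,
                         train_cfg = NULL, synth_cfg = NULL,
                         artifacts = list()) {
  cfg <- list(transform = if (!is.null(transform_cfg)) unclass(transform_cfg),
              train = if (!is.null(train_cfg)) unclass(train_cfg),
              synth = if (!is.null(synth_cfg)) unclass(synth_cfg))
  structure(
    list(tool = "eegfuse",
         version = as.character(utils::packageVersion("eegfuse")),
         master_seed = as.integer(seed),
         fold_seeds = if (!is.null(n_folds))
           vapply(seq_len(n_folds), function(f) derive_seed(seed, 9L, f), 1L),
         config = cfg, config_hash = config_hash(cfg),
         artifacts = as.list(artifacts),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Save / load a trained model
#'
#' Weights and batch-norm state go into one portable RDS container; the
#' architecture and training configuration are additionally mirrored into a
#' JSON sidecar for inspection.
#'
#' @param model A `hybrid_model` (or a full `train_record`).
#' @param path Output path.
#' @return `path` (save) / the model object (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  m <- if (inherits(model, "train_record")) model$model else model
  meta <- list(branches = names(m$branches), head_dim = m$head_dim,
               l2_lambda = m$l2_lambda,
               parameters = count_parameters(m)$breakdown)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Per-layer summary of a model
#'
#' Prints one line per convolution stage with kernel shape, channels, and
#' parameter count, plus the head and total (the lightweight-design audit).
#'
#' @param model A `hybrid_model`.
#' @return Data frame of the printed table, invisibly.
#' @export
model_summary <- function(model) {
  rows <- list()
  for (br in names(model$branches)) {
    spec <- model$branches[[br]]
    for (i in seq_along(spec$stages)) {
      st <- spec$stages[[i]]
      p <- model$params[[br]][[paste0("s", i)]]
      n <- sum(vapply(p, length, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        branch = br, stage = i,
        layer = if (st$kind == "conv") "Conv" else "DConv",
        kernel = paste(st$kernel, collapse = "x"),
        channels = sprintf("%d->%d", st$cin, st$cout),
        params = n)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    branch = "head", stage = NA, layer = "Dense",
    kernel = sprintf("%dx2", model$head_dim), channels = "",
    params = length(model$params$head$W) + length(model$params$head$b))
  df <- do.call(rbind, rows)
  print(df, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n",
              count_parameters(model)$total))
  invisible(df)
}
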