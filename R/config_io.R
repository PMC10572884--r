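#' Save / load a fitted Double U-Net
#'
#' Checkpoints are plain RDS serializations of the `dunet` object (weights,
#' configuration, training history).
#'
#' @param model a `dunet`.
#' @param path checkpoint file path.
#' @export
save_dunet <- function(model, path) {
  if (!inherits(model, "dunet")) stop("model must be a dunet", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dunet
#' @return `load_dunet()` returns the restored `dunet`.
#' @export
load_dunet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dunet")) stop("file does not contain a dunet", call. = FALSE)
  model
}

#' Build an experiment configuration from a YAML file
#'
#' The file may contain any [experiment_config()] fields plus nested
#' `network:` ([network_config()] fields) and `loss_config:`
#' ([loss_config()] fields) blocks, e.g.
#'
#' ```yaml
#' n_folds: 10
#' nm_method: otsu
#' add_negatives: true
#' loss: focal_tversky
#' loss_config: {alpha: 0.3, beta: 0.7, gamma: 0.75}
#' network: {input_shape: [640, 512], encoder_widths: [16, 32, 64]}
#' ```
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  args <- spec
  args$network <- if (is.null(spec$network)) network_config()
  else do.call(network_config, spec$network)
  args$loss_config <- if (is.null(spec$loss_config)) loss_config()
  else do.call(loss_config, spec$loss_config)
  do.call(experiment_config, args)
}

#' Write per-fold and aggregate cross-validation metrics to CSV and JSON
#'
#' @param result a `cv_result` from [run_cv()] or [run_transfer()].
#' @param path_prefix output prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return data frame of the emitted table, invisibly.
#' @export
write_cv_results <- function(result, path_prefix) {
  df <- as.data.frame(result)
  utils::write.csv(df, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = list(nm_method = result$config$nm_method,
                       loss = result$config$loss,
                       n_folds = result$config$n_folds,
                       iterations = result$config$iterations,
                       seed = result$config$seed),
         cohort = result$cohort, folds = df),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(df)
}

#' @export
as.data.frame.cv_result <- function(x, ...) {
  ok <- Filter(function(f) !isTRUE(f$failed), x$folds)
  df <- do.call(rbind, lapply(ok, function(f)
    data.frame(fold = f$fold_id,
               precision = round_half_up(f$metrics$precision),
               sensitivity = round_half_up(f$metrics$sensitivity),
               f1 = round_half_up(f$metrics$f1))))
  if (length(ok)) {
    agg <- aggregate_folds(ok)
    df <- rbind(df, data.frame(fold = NA, precision = agg$precision,
                               sensitivity = agg$sensitivity, f1 = agg$f1))
  }
  df
}

#' Pixel-level metrics over a set of predictions
#'
#' Micro averaging (the reporting default) pools confusion counts over all
#' images before computing metrics; macro averaging computes metrics per
#' image and averages the records (aggregate F1 again as the harmonic mean
#' of the mean precision and sensitivity).
#'
#' @param pred_list list of class matrices or `prediction_map`s.
#' @param truth_list list of class matrices or `label_map`s.
#' @param positive_class 0-based positive class id (default M = 2).
#' @param average `"micro"` or `"macro"`.
#' @return a `metrics_record`.
#' @export
segmentation_metrics <- function(pred_list, truth_list, positive_class = 2L,
                                 average = c("micro", "macro")) {
  average <- match.arg(average)
  counts <- Map(function(p, t) confusion(p, t, positive_class),
                pred_list, truth_list)
  if (average == "micro") return(metrics_from_counts(sum_confusion(counts)))
  aggregate_folds(lapply(counts, metrics_from_counts), digits = Inf)
}
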