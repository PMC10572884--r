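#' Pixel-level confusion counts
#'
#' Counts true/false positives/negatives treating `positive_class` (the
#' metastasis class) as positive and every other class as negative.
#'
#' @param pred_classes,truth_classes integer matrices of class ids (or
#'   `prediction_map` / `label_map` objects) of identical shape.
#' @param positive_class 0-based id of the positive class (default M = 2).
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` summing to the number of pixels.
#' @export
confusion <- function(pred_classes, truth_classes, positive_class = 2L) {
  if (inherits(pred_classes, "prediction_map")) pred_classes <- pred_classes$classes
  if (inherits(truth_classes, "label_map")) truth_classes <- truth_classes$classes
  if (!identical(dim(pred_classes), dim(truth_classes)))
    stop_dim("pred and truth must share dimensions")
  p <- pred_classes == positive_class
  t <- truth_classes == positive_class
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# Sum confusion counts across images (micro / pooled-pixel evaluation).
sum_confusion <- function(counts) {
  structure(list(tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
                 fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
                 tn = sum(vapply(counts, `[[`, numeric(1), "tn")),
                 fn = sum(vapply(counts, `[[`, numeric(1), "fn"))),
            class = "confusion_counts")
}

#' Precision, sensitivity and F1 from confusion counts
#'
#' Precision = 100 TP / (TP + FP), sensitivity = 100 TP / (TP + FN), F1 is
#' their harmonic mean — all in percent. Degenerate 0/0 ratios are defined
#' as 0.
#'
#' @param counts a `confusion_counts`.
#' @return object of class `metrics_record` with `precision`, `sensitivity`,
#'   `f1` (percent, full precision; rounding happens at reporting time).
#' @export
metrics_from_counts <- function(counts) {
  ratio <- function(num, den) if (den == 0) 0 else 100 * num / den
  precision <- ratio(counts$tp, counts$tp + counts$fp)
  sensitivity <- ratio(counts$tp, counts$tp + counts$fn)
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  metrics_record(precision, sensitivity, f1)
}

#' Construct a metrics record
#'
#' @param precision,sensitivity,f1 percentages in \[0, 100\]; if `f1` is
#'   `NULL` it is computed as the harmonic mean of the other two.
#' @return object of class `metrics_record`.
#' @export
metrics_record <- function(precision, sensitivity, f1 = NULL) {
  if (is.null(f1))
    f1 <- if (precision + sensitivity == 0) 0 else
      2 * precision * sensitivity / (precision + sensitivity)
  structure(list(precision = precision, sensitivity = sensitivity, f1 = f1),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, digits = 2, ...) {
  cat(sprintf("precision %.2f  sensitivity %.2f  F1 %.2f\n",
              round_half_up(x$precision, digits),
              round_half_up(x$sensitivity, digits),
              round_half_up(x$f1, digits)))
  invisible(x)
}

#' Aggregate per-fold metrics the way cross-validation tables report them
#'
#' The aggregate precision and sensitivity are the arithmetic means of the
#' per-fold values; the aggregate F1 is the harmonic mean of those two means
#' (not the mean of per-fold F1 values — this is the convention that
#' reproduces published 10-fold "Mean" rows). Values are rounded half-up to
#' `digits` decimals, matching table formatting.
#'
#' @param folds list of `metrics_record`s (or a data frame with `precision`
#'   and `sensitivity` columns).
#' @param digits decimals for reporting; `Inf` disables rounding.
#' @return aggregate `metrics_record`.
#' @export
aggregate_folds <- function(folds, digits = 2) {
  if (is.data.frame(folds)) {
    prec <- folds$precision; sens <- folds$sensitivity
  } else {
    if (length(folds) == 0) stop("no folds to aggregate", call. = FALSE)
    prec <- vapply(folds, function(f) {
      if (inherits(f, "fold_result")) f <- f$metrics
      f$precision
    }, numeric(1))
    sens <- vapply(folds, function(f) {
      if (inherits(f, "fold_result")) f <- f$metrics
      f$sensitivity
    }, numeric(1))
  }
  if (length(prec) == 0) stop("no folds to aggregate", call. = FALSE)
  r <- function(v) if (is.finite(digits)) round_half_up(v, digits) else v
  mp <- r(mean(prec)); ms <- r(mean(sens))
  f1 <- if (mp + ms == 0) 0 else 2 * mp * ms / (mp + ms)
  metrics_record(mp, ms, r(f1))
}

#' Componentwise improvement between two metric records
#'
#' `a - b` per metric, rounded half-up to two decimals for reporting, as in
#' published improvement deltas.
#'
#' @param a,b `metrics_record`s.
#' @param digits decimals for rounding.
#' @return named numeric vector with `precision`, `sensitivity`, `f1`.
#' @export
improvement <- function(a, b, digits = 2) {
  round_half_up(c(precision = a$precision - b$precision,
                  sensitivity = a$sensitivity - b$sensitivity,
                  f1 = a$f1 - b$f1), digits)
}

#' Reference 10-fold cross-validation tables
#'
#' Per-fold pixel-level precision/sensitivity/F1 of the clinical 10-fold
#' benchmark experiments (baseline two-class training; Otsu three-class with
#' and without added negative samples; negative-mining three-class with and
#' without added negatives; transfer learning), for Dice and focal Tversky
#' losses, together with the published aggregate ("mean") rows. Shipped as a
#' plain-text fixture and used to validate the package's metric arithmetic
#' and fold-aggregation conventions.
#'
#' @return data frame with columns `experiment`, `loss`, `fold` (1..10, or
#'   `"mean"` for the published aggregate row), `precision`, `sensitivity`,
#'   `f1`.
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_fold_metrics.tsv",
                      package = "boneseg", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    experiment = "character", loss = "character", fold = "character",
    precision = "numeric", sensitivity = "numeric", f1 = "numeric"))
}
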