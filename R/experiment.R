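#' Experiment configuration for the cross-validation harness
#'
#' Defaults mirror the clinical training protocol: 10-fold cross-validation
#' with an 8:1:1 train:validation:test split of the positive samples,
#' learning rate 1e-4, batch size 4, 500 training iterations. Desk-scale
#' phantom experiments override folds, iterations and the network preset.
#'
#' @param n_folds number of cross-validation folds.
#' @param split_ratio 3-vector of train:validation:test proportions.
#' @param learning_rate,batch_size,iterations,iteration_unit passed to
#'   [train_dunet()].
#' @param nm_method label construction: `"none"` (two-class baseline),
#'   `"otsu"` or `"mining"`.
#' @param add_negatives append all negative samples to every fold's training
#'   set (test sets are unaffected).
#' @param network a [network_config()].
#' @param loss `"dice"` or `"focal_tversky"`.
#' @param loss_config a [loss_config()].
#' @param mining_iterations iterations for the per-fold positive-only model
#'   that negative mining requires (defaults to `iterations`).
#' @param seed master seed; splits, initialization and shuffling all derive
#'   from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_folds = 10L, split_ratio = c(8, 1, 1),
                              learning_rate = 1e-4, batch_size = 4L,
                              iterations = 500L,
                              iteration_unit = c("epochs", "steps"),
                              nm_method = c("otsu", "none", "mining"),
                              add_negatives = FALSE,
                              network = network_config(),
                              loss = c("dice", "focal_tversky"),
                              loss_config = default_loss_config(),
                              mining_iterations = NULL,
                              seed = 1L) {
  nm_method <- match.arg(nm_method)
  loss <- match.arg(loss)
  iteration_unit <- match.arg(iteration_unit)
  if (length(split_ratio) != 3 || any(split_ratio < 0) || split_ratio[1] <= 0)
    stop("configuration error: split_ratio must be 3 non-negative proportions",
         call. = FALSE)
  if (learning_rate <= 0 || batch_size < 1 || iterations < 1 || n_folds < 2)
    stop("configuration error: hyperparameters must be positive", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds), split_ratio = split_ratio,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 iteration_unit = iteration_unit,
                 nm_method = nm_method, add_negatives = add_negatives,
                 network = network, loss = loss, loss_config = loss_config,
                 mining_iterations = if (is.null(mining_iterations)) NULL
                 else as.integer(mining_iterations),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Dataset specification: positive and negative samples
#'
#' @param positives list of samples with non-empty metastasis masks; each
#'   sample is a list with `image` (numeric matrix) and `m_mask` (logical
#'   matrix).
#' @param negatives list of lesion-free samples (`m_mask` all `FALSE` or
#'   absent).
#' @param cohort_tag label for reporting.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(positives, negatives = list(), cohort_tag = "cohort") {
  chk <- function(s, need_lesions) {
    stopifnot(is.list(s), is.matrix(s$image))
    if (is.null(s$m_mask)) s$m_mask <- matrix(FALSE, nrow(s$image), ncol(s$image))
    if (!need_lesions && any(s$m_mask))
      stop("configuration error: negative samples must have empty M masks",
           call. = FALSE)
    s
  }
  structure(list(positives = lapply(positives, chk, need_lesions = TRUE),
                 negatives = lapply(negatives, chk, need_lesions = FALSE),
                 cohort_tag = cohort_tag),
            class = "dataset_spec")
}

#' Build a phantom dataset at network scale
#'
#' Generates a seeded cohort of single-view phantoms sized directly for the
#' network input (no clinical-geometry pre-processing), normalizes each view's
#' brightness, and wraps it as a [dataset_spec()]. High-contrast lesions on a
#' moderate body background make tiny training runs informative.
#'
#' @param n_positive,n_negative sample counts.
#' @param base_seed cohort seed.
#' @param image_size `c(rows, cols)` of the images.
#' @param n_lesion_range per-positive lesion count interval.
#' @param normalize apply [normalize_brightness()] to each view.
#' @param config optional [phantom_config()] template.
#' @param cohort_tag forwarded to [dataset_spec()].
#' @return a `dataset_spec`.
#' @export
phantom_dataset <- function(n_positive, n_negative, base_seed,
                            image_size = c(64L, 64L),
                            n_lesion_range = c(1L, 3L), normalize = TRUE,
                            config = NULL, cohort_tag = "phantom") {
  if (is.null(config))
    config <- phantom_config(view_shape = image_size)
  else
    config$view_shape <- as.integer(image_size)
  cohort <- generate_cohort(n_positive, n_negative, base_seed, config,
                            n_lesion_range = n_lesion_range)
  to_sample <- function(s) {
    img <- s$ap_view
    if (normalize) {
      img <- normalize_brightness(img)
      attr(img, "gain") <- NULL
    }
    list(image = img, m_mask = s$lesion_mask_ap, silhouette = s$silhouette_ap)
  }
  pos <- lapply(cohort[seq_len(n_positive)], to_sample)
  neg <- if (n_negative > 0)
    lapply(cohort[n_positive + seq_len(n_negative)], to_sample) else list()
  dataset_spec(pos, neg, cohort_tag)
}

#' Partition a dataset into cross-validation folds
#'
#' Positives are shuffled (seeded) and partitioned into `n_folds` disjoint
#' test sets; each fold's remaining positives split into training and
#' validation by the configured ratio. When `add_negatives` is set, every
#' negative sample joins every fold's training set — never its validation or
#' test set.
#'
#' @param spec a [dataset_spec()].
#' @param config an [experiment_config()].
#' @return list of fold assignments: each a list with integer index vectors
#'   `test`, `val`, `train` (into `spec$positives`) and `train_neg` (into
#'   `spec$negatives`).
#' @export
make_folds <- function(spec, config) {
  n <- length(spec$positives)
  if (n < config$n_folds)
    stop("configuration error: need at least one positive sample per fold",
         call. = FALSE)
  local_seed(derive_seed(config$seed, 0L), {
    perm <- sample.int(n)
    test_sets <- split(perm, cut(seq_len(n), config$n_folds, labels = FALSE))
    lapply(seq_len(config$n_folds), function(k) {
      test <- sort(test_sets[[k]])
      rest <- perm[!perm %in% test]
      n_val <- round(length(rest) * config$split_ratio[2] /
                       (config$split_ratio[1] + config$split_ratio[2]))
      n_val <- min(max(n_val, if (config$split_ratio[2] > 0) 1L else 0L),
                   length(rest) - 1L)
      val <- if (n_val > 0) sort(utils::head(rest, n_val)) else integer(0)
      train <- sort(setdiff(rest, val))
      list(fold_id = k, test = test, val = val, train = train,
           train_neg = if (config$add_negatives)
             seq_along(spec$negatives) else integer(0))
    })
  })
}

# Build label maps for a set of samples under the configured NM method.
build_labels <- function(samples, nm_method, miner = NULL) {
  lapply(samples, function(s) {
    switch(nm_method,
      none = encode_two_class(s$m_mask),
      otsu = encode_three_class(make_nm_mask_otsu(s$image, s$m_mask), s$m_mask),
      mining = {
        nm <- if (any(s$m_mask))
          mine_positive_masks(miner, list(s$image), list(s$m_mask))[[1]]
        else mine_negative_masks(miner, list(s$image))[[1]]
        encode_three_class(nm, s$m_mask)
      })
  })
}

# Network configuration consistent with the label scheme.
net_config_for <- function(config) {
  nc <- config$network
  nc$n_classes <- if (config$nm_method == "none") 2L else 3L
  nc
}

#' Run the cross-validated training protocol
#'
#' For each fold: builds label maps under the configured NM-mask method
#' (negative mining first trains a fold-local positive-only baseline model,
#' avoiding test-set leakage), trains the Double U-Net on the fold's
#' training samples, and evaluates pixel-pooled metastasis-class metrics on
#' the fold's held-out positive test samples.
#'
#' @param spec a [dataset_spec()].
#' @param config an [experiment_config()].
#' @param init optional pretrained `dunet` used to initialize every fold
#'   (transfer learning).
#' @param folds optional precomputed [make_folds()] output.
#' @return object of class `cv_result`: list of `fold_result`s (each with
#'   `fold_id`, `metrics`, `counts`) plus the configuration; its
#'   [aggregate_folds()]-based summary prints like a cross-validation table.
#' @export
run_cv <- function(spec, config, init = NULL, folds = NULL) {
  if (is.null(folds)) folds <- make_folds(spec, config)
  m_class <- if (config$nm_method == "none") 1L else 2L
  nc <- net_config_for(config)
  results <- lapply(folds, function(fold) {
    train_pos <- spec$positives[fold$train]
    train_neg <- spec$negatives[fold$train_neg]
    miner <- NULL
    if (config$nm_method == "mining") {
      mit <- if (is.null(config$mining_iterations)) config$iterations
      else config$mining_iterations
      miner_cfg <- nc; miner_cfg$n_classes <- 2L
      miner <- train_dunet(lapply(train_pos, `[[`, "image"),
                           lapply(train_pos, function(s) encode_two_class(s$m_mask)),
                           config = miner_cfg, loss = config$loss,
                           loss_config = config$loss_config,
                           lr = config$learning_rate,
                           batch_size = config$batch_size, iterations = mit,
                           iteration_unit = config$iteration_unit,
                           seed = derive_seed(config$seed, 100L + fold$fold_id))
    }
    train_all <- c(train_pos, train_neg)
    labels <- build_labels(train_all, config$nm_method, miner)
    val <- if (length(fold$val) > 0) {
      vs <- spec$positives[fold$val]
      list(x = lapply(vs, `[[`, "image"),
           y = build_labels(vs, config$nm_method, miner))
    } else NULL
    model <- tryCatch(
      train_dunet(lapply(train_all, `[[`, "image"), labels, config = nc,
                  loss = config$loss, loss_config = config$loss_config,
                  lr = config$learning_rate, batch_size = config$batch_size,
                  iterations = config$iterations,
                  iteration_unit = config$iteration_unit,
                  seed = derive_seed(config$seed, fold$fold_id),
                  init = init, validation = val),
      error = function(e) e)
    if (inherits(model, "error")) {
      warning(sprintf("fold %d failed: %s", fold$fold_id, conditionMessage(model)))
      return(structure(list(fold_id = fold$fold_id, metrics = NULL,
                            counts = NULL, failed = TRUE,
                            message = conditionMessage(model)),
                       class = "fold_result"))
    }
    counts <- sum_confusion(lapply(spec$positives[fold$test], function(s) {
      pred <- stats::predict(model, s$image)
      truth <- if (config$nm_method == "none") encode_two_class(s$m_mask)
      else {
        cl <- matrix(0L, nrow(s$m_mask), ncol(s$m_mask))
        cl[s$m_mask] <- m_class
        structure(list(classes = cl, n_classes = 3L), class = "label_map")
      }
      confusion(pred, truth, positive_class = m_class)
    }))
    structure(list(fold_id = fold$fold_id,
                   metrics = metrics_from_counts(counts),
                   counts = counts, failed = FALSE),
              class = "fold_result")
  })
  structure(list(folds = results, config = config, cohort = spec$cohort_tag),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  ok <- Filter(function(f) !isTRUE(f$failed), x$folds)
  cat(sprintf("cross-validation (%s, nm_method=%s, loss=%s): %d/%d folds\n",
              x$cohort, x$config$nm_method, x$config$loss,
              length(ok), length(x$folds)))
  for (f in ok)
    cat(sprintf("  fold %2d: precision %6.2f  sensitivity %6.2f  F1 %6.2f\n",
                f$fold_id, round_half_up(f$metrics$precision),
                round_half_up(f$metrics$sensitivity),
                round_half_up(f$metrics$f1)))
  if (length(ok)) {
    agg <- aggregate_folds(ok)
    cat(sprintf("  mean:     precision %6.2f  sensitivity %6.2f  F1 %6.2f\n",
                agg$precision, agg$sensitivity, agg$f1))
  }
  invisible(x)
}

#' Pretrain on one cohort, then run cross-validated fine-tuning on another
#'
#' One pretraining pass over the full pretraining cohort (labels built with
#' the configured NM method; negatives added when configured), then [run_cv()]
#' on the target cohort with every fold's model initialized from the
#' pretrained weights.
#'
#' @param pretrain_spec,finetune_spec [dataset_spec()]s with identical image
#'   geometry.
#' @param config an [experiment_config()]; `pretrain_iterations` overrides
#'   the iteration budget of the pretraining phase.
#' @param pretrain_iterations iterations for the pretraining phase (defaults
#'   to `config$iterations`).
#' @return a `cv_result` with the pretrained model attached as `pretrained`.
#' @export
run_transfer <- function(pretrain_spec, finetune_spec, config,
                         pretrain_iterations = NULL) {
  if (config$nm_method == "mining")
    stop("configuration error: transfer pretraining uses otsu or none labels",
         call. = FALSE)
  nc <- net_config_for(config)
  samples <- c(pretrain_spec$positives,
               if (config$add_negatives) pretrain_spec$negatives else list())
  labels <- build_labels(samples, config$nm_method)
  it <- if (is.null(pretrain_iterations)) config$iterations
  else as.integer(pretrain_iterations)
  pre <- train_dunet(lapply(samples, `[[`, "image"), labels, config = nc,
                     loss = config$loss, loss_config = config$loss_config,
                     lr = config$learning_rate, batch_size = config$batch_size,
                     iterations = it, iteration_unit = config$iteration_unit,
                     seed = derive_seed(config$seed, 999L))
  out <- run_cv(finetune_spec, config, init = pre)
  out$pretrained <- pre
  out
}
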