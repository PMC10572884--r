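make_tiny_spec <- function(n_pos = 8, n_neg = 3, seed = 51)
  phantom_dataset(n_pos, n_neg, base_seed = seed, image_size = c(32, 32))

tiny_exp_config <- function(..., iterations = 20, seed = 1)
  experiment_config(n_folds = 2, iterations = iterations,
                    iteration_unit = "steps", learning_rate = 1e-3,
                    batch_size = 4, network = tiny_net(), seed = seed, ...)

test_that("fold assignments partition positives without leakage", {
  spec <- phantom_dataset(12, 3, base_seed = 52, image_size = c(32, 32))
  cfg <- experiment_config(n_folds = 4, network = tiny_net(),
                           add_negatives = TRUE, seed = 3)
  folds <- make_folds(spec, cfg)
  expect_length(folds, 4)
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, 1:12)   # each positive in exactly one test set
  for (f in folds) {
    expect_length(intersect(f$test, f$train), 0)
    expect_length(intersect(f$test, f$val), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_identical(sort(c(f$test, f$train, f$val)), 1:12)
    expect_identical(f$train_neg, 1:3)  # negatives join every training set
  }
})

test_that("fold splits are deterministic in the seed and honor the ratio", {
  spec <- phantom_dataset(10, 0, base_seed = 53, image_size = c(32, 32))
  cfg <- tiny_exp_config()
  expect_identical(make_folds(spec, cfg), make_folds(spec, cfg))
  cfg2 <- tiny_exp_config(seed = 2)
  expect_false(identical(make_folds(spec, cfg), make_folds(spec, cfg2)))
  # 8:1:1-style split: with 10 positives and 2 folds, 5 test, 1 val, 4 train
  f <- make_folds(spec, cfg)[[1]]
  expect_length(f$test, 5)
  expect_length(f$val, 1)
  expect_length(f$train, 4)
  expect_error(make_folds(phantom_dataset(1, 0, 54, image_size = c(32, 32)),
                          cfg), "positive")
})

test_that("adding negatives changes only the training sets", {
  spec <- make_tiny_spec()
  with_neg <- make_folds(spec, tiny_exp_config(add_negatives = TRUE))
  without <- make_folds(spec, tiny_exp_config(add_negatives = FALSE))
  for (k in seq_along(with_neg)) {
    expect_identical(with_neg[[k]]$test, without[[k]]$test)
    expect_identical(with_neg[[k]]$val, without[[k]]$val)
    expect_identical(with_neg[[k]]$train, without[[k]]$train)
    expect_length(without[[k]]$train_neg, 0)
    expect_length(with_neg[[k]]$train_neg, length(spec$negatives))
  }
})

test_that("negative samples with lesions are rejected by the dataset spec", {
  s <- generate_phantom(phantom_config(seed = 1, n_lesions = 1,
                                       view_shape = c(32, 32)))
  bad <- list(image = s$ap_view, m_mask = s$lesion_mask_ap)
  expect_error(dataset_spec(list(), list(bad)), "negative samples")
})

test_that("a scaled cross-validation run emits valid fold records", {
  spec <- make_tiny_spec()
  res <- run_cv(spec, tiny_exp_config(nm_method = "otsu", add_negatives = TRUE))
  expect_s3_class(res, "cv_result")
  expect_length(res$folds, 2)
  for (f in res$folds) {
    expect_false(f$failed)
    m <- f$metrics
    expect_true(all(c(m$precision, m$sensitivity, m$f1) >= 0))
    expect_true(all(c(m$precision, m$sensitivity, m$f1) <= 100))
    expect_equal(f$counts$tp + f$counts$fp + f$counts$tn + f$counts$fn,
                 4 * 32 * 32)   # pooled pixels of the fold's 4 test images
  }
  expect_output(print(res), "cross-validation")
})

test_that("the baseline protocol runs with two classes and no NM masks", {
  spec <- make_tiny_spec(n_pos = 6, n_neg = 0)
  res <- run_cv(spec, tiny_exp_config(nm_method = "none"))
  expect_length(res$folds, 2)
  expect_true(all(vapply(res$folds, function(f) !f$failed, logical(1))))
})

test_that("negative mining inside cross-validation stays fold-local and runs", {
  spec <- make_tiny_spec(n_pos = 6, n_neg = 2)
  res <- run_cv(spec, tiny_exp_config(nm_method = "mining", add_negatives = TRUE,
                                      mining_iterations = 10))
  expect_length(res$folds, 2)
  expect_true(all(vapply(res$folds, function(f) !f$failed, logical(1))))
})

test_that("seeded experiment runs are bit-reproducible", {
  spec <- make_tiny_spec(n_pos = 6, n_neg = 0)
  cfg <- tiny_exp_config(nm_method = "otsu", iterations = 10)
  r1 <- run_cv(spec, cfg)
  r2 <- run_cv(spec, cfg)
  for (k in 1:2)
    expect_identical(r1$folds[[k]]$metrics, r2$folds[[k]]$metrics)
})

test_that("transfer learning initializes every fold from the pretrained weights", {
  pre_spec <- make_tiny_spec(n_pos = 6, n_neg = 2, seed = 61)
  pre_samples <- pre_spec$positives
  pre <- train_dunet(
    lapply(pre_samples, `[[`, "image"),
    lapply(pre_samples, function(s)
      encode_three_class(make_nm_mask_otsu(s$image, s$m_mask), s$m_mask)),
    config = tiny_net(), loss = "focal_tversky", lr = 1e-3, batch_size = 4,
    iterations = 10, iteration_unit = "steps", seed = 8)
  # a fine-tuning step with zero learning rate keeps the pretrained weights
  tuned <- train_dunet(list(pre_samples[[1]]$image),
                       list(encode_three_class(
                         make_nm_mask_otsu(pre_samples[[1]]$image,
                                           pre_samples[[1]]$m_mask),
                         pre_samples[[1]]$m_mask)),
                       config = tiny_net(), loss = "focal_tversky", lr = 0,
                       batch_size = 1, iterations = 2, iteration_unit = "steps",
                       seed = 9, init = pre)
  expect_identical(tuned$net1, pre$net1)
  expect_identical(tuned$net2, pre$net2)
  # architecture mismatch between phases is refused
  expect_error(train_dunet(list(pre_samples[[1]]$image),
                           list(encode_two_class(pre_samples[[1]]$m_mask)),
                           config = tiny_net(n_classes = 2L), init = pre,
                           iterations = 1, iteration_unit = "steps"),
               "architecture")
})

test_that("the two-phase transfer protocol completes end to end", {
  pre_spec <- make_tiny_spec(n_pos = 6, n_neg = 2, seed = 62)
  fit_spec <- make_tiny_spec(n_pos = 6, n_neg = 2, seed = 63)
  cfg <- tiny_exp_config(nm_method = "otsu", add_negatives = TRUE,
                         iterations = 10)
  res <- run_transfer(pre_spec, fit_spec, cfg, pretrain_iterations = 10)
  expect_s3_class(res, "cv_result")
  expect_s3_class(res$pretrained, "dunet")
  expect_true(all(vapply(res$folds, function(f) !f$failed, logical(1))))
})
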