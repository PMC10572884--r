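test_that("the fast Otsu equals exhaustive between-class-variance search", {
  set.seed(1)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 400, TRUE, prob = stats::runif(256)), 20, 20)
    expect_identical(otsu_threshold(img), brute_otsu(img))
  }
  for (seed in c(1, 3)) {
    s <- generate_phantom(phantom_config(seed = seed, n_lesions = 1,
                                         view_shape = c(128, 64)))
    expect_identical(otsu_threshold(s$ap_view), brute_otsu(s$ap_view))
  }
})

test_that("Otsu separates a two-valued image and shifts with the intensities", {
  img <- matrix(50, 20, 20); img[1:6, ] <- 200
  t0 <- otsu_threshold(img)
  # every threshold in [50, 200) separates the two values; the tie-break
  # picks the smallest
  expect_gte(t0, 50); expect_lt(t0, 200)
  expect_true(all(img[img > t0] == 200) && all(img[img <= t0] == 50))
  s <- generate_phantom(phantom_config(seed = 5, n_lesions = 1,
                                       view_shape = c(128, 64)))
  base <- otsu_threshold(pmin(s$ap_view, 200))
  expect_identical(otsu_threshold(pmin(s$ap_view, 200) + 30), base + 30L)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("Otsu NM masks match the generator silhouette on negatives", {
  s <- generate_phantom(phantom_config(seed = 8, n_lesions = 0))
  nm <- make_nm_mask_otsu(s$ap_view)
  expect_identical(nm$method, "otsu")
  expect_identical(nm$source_polarity, "negative")
  expect_gte(mean(nm$mask == s$silhouette_ap), 0.99)
})

test_that("Otsu NM masks exclude every metastasis pixel on positives", {
  s <- generate_phantom(phantom_config(seed = 9, n_lesions = 3,
                                       view_shape = c(256, 128)))
  nm <- make_nm_mask_otsu(s$ap_view, s$lesion_mask_ap)
  expect_identical(nm$source_polarity, "positive")
  expect_false(any(nm$mask & s$lesion_mask_ap))  # the "black holes"
})

test_that("injected stub predictors drive negative mining exactly", {
  imgs <- list(matrix(10, 16, 16), matrix(20, 16, 16))
  blob <- matrix(FALSE, 16, 16); blob[4:6, 4:6] <- TRUE
  masks <- mine_negative_masks(function(img) blob, imgs)
  expect_true(all(vapply(masks, function(m) identical(m$mask, blob), logical(1))))
  expect_identical(masks[[1]]$method, "negative_mining")
  empty <- mine_negative_masks(function(img) matrix(FALSE, 16, 16), imgs)
  expect_false(any(empty[[1]]$mask))
})

test_that("positive mining subtracts the known metastasis regions", {
  img <- matrix(10, 16, 16)
  blob <- matrix(FALSE, 16, 16); blob[4:8, 4:8] <- TRUE
  m <- matrix(FALSE, 16, 16); m[6:10, 6:10] <- TRUE
  out <- mine_positive_masks(function(img) blob, list(img), list(m))[[1]]
  expect_identical(out$mask, blob & !m)
  disjoint <- matrix(FALSE, 16, 16); disjoint[12:14, 12:14] <- TRUE
  out2 <- mine_positive_masks(function(img) disjoint, list(img), list(m))[[1]]
  expect_identical(out2$mask, disjoint)
  out3 <- mine_positive_masks(function(img) matrix(FALSE, 16, 16),
                              list(img), list(m))[[1]]
  expect_false(any(out3$mask))
})

test_that("three-class encoding partitions the image with exact proportions", {
  nm <- matrix(FALSE, 20, 20); nm[1:4, ] <- TRUE      # 20%
  m <- matrix(FALSE, 20, 20); m[11:12, ] <- TRUE      # 10%
  lab <- encode_three_class(nm, m)
  tab <- tabulate(as.integer(lab$classes) + 1L, 3)
  expect_equal(tab / 400, c(0.70, 0.20, 0.10))
  empty <- encode_three_class(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5))
  expect_true(all(empty$classes == 0))
  expect_error(encode_three_class(m, m), "overlap")
})

test_that("one-hot encoding round-trips through argmax and sums to one", {
  set.seed(2)
  lab <- matrix(sample(0:2, 144, TRUE), 12, 12)
  oh <- one_hot(lab, 3)
  expect_true(all(apply(oh, c(1, 2), sum) == 1))
  expect_identical(class_map(oh), lab)
  # argmax of a hand-set probability tensor
  p <- array(c(0.2, 0.5, 0.3, 0.6, 0.1, 0.3), dim = c(1, 2, 3))
  # pixel (1,1): channels (0.2, 0.3, 0.1) -> class 1; (1,2): (0.5, 0.6, 0.3) -> 1
  expect_identical(class_map(p), matrix(c(1L, 1L), 1, 2))
})

test_that("NM and M stay disjoint and the classes partition every image", {
  for (seed in c(11, 12)) {
    s <- generate_phantom(phantom_config(seed = seed, n_lesions = 2,
                                         view_shape = c(128, 64)))
    nm <- make_nm_mask_otsu(s$ap_view, s$lesion_mask_ap)
    expect_false(any(nm$mask & s$lesion_mask_ap))
    lab <- encode_three_class(nm, s$lesion_mask_ap)
    expect_true(all(lab$classes %in% 0:2))
    expect_equal(sum(lab$classes == 2), sum(s$lesion_mask_ap))
    expect_equal(sum(lab$classes == 1), sum(nm$mask))
  }
})

test_that("mined NM masks on negatives are false positives by construction, and
          smaller than Otsu masks as a tendency", {
  ds <- phantom_dataset(8, 0, base_seed = 21, image_size = c(32, 32))
  model <- train_dunet(
    lapply(ds$positives, `[[`, "image"),
    lapply(ds$positives, function(s) encode_two_class(s$m_mask)),
    config = tiny_net(n_classes = 2L), loss = "focal_tversky", lr = 1e-3,
    batch_size = 4, iterations = 40, iteration_unit = "steps", seed = 5)
  negs <- phantom_dataset(0, 20, base_seed = 22, image_size = c(32, 32))$negatives
  mined <- mine_negative_masks(model, lapply(negs, `[[`, "image"))
  # every mined pixel has empty ground truth, hence is a false positive
  expect_true(all(vapply(seq_along(mined), function(i)
    !any(mined[[i]]$mask & negs[[i]]$m_mask), logical(1))))
  otsu_area <- sum(vapply(negs, function(s)
    sum(make_nm_mask_otsu(s$image)$mask), numeric(1)))
  mined_area <- sum(vapply(mined, function(m) sum(m$mask), numeric(1)))
  expect_gte(otsu_area, mined_area)
})
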