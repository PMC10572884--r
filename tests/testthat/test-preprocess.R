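make_scan <- function(seed = 2, n_lesions = 3) {
  s <- generate_phantom(phantom_config(seed = seed, n_lesions = n_lesions))
  raw_scan(s$ap_view, s$pa_view, sprintf("phantom%d", seed))
}

test_that("projection profiles recover the generator's body extent", {
  s <- generate_phantom(phantom_config(seed = 2, n_lesions = 3))
  b <- detect_body_range(s$ap_view)
  sil_rows <- range(which(rowSums(s$silhouette_ap) > 0))
  sil_cols <- range(which(colSums(s$silhouette_ap) > 0))
  expect_lte(abs(b$rows[1] - sil_rows[1]), 2)
  expect_lte(abs(b$rows[2] - sil_rows[2]), 2)
  expect_lte(abs(b$cols[1] - sil_cols[1]), 2)
  expect_lte(abs(b$cols[2] - sil_cols[2]), 2)
})

test_that("body detection errors on an all-background image", {
  expect_error(detect_body_range(matrix(0, 64, 32)), "empty-body")
})

test_that("body detection spans the full extent of an all-body image", {
  b <- detect_body_range(matrix(50, 64, 32))
  expect_equal(b$rows, c(1, 64))
  expect_equal(b$cols, c(1, 32))
})

test_that("cut_and_center outputs the standard frame with a centered body", {
  s <- generate_phantom(phantom_config(seed = 2, n_lesions = 3))
  out <- cut_and_center(s$ap_view)
  expect_equal(dim(out), c(950, 256))
  bm <- out > 0.01 * max(out)
  com <- sum(col(out)[bm]) / sum(bm)
  expect_lt(abs(com - 128.5), 1)
})

test_that("a horizontally shifted body is re-centered to the same frame", {
  s <- generate_phantom(phantom_config(seed = 4, n_lesions = 2))
  v <- s$ap_view
  shifted <- cbind(v[, 31:256], matrix(0, 1024, 30))
  a <- cut_and_center(v)
  b <- cut_and_center(shifted)
  com <- function(m) { bm <- m > 0.01 * max(m); sum(col(m)[bm]) / sum(bm) }
  expect_lt(abs(com(a) - com(b)), 1)
})

test_that("an in-frame centered body passes through cut_and_center unchanged", {
  img <- matrix(0, 950, 256)
  img[100:800, 98:158] <- 40
  out <- cut_and_center(img, bounds = list(rows = c(1, 950), cols = c(98, 158)))
  expect_equal(out, img)
})

test_that("a body taller than the frame is truncated with a warning", {
  img <- matrix(10, 1024, 256)
  expect_warning(out <- cut_and_center(img), "truncat")
  expect_equal(dim(out), c(950, 256))
})

test_that("brightness normalization reaches the target band from both sides", {
  base <- matrix(0, 100, 50)
  base[20:80, 10:40] <- 1  # body footprint
  for (m0 in c(40, 1)) {
    img <- base * m0 / mean(base)  # exact starting mean m0
    out <- normalize_brightness(img)
    expect_gt(mean(out), 7)
    expect_lt(mean(out), 14)
    # single multiplicative gain, clipping aside
    expect_equal(out, pmin(pmax(img * attr(out, "gain"), 0), 255),
                 ignore_attr = TRUE)
  }
})

test_that("brightness normalization is idempotent", {
  img <- matrix(0, 100, 50); img[20:80, 10:40] <- 30
  once <- normalize_brightness(img)
  twice <- normalize_brightness(once)
  expect_equal(attr(twice, "gain"), 1)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)
})

test_that("normalization leaves an in-band image untouched (gain 1)", {
  img <- matrix(10, 64, 64)
  out <- normalize_brightness(img)
  expect_equal(attr(out, "gain"), 1)
  expect_equal(unclass(out), img, ignore_attr = TRUE)
})

test_that("above-knee crop keeps exactly the first 640 rows", {
  img <- matrix(seq_len(950 * 256), 950, 256)
  out <- crop_above_knees(img)
  expect_equal(dim(out), c(640, 256))
  expect_equal(out, img[1:640, ])          # row 639 (0-based) kept
  expect_false(any(out == img[641, 1]))    # row 640 (0-based) gone
  expect_error(crop_above_knees(matrix(0, 500, 256)), "rows")
  cst <- crop_above_knees(matrix(3, 950, 10))
  expect_true(all(cst == 3) && all(dim(cst) == c(640, 10)))
})

test_that("merging places AP left and PA right, and splits back exactly", {
  ap <- matrix(3, 640, 256); pa <- matrix(5, 640, 256)
  m <- merge_views(ap, pa)
  expect_equal(dim(m), c(640, 512))
  expect_true(all(m[, 1:256] == 3) && all(m[, 257:512] == 5))
  ap2 <- matrix(runif(640 * 256), 640, 256)
  pa2 <- matrix(runif(640 * 256), 640, 256)
  m2 <- merge_views(ap2, pa2)
  expect_identical(m2[, 1:256], ap2)
  expect_identical(m2[, 257:512], pa2)
  expect_error(merge_views(ap, matrix(0, 100, 256)), "dimensions")
})

test_that("the full chain yields a 640x512 in-band image, deterministically", {
  scan <- make_scan(seed = 6)
  p1 <- preprocess_scan(scan)
  p2 <- preprocess_scan(scan)
  expect_identical(p1, p2)
  expect_equal(dim(p1$pixels), c(640, 512))
  expect_gt(mean(p1$pixels), 7)
  expect_lt(mean(p1$pixels), 14)
  expect_true(all(p1$pixels >= 0) && all(p1$pixels <= 255))
  expect_identical(p1$provenance$source_id, "phantom6")
})
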