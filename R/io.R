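#' Read a grayscale PNG as an intensity matrix
#'
#' @param path PNG file; multi-channel images are averaged to grayscale.
#' @return numeric matrix with intensities in \[0, 255\].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img * 255
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param image numeric matrix; values are clipped to \[0, 255\].
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clip(image, 0, 255) / 255, path)
  invisible(path)
}

#' Write a binary or class-label mask as a PNG
#'
#' Class ids are stored as scaled gray levels so the file round-trips
#' through 8-bit PNG exactly (`id * 255 / (n_classes - 1)`).
#'
#' @param mask logical matrix, integer class matrix, or `label_map`.
#' @param path output file.
#' @param n_classes number of classes encoded (2 for binary masks).
#' @export
write_mask_png <- function(mask, path, n_classes = NULL) {
  if (inherits(mask, "label_map")) {
    n_classes <- mask$n_classes
    mask <- mask$classes
  }
  if (is.logical(mask)) {
    mask <- mask * 1L
    if (is.null(n_classes)) n_classes <- 2L
  }
  if (is.null(n_classes)) n_classes <- max(mask) + 1L
  png::writePNG(mask / (n_classes - 1L), path)
  invisible(path)
}

#' Read a mask PNG written by [write_mask_png()]
#'
#' @param path PNG file.
#' @param n_classes number of classes encoded.
#' @return integer matrix of 0-based class ids.
#' @export
read_mask_png <- function(path, n_classes = 2L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * (n_classes - 1L))), nrow(img), ncol(img))
}

#' Read a polygon-annotation JSON file as a metastasis mask
#'
#' Accepts the annotation-tool convention of a JSON object with a `shapes`
#' array of labelled polygons (`points` as x/y pairs in image coordinates)
#' plus `imageHeight`/`imageWidth`; every polygon is rasterized into one
#' logical mask.
#'
#' @param path JSON annotation file.
#' @param shape optional `c(rows, cols)` overriding the recorded image size.
#' @return logical matrix.
#' @export
read_annotation_json <- function(path, shape = NULL) {
  ann <- jsonlite::read_json(path)
  if (is.null(shape)) shape <- c(ann$imageHeight, ann$imageWidth)
  shape <- as.integer(shape)
  mask <- matrix(FALSE, shape[1], shape[2])
  for (sh in ann$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    # points are (x, y) with y down; rasterize by even-odd rule per row
    mask <- mask | polygon_mask(pts[, 2] + 1, pts[, 1] + 1, shape)
  }
  mask
}

# Even-odd polygon rasterization on the pixel grid (centers at integers).
polygon_mask <- function(ry, cx, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  n <- length(ry)
  for (r in seq_len(shape[1])) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ry[i] > r) != (ry[j] > r)) {
        xs <- c(xs, cx[i] + (r - ry[i]) / (ry[j] - ry[i]) * (cx[j] - cx[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
        if (hi >= lo) mask[r, max(1, lo):min(shape[2], hi)] <- TRUE
      }
    }
  }
  mask
}

#' Write a phantom cohort to disk as PNGs with a JSON manifest
#'
#' Each sample produces `<id>_ap.png`, `<id>_pa.png` and, for positives,
#' `<id>_mask_ap.png` / `<id>_mask_pa.png`; `manifest.json` records ids,
#' polarity, cohort tags and generator seeds.
#'
#' @param cohort list of `phantom_sample`s from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort_png <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    id <- sprintf("sample%03d", i)
    write_image_png(s$ap_view, file.path(dir, paste0(id, "_ap.png")))
    write_image_png(s$pa_view, file.path(dir, paste0(id, "_pa.png")))
    if (s$polarity == "positive") {
      write_mask_png(s$lesion_mask_ap, file.path(dir, paste0(id, "_mask_ap.png")))
      write_mask_png(s$lesion_mask_pa, file.path(dir, paste0(id, "_mask_pa.png")))
    }
    list(id = id, polarity = s$polarity, cohort_tag = s$cohort_tag,
         seed = s$config$seed, n_lesions = s$config$n_lesions)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a processed image plus its provenance sidecar
#'
#' @param processed a `processed_image`.
#' @param path output PNG path; the sidecar is `<path>.json`.
#' @export
write_processed_png <- function(processed, path) {
  write_image_png(processed$pixels, path)
  jsonlite::write_json(processed$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
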