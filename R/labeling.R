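#' Class ids of the three-class label scheme
#'
#' Air background (BG) = 0, non-metastatic body (NM) = 1, metastasis (M) = 2.
#' The two-class baseline scheme uses BG = 0, M = 1.
#' @name class_ids
NULL

BG_CLASS <- 0L
NM_CLASS <- 1L
M_CLASS <- 2L

#' Otsu threshold of a grayscale image
#'
#' Selects the intensity threshold maximizing the between-class variance of
#' the image histogram, computed over 256 integer bins (0..255) of the
#' rounded, clipped image. Foreground (body) is `image > threshold`. Ties are
#' broken toward the smallest threshold.
#'
#' @param image numeric matrix with at least two distinct intensity values.
#' @return scalar integer threshold in 0..254.
#' @export
otsu_threshold <- function(image) {
  check_matrix(image, "image")
  v <- as.integer(clip(round(image), 0, 255))
  if (length(unique(v)) < 2)
    stop("degenerate-histogram error: image has a single intensity value",
         call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)                 # class {<= t} weight, t = 0..255
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254
  w0t <- w0[1:255]; mut <- mu[1:255]
  valid <- w0t > 0 & w0t < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0t[valid] - mut[valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  which.max(sigma_b) - 1L         # smallest argmax; threshold on 0..254 scale
}

#' Non-metastasis mask from Otsu thresholding
#'
#' Body pixels above the Otsu threshold, with the (manually annotated)
#' metastasis regions excluded, form the non-metastatic (NM) mask. Negative
#' samples must pass an all-zero (or `NULL`) metastasis mask.
#'
#' @param image numeric matrix (typically the merged normalized image).
#' @param m_mask logical metastasis mask of the same shape, or `NULL`.
#' @param min_object_px optional morphological cleanup: connected mask
#'   components smaller than this many pixels are dropped. Off (0) by
#'   default — raw masks are the reference behavior.
#' @return object of class `nm_mask`: list with logical `mask`,
#'   `method = "otsu"` and `source_polarity`.
#' @export
make_nm_mask_otsu <- function(image, m_mask = NULL, min_object_px = 0L) {
  t0 <- otsu_threshold(image)
  body <- image > t0
  if (is.null(m_mask)) m_mask <- matrix(FALSE, nrow(image), ncol(image))
  if (!identical(dim(m_mask), dim(image)))
    stop_dim("m_mask and image must share dimensions")
  mask <- body & !m_mask
  if (min_object_px > 0) mask <- drop_small_objects(mask, min_object_px)
  structure(list(mask = mask, method = "otsu",
                 source_polarity = if (any(m_mask)) "positive" else "negative",
                 threshold = t0),
            class = "nm_mask")
}

#' Remove small connected components from a binary mask
#'
#' 8-connected components with fewer than `min_px` pixels are cleared.
#'
#' @param mask logical matrix.
#' @param min_px minimum component size to keep.
#' @return cleaned logical matrix.
#' @export
drop_small_objects <- function(mask, min_px) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  n <- 0L
  sizes <- integer(0)
  members <- list()
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    comp <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% h + 1L; cc <- (cur - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) {
          id <- (c2 - 1L) * h + rr
          if (mask[id] && lab[id] == 0L) {
            lab[id] <- n; queue <- c(queue, id); comp <- c(comp, id)
          }
        }
      }
    }
    sizes[n] <- length(comp)
    members[[n]] <- comp
  }
  for (k in seq_len(n)) if (sizes[k] < min_px) mask[members[[k]]] <- FALSE
  mask
}

#' @export
print.nm_mask <- function(x, ...) {
  cat(sprintf("nm_mask (%s, %s sample): %d px\n", x$method,
              x$source_polarity, sum(x$mask)))
  invisible(x)
}

# Predicted metastasis pixels of a model on one image, as a logical mask.
# The model is either a fitted object with a predict() method returning
# per-pixel classes (metastasis = highest id) or a plain function
# image -> logical mask / class matrix (used for injected test predictors).
predicted_m_mask <- function(model, image) {
  if (is.function(model)) {
    out <- model(image)
    if (is.logical(out)) return(out)
    return(out == max(out))
  }
  pred <- try(stats::predict(model, image), silent = TRUE)
  if (inherits(pred, "try-error") || is.null(pred$classes))
    stop("model error: predictor is untrained or incompatible", call. = FALSE)
  m_class <- if (!is.null(pred$probabilities))
    dim(pred$probabilities)[3] - 1L else max(pred$classes)
  pred$classes == m_class
}

#' Mine NM masks from a model's false positives on negative samples
#'
#' A model trained on positive samples only is applied to lesion-free
#' images; every predicted-metastasis pixel is by construction a false
#' positive and is harvested as non-metastatic (NM) tissue.
#'
#' @param model a trained predictor with a [predict()] method returning
#'   per-pixel `classes` (the metastasis class being the highest id).
#' @param negatives list of images (numeric matrices or `processed_image`s).
#' @return list of `nm_mask` objects with `method = "negative_mining"`.
#' @export
mine_negative_masks <- function(model, negatives) {
  lapply(negatives, function(img) {
    if (inherits(img, "processed_image")) img <- img$pixels
    structure(list(mask = predicted_m_mask(model, img),
                   method = "negative_mining", source_polarity = "negative"),
              class = "nm_mask")
  })
}

#' Mine NM masks from model predictions on positive samples
#'
#' As [mine_negative_masks()], but the known metastasis regions are excluded
#' from the harvested mask (the prediction inside true lesions is not a
#' false positive).
#'
#' @param model trained predictor.
#' @param positives list of images.
#' @param m_masks list of logical metastasis masks, same length and shapes.
#' @return list of `nm_mask` objects.
#' @export
mine_positive_masks <- function(model, positives, m_masks) {
  if (length(positives) != length(m_masks))
    stop_dim("positives and m_masks must have equal length")
  Map(function(img, m) {
    if (inherits(img, "processed_image")) img <- img$pixels
    structure(list(mask = predicted_m_mask(model, img) & !m,
                   method = "negative_mining", source_polarity = "positive"),
              class = "nm_mask")
  }, positives, m_masks)
}

#' Encode NM and M masks as a three-class label map
#'
#' @param nm an `nm_mask` or logical matrix.
#' @param m_mask logical metastasis mask, disjoint from `nm`.
#' @return object of class `label_map`: list with integer matrix `classes`
#'   (BG = 0, NM = 1, M = 2) and `n_classes = 3`.
#' @export
encode_three_class <- function(nm, m_mask) {
  if (inherits(nm, "nm_mask")) nm <- nm$mask
  if (!identical(dim(nm), dim(m_mask)))
    stop_dim("nm and m_mask must share dimensions")
  if (any(nm & m_mask))
    stop("consistency error: NM and M masks overlap", call. = FALSE)
  classes <- matrix(BG_CLASS, nrow(nm), ncol(nm))
  classes[nm] <- NM_CLASS
  classes[m_mask] <- M_CLASS
  structure(list(classes = classes, n_classes = 3L), class = "label_map")
}

#' Encode a metastasis mask as a two-class (baseline) label map
#'
#' @param m_mask logical metastasis mask; everything else is background.
#' @return `label_map` with classes BG = 0, M = 1.
#' @export
encode_two_class <- function(m_mask) {
  classes <- matrix(0L, nrow(m_mask), ncol(m_mask))
  classes[m_mask] <- 1L
  structure(list(classes = classes, n_classes = 2L), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(as.integer(x$classes) + 1L, nbins = x$n_classes)
  cat(sprintf("label_map %dx%d, %d classes; pixels: %s\n",
              nrow(x$classes), ncol(x$classes), x$n_classes,
              paste(tab, collapse = "/")))
  invisible(x)
}

#' One-hot encode a label map
#'
#' @param labels a `label_map` or integer matrix of 0-based class ids.
#' @param n_classes number of channels.
#' @return array `nrow x ncol x n_classes` of 0/1, channels summing to 1.
#' @export
one_hot <- function(labels, n_classes = NULL) {
  if (inherits(labels, "label_map")) {
    if (is.null(n_classes)) n_classes <- labels$n_classes
    labels <- labels$classes
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  h <- nrow(labels); w <- ncol(labels)
  out <- array(0, dim = c(h, w, n_classes))
  for (k in seq_len(n_classes)) out[, , k] <- as.numeric(labels == (k - 1L))
  out
}

#' Per-pixel argmax class of a one-hot or probability array
#'
#' @param x array `h x w x n_classes`.
#' @return integer matrix of 0-based class ids (first maximum on ties).
#' @export
class_map <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}
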