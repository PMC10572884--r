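#' Raw two-view scan container
#'
#' @param ap_view,pa_view numeric matrices of identical dimensions
#'   (1024 x 256 in clinical acquisitions), non-negative counts.
#' @param source_id opaque identifier carried through provenance.
#' @return object of class `raw_scan`.
#' @export
raw_scan <- function(ap_view, pa_view, source_id = "scan") {
  check_matrix(ap_view, "ap_view"); check_matrix(pa_view, "pa_view")
  if (!identical(dim(ap_view), dim(pa_view)))
    stop_dim("ap_view and pa_view must share identical dimensions")
  if (min(ap_view) < 0 || min(pa_view) < 0)
    stop_dim("raw scan intensities must be non-negative")
  structure(list(ap_view = ap_view, pa_view = pa_view, source_id = source_id),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("raw_scan '%s': 2 views of %dx%d\n", x$source_id,
              nrow(x$ap_view), ncol(x$ap_view)))
  invisible(x)
}

#' Brightness-normalization configuration
#'
#' The normalization drives the image mean intensity into the open band
#' `(target_mean_low, target_mean_high)` — (7, 14) grayscale levels in the
#' clinical protocol — by iterated linear gain with clipping to
#' `output_range`.
#'
#' @param target_mean_low,target_mean_high band bounds, `0 < low < high`.
#' @param max_iterations maximum gain iterations (>= 1).
#' @param output_range clipping range, default `c(0, 255)`.
#' @param body_only if `TRUE`, the mean is computed over body pixels only
#'   (above the projection-profile noise floor) instead of the whole image.
#' @return object of class `norm_config`.
#' @export
norm_config <- function(target_mean_low = 7, target_mean_high = 14,
                        max_iterations = 10L, output_range = c(0, 255),
                        body_only = FALSE) {
  if (!(target_mean_low > 0 && target_mean_low < target_mean_high))
    stop("configuration error: need 0 < target_mean_low < target_mean_high",
         call. = FALSE)
  if (max_iterations < 1)
    stop("configuration error: max_iterations must be >= 1", call. = FALSE)
  structure(list(target_mean_low = target_mean_low,
                 target_mean_high = target_mean_high,
                 max_iterations = as.integer(max_iterations),
                 output_range = output_range, body_only = body_only),
            class = "norm_config")
}

#' Detect the body extent of a view by projection profiles
#'
#' Row and column sums of the image form projection profiles; the body range
#' is the span from the first to the last index whose profile value exceeds a
#' noise floor, a fixed fraction of the profile maximum.
#'
#' @param view numeric matrix.
#' @param floor_frac noise floor as a fraction of the maximum profile value.
#' @return list with integer bounds `rows = c(first, last)` and
#'   `cols = c(first, last)` (1-based, inclusive).
#' @export
detect_body_range <- function(view, floor_frac = 0.01) {
  check_matrix(view, "view")
  span <- function(profile) {
    idx <- which(profile > floor_frac * max(profile) & profile > 0)
    if (length(idx) == 0)
      stop("empty-body error: projection profile never exceeds the noise floor",
           call. = FALSE)
    c(min(idx), max(idx))
  }
  if (max(view) <= 0)
    stop("empty-body error: projection profile never exceeds the noise floor",
         call. = FALSE)
  list(rows = span(rowSums(view)), cols = span(colSums(view)))
}

#' Cut and center a view to the standard pre-crop geometry
#'
#' Extracts the detected body rows, centers them vertically in a fixed-height
#' frame (950 rows in the clinical protocol) and shifts columns so the body's
#' horizontal center of mass lands on the frame's center column. No scaling
#' or resampling is applied; uncovered pixels are zero. A body taller than
#' the frame is bottom-truncated with a warning.
#'
#' @param view numeric matrix.
#' @param bounds output of [detect_body_range()]; recomputed when `NULL`.
#' @param out_height output frame height.
#' @param floor_frac noise floor used for the body mask in the center-of-mass
#'   computation.
#' @return numeric matrix `out_height x ncol(view)`.
#' @export
cut_and_center <- function(view, bounds = NULL, out_height = 950L,
                           floor_frac = 0.01) {
  check_matrix(view, "view")
  if (is.null(bounds)) bounds <- detect_body_range(view, floor_frac)
  r1 <- bounds$rows[1]; r2 <- bounds$rows[2]
  h <- r2 - r1 + 1
  if (h > out_height) {
    warning(sprintf("body spans %d rows; truncating to %d", h, out_height))
    r2 <- r1 + out_height - 1L
    h <- out_height
  }
  w <- ncol(view)
  body <- view[r1:r2, , drop = FALSE]
  # horizontal center of mass of the body mask (pixels above the noise floor)
  bm <- body > floor_frac * max(body)
  com <- sum(col(body)[bm]) / sum(bm)
  shift <- round((w + 1) / 2 - com)
  out <- matrix(0, out_height, w)
  dst_r <- floor((out_height - h) / 2) + seq_len(h)
  src_c <- seq_len(w)
  dst_c <- src_c + shift
  keep <- dst_c >= 1 & dst_c <= w
  out[dst_r, dst_c[keep]] <- body[, src_c[keep], drop = FALSE]
  out
}

#' Normalize image brightness into a target mean band
#'
#' Iterated linear transformation: while the mean intensity lies outside the
#' open band `(low, high)`, the image is multiplied by `midpoint / mean` and
#' clipped to the output range, then re-checked. Images already in band are
#' returned unchanged (gain 1); the procedure is idempotent.
#'
#' @param image numeric matrix.
#' @param config a [norm_config()].
#' @return normalized matrix; attribute `"gain"` records the cumulative
#'   applied gain.
#' @export
normalize_brightness <- function(image, config = norm_config()) {
  check_matrix(image, "image")
  if (max(image) <= 0)
    stop("normalization error: image has no body signal", call. = FALSE)
  target <- (config$target_mean_low + config$target_mean_high) / 2
  msk <- if (config$body_only) image > 0.01 * max(image) else
    matrix(TRUE, nrow(image), ncol(image))
  gain <- 1
  for (it in seq_len(config$max_iterations)) {
    m <- mean(image[msk])
    if (m > config$target_mean_low && m < config$target_mean_high) {
      attr(image, "gain") <- gain
      return(image)
    }
    g <- target / m
    image <- clip(image * g, config$output_range[1], config$output_range[2])
    gain <- gain * g
    if (config$body_only) msk <- image > 0.01 * max(image)
  }
  m <- mean(image[msk])
  if (m > config$target_mean_low && m < config$target_mean_high) {
    attr(image, "gain") <- gain
    return(image)
  }
  stop("normalization error: mean intensity did not reach the target band",
       call. = FALSE)
}

#' Crop a view above the knees
#'
#' Keeps the first `keep_rows` rows (rows 0..639 in 0-based clinical
#' convention), discarding the metastasis-sparse region below the knees.
#'
#' @param image numeric matrix with at least `keep_rows` rows.
#' @param keep_rows number of top rows to keep.
#' @return `keep_rows x ncol(image)` matrix, values unchanged.
#' @export
crop_above_knees <- function(image, keep_rows = 640L) {
  check_matrix(image, "image")
  if (nrow(image) < keep_rows)
    stop_dim(sprintf("input has %d rows; %d required", nrow(image), keep_rows))
  image[seq_len(keep_rows), , drop = FALSE]
}

#' Merge AP and PA views side by side
#'
#' @param ap,pa numeric matrices of identical dimensions (640 x 256 in the
#'   clinical protocol).
#' @return matrix with AP in the left column block and PA in the right.
#' @export
merge_views <- function(ap, pa) {
  check_matrix(ap, "ap"); check_matrix(pa, "pa")
  if (!identical(dim(ap), dim(pa)))
    stop_dim("ap and pa must share identical dimensions")
  cbind(ap, pa)
}

#' Full pre-processing chain for a raw two-view scan
#'
#' Applies, per view: projection-profile body detection, cut-and-center to
#' `out_height` rows, brightness normalization, above-knee crop to
#' `keep_rows` rows; then merges the two views horizontally (640 x 512 for
#' clinical geometry) and re-runs the (idempotent) brightness normalization
#' on the merged image so the final mean intensity sits in the target band.
#'
#' @param scan a [raw_scan()].
#' @param config a [norm_config()].
#' @param out_height,keep_rows geometry of the intermediate and final crops;
#'   defaults follow the clinical 1024-row acquisition.
#' @param floor_frac projection-profile noise floor fraction.
#' @return object of class `processed_image`: list with `pixels` (merged
#'   matrix) and `provenance` (source id, per-view row bounds, gains).
#' @export
preprocess_scan <- function(scan, config = norm_config(), out_height = 950L,
                            keep_rows = 640L, floor_frac = 0.01) {
  if (!inherits(scan, "raw_scan")) stop_dim("scan must be a raw_scan")
  do_view <- function(v) {
    b <- detect_body_range(v, floor_frac)
    cc <- cut_and_center(v, b, out_height, floor_frac)
    nb <- normalize_brightness(cc, config)
    list(img = crop_above_knees(nb, keep_rows), bounds = b,
         gain = attr(nb, "gain"))
  }
  ap <- do_view(scan$ap_view)
  pa <- do_view(scan$pa_view)
  merged <- normalize_brightness(merge_views(ap$img, pa$img), config)
  final_gain <- attr(merged, "gain")
  attr(merged, "gain") <- NULL
  structure(list(pixels = merged,
                 provenance = list(source_id = scan$source_id,
                                   ap_bounds = ap$bounds, pa_bounds = pa$bounds,
                                   ap_gain = ap$gain, pa_gain = pa$gain,
                                   merged_gain = final_gain)),
            class = "processed_image")
}

#' @export
print.processed_image <- function(x, ...) {
  cat(sprintf("processed_image '%s': %dx%d, mean %.2f\n",
              x$provenance$source_id, nrow(x$pixels), ncol(x$pixels),
              mean(x$pixels)))
  invisible(x)
}
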