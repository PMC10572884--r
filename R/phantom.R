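#' Configuration for the synthetic bone-scan phantom generator
#'
#' Describes one synthetic two-view whole-body bone-scan-like acquisition.
#' Images are count-like 8-bit grayscale matrices (rows x cols): a dark air
#' background with low Poisson noise, a connected, horizontally centered body
#' silhouette with skeleton-like high-uptake structure (skull, spine,
#' shoulders, pelvis), and optionally bright focal lesions (hotspots) fully
#' inside the silhouette.
#'
#' @param seed integer master seed; the same configuration always produces a
#'   bit-identical sample.
#' @param view_shape integer vector `c(rows, cols)` of one view. The default
#'   `c(1024, 256)` matches clinical raw acquisition geometry; small shapes
#'   (e.g. `c(64, 64)`) are used for desk-scale training tests.
#' @param n_lesions non-negative number of focal lesions. `0` produces a
#'   negative (lesion-free) sample.
#' @param lesion_intensity_range grayscale interval for lesion peak amplitude.
#'   Must lie strictly above the body intensity range so that hotspots are the
#'   brightest structures, as in Tc-99m MDP scans.
#' @param body_intensity_range grayscale interval from which the per-sample
#'   mean body count rate is drawn.
#' @param air_noise_level Poisson rate of the air background (counts).
#' @param artifact_flags character subset of
#'   `c("bladder", "injection_site", "motion")`: confounding hotspots at
#'   anatomically plausible fixed locations (high bladder activity, tracer
#'   injection site on the forearm) and a simple motion-shift band. Artifacts
#'   are never part of the lesion ground truth.
#' @param cohort_tag `"breast_like"` or `"prostate_like"`.
#' @param lesion_sigma_range Gaussian-profile scale interval in pixels;
#'   default scales with image size (`c(0.015, 0.03) * sqrt(rows * cols)`).
#' @param hot_structure_range integer interval for the number of elongated
#'   high-uptake skeletal segments (hot spine facets, joints) per sample.
#'   These reach lesion-level intensity but are elongated rather than
#'   compact, mirroring the benign hotspots that make brightness alone an
#'   ambiguous metastasis cue in real scans; they are never part of the
#'   lesion ground truth.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           view_shape = c(1024L, 256L),
                           n_lesions = 3L,
                           lesion_intensity_range = c(120, 220),
                           body_intensity_range = c(20, 45),
                           air_noise_level = 0.1,
                           artifact_flags = character(),
                           cohort_tag = c("breast_like", "prostate_like"),
                           lesion_sigma_range = NULL,
                           hot_structure_range = c(1L, 3L)) {
  cohort_tag <- match.arg(cohort_tag)
  view_shape <- as.integer(view_shape)
  if (length(view_shape) != 2 || any(is.na(view_shape)) || any(view_shape < 32))
    stop("configuration error: view_shape must be two integers >= 32", call. = FALSE)
  if (length(n_lesions) != 1 || is.na(n_lesions) || n_lesions < 0)
    stop("configuration error: n_lesions must be a non-negative integer", call. = FALSE)
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] >= r[2])
      stop(sprintf("configuration error: %s must be a non-empty interval", nm),
           call. = FALSE)
  }
  chk_range(lesion_intensity_range, "lesion_intensity_range")
  chk_range(body_intensity_range, "body_intensity_range")
  if (lesion_intensity_range[1] <= body_intensity_range[2])
    stop("configuration error: lesion intensities must strictly exceed body intensities",
         call. = FALSE)
  if (air_noise_level < 0)
    stop("configuration error: air_noise_level must be non-negative", call. = FALSE)
  bad <- setdiff(artifact_flags, c("bladder", "injection_site", "motion"))
  if (length(bad))
    stop("configuration error: unknown artifact flags: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(lesion_sigma_range))
    lesion_sigma_range <- c(0.015, 0.03) * sqrt(prod(view_shape))
  # hotspots are never sub-pixel in practice: floor the profile scale so a
  # lesion spans at least a few pixels even in strongly down-scaled phantoms
  lesion_sigma_range <- pmax(lesion_sigma_range, 1.3)
  structure(list(seed = as.integer(seed), view_shape = view_shape,
                 n_lesions = as.integer(n_lesions),
                 lesion_intensity_range = lesion_intensity_range,
                 body_intensity_range = body_intensity_range,
                 air_noise_level = air_noise_level,
                 artifact_flags = artifact_flags,
                 cohort_tag = cohort_tag,
                 lesion_sigma_range = lesion_sigma_range,
                 hot_structure_range = as.integer(hot_structure_range)),
            class = "phantom_config")
}

# Binary body silhouette: head / neck / torso-with-arms / pelvis / legs,
# defined by a per-row half-width profile around the image center column.
# Deterministic in the view shape; connected and horizontally centered.
phantom_silhouette <- function(view_shape) {
  h <- view_shape[1]; w <- view_shape[2]
  cc <- (w + 1) / 2
  t <- (seq_len(h) - 0.5) / h
  hw <- numeric(h)      # outer half-width, in pixels
  gap <- numeric(h)     # inner gap half-width (between the legs)
  head <- t >= 0.05 & t < 0.145
  hw[head] <- 0.17 * w * sqrt(pmax(0, 1 - ((t[head] - 0.0975) / 0.0475)^2))
  neck <- t >= 0.145 & t < 0.175
  hw[neck] <- 0.07 * w
  shoulder <- t >= 0.175 & t < 0.22
  hw[shoulder] <- (0.07 + (0.34 - 0.07) * (t[shoulder] - 0.175) / 0.045) * w
  torso <- t >= 0.22 & t < 0.56
  hw[torso] <- 0.34 * w
  pelvis <- t >= 0.56 & t < 0.63
  hw[pelvis] <- 0.30 * w
  legs <- t >= 0.63 & t < 0.92
  hw[legs] <- (0.26 - 0.06 * (t[legs] - 0.63) / 0.29) * w
  gap[legs] <- 0.03 * w
  d <- abs(matrix(seq_len(w), h, w, byrow = TRUE) - cc)
  mask <- d <= matrix(hw, h, w) & d >= matrix(gap, h, w)
  storage.mode(mask) <- "logical"
  mask
}

# Skeleton-like relative uptake map (multiplies the base body rate).
phantom_uptake_boost <- function(view_shape) {
  h <- view_shape[1]; w <- view_shape[2]
  cc <- (w + 1) / 2
  t <- matrix((seq_len(h) - 0.5) / h, h, w)
  d <- abs(matrix(seq_len(w), h, w, byrow = TRUE) - cc)
  boost <- matrix(1, h, w)
  boost[t < 0.145] <- 1.5                                    # skull
  boost[t >= 0.175 & t < 0.63 & d < 0.035 * w] <- 1.8        # spine
  boost[t >= 0.19 & t < 0.23 & d >= 0.10 * w] <- 1.5         # shoulder girdle
  boost[t >= 0.56 & t < 0.63 & d >= 0.05 * w] <- 1.4         # pelvic ring
  boost
}

# Sample lesion parameters inside the silhouette with pairwise separation,
# so emitted masks have exactly n_lesions connected components.
sample_lesions <- function(n, sil, cfg) {
  h <- nrow(sil); w <- ncol(sil)
  inside <- which(sil, arr.ind = TRUE)
  inside <- inside[inside[, 1] > 0.04 * h & inside[, 1] < 0.93 * h, , drop = FALSE]
  out <- vector("list", n)
  placed <- matrix(numeric(0), 0, 2)
  ext <- numeric(0)
  for (i in seq_len(n)) {
    s0 <- stats::runif(1, cfg$lesion_sigma_range[1], cfg$lesion_sigma_range[2])
    ecc <- stats::runif(1, 1, 1.5)
    ang <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, cfg$lesion_intensity_range[1], cfg$lesion_intensity_range[2])
    a <- s0 * ecc; b <- s0 / ecc
    extent <- 2 * a            # mask reaches 2 sigma along the major axis
    ok <- FALSE
    # separation shrinks over rounds so small images still place all lesions
    # (masks stay disjoint as long as footprints do not touch)
    for (sep in c(4, 2, 1)) {
      for (try in 1:400) {
        k <- inside[sample.int(nrow(inside), 1), ]
        r0 <- k[1]; c0 <- k[2]
        if (nrow(placed) > 0 &&
            any(sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2) <
                ext + extent + sep)) next
        # lesion footprint must stay inside the silhouette
        rr <- max(1, floor(r0 - extent - 1)):min(h, ceiling(r0 + extent + 1))
        ccs <- max(1, floor(c0 - extent - 1)):min(w, ceiling(c0 + extent + 1))
        q <- lesion_q(rr, ccs, r0, c0, a, b, ang)
        foot <- q <= 4
        if (r0 - extent < 1 || r0 + extent > h || c0 - extent < 1 || c0 + extent > w) next
        if (all(sil[rr, ccs][foot])) { ok <- TRUE; break }
      }
      if (ok) break
    }
    if (!ok)
      stop("phantom generation failed: could not place lesion ", i,
           " inside the silhouette (image too small for n_lesions?)", call. = FALSE)
    placed <- rbind(placed, c(r0, c0))
    ext <- c(ext, extent)
    out[[i]] <- list(row = r0, col = c0, a = a, b = b, angle = ang, amp = amp)
  }
  out
}

# Elongated high-uptake skeletal segments (hot spine facets, sacroiliac
# joints): lesion-level amplitude but band-like geometry, placed along the
# spine column. Reuses the elliptical-Gaussian machinery with one long axis.
sample_hot_structures <- function(n, sil, cfg) {
  h <- nrow(sil); w <- ncol(sil)
  s <- sqrt(h * w)
  cc <- (w + 1) / 2
  zone <- which(sil, arr.ind = TRUE)
  zone <- zone[zone[, 1] > 0.18 * h & zone[, 1] < 0.62 * h &
                 abs(zone[, 2] - cc) < 0.08 * w, , drop = FALSE]
  if (nrow(zone) == 0) return(list())
  lapply(seq_len(n), function(i) {
    k <- zone[sample.int(nrow(zone), 1), ]
    list(row = k[1], col = k[2],
         a = max(2.5, stats::runif(1, 0.05, 0.10) * s),
         b = stats::runif(1, 0.9, 1.4),
         angle = pi / 2 + stats::runif(1, -0.25, 0.25),
         amp = stats::runif(1, cfg$lesion_intensity_range[1],
                            cfg$lesion_intensity_range[2]) *
           stats::runif(1, 0.75, 1.05))
  })
}

# Squared Mahalanobis distance of grid (rr x ccs) to an elliptical Gaussian.
lesion_q <- function(rr, ccs, r0, c0, a, b, ang) {
  dy <- matrix(rr - r0, length(rr), length(ccs))
  dx <- matrix(ccs - c0, length(rr), length(ccs), byrow = TRUE)
  u <- cos(ang) * dx + sin(ang) * dy
  v <- -sin(ang) * dx + cos(ang) * dy
  (u / a)^2 + (v / b)^2
}

apply_lesions <- function(img, mask, lesions, mirror = FALSE) {
  h <- nrow(img); w <- ncol(img)
  for (L in lesions) {
    c0 <- if (mirror) w + 1 - L$col else L$col
    ang <- if (mirror) pi - L$angle else L$angle
    extent <- 2 * L$a
    rr <- max(1, floor(L$row - extent - 1)):min(h, ceiling(L$row + extent + 1))
    ccs <- max(1, floor(c0 - extent - 1)):min(w, ceiling(c0 + extent + 1))
    q <- lesion_q(rr, ccs, L$row, c0, L$a, L$b, ang)
    sel <- q <= 4
    patch <- img[rr, ccs]
    patch[sel] <- patch[sel] + L$amp * exp(-q[sel] / 2)
    img[rr, ccs] <- patch
    mpatch <- mask[rr, ccs]
    mpatch[sel] <- TRUE
    mask[rr, ccs] <- mpatch
  }
  list(img = img, mask = mask)
}

add_artifacts <- function(img, cfg) {
  h <- nrow(img); w <- ncol(img)
  blob <- function(img, r0, c0, s0, amp) {
    s0 <- max(s0, 1.2)          # artifacts, like lesions, are never sub-pixel
    extent <- 2.5 * s0
    rr <- max(1, floor(r0 - extent)):min(h, ceiling(r0 + extent))
    ccs <- max(1, floor(c0 - extent)):min(w, ceiling(c0 + extent))
    q <- lesion_q(rr, ccs, r0, c0, s0, s0, 0)
    img[rr, ccs] <- img[rr, ccs] + amp * exp(-q / 2) * (q <= 6.25)
    img
  }
  if ("bladder" %in% cfg$artifact_flags)
    img <- blob(img, 0.615 * h, (w + 1) / 2, 0.012 * sqrt(h * w), 160)
  if ("injection_site" %in% cfg$artifact_flags)
    img <- blob(img, 0.33 * h, (w + 1) / 2 + 0.30 * w, 0.008 * sqrt(h * w), 180)
  if ("motion" %in% cfg$artifact_flags) {
    rows <- floor(0.25 * h):floor(0.30 * h)
    shift <- max(1L, round(0.01 * w))
    img[rows, ] <- cbind(img[rows, (shift + 1):w, drop = FALSE],
                         matrix(0, length(rows), shift))
  }
  img
}

#' Generate one synthetic two-view bone-scan phantom
#'
#' Produces paired anterior (AP) and posterior (PA) count images plus exact
#' per-view lesion ground-truth masks. The PA view mirrors the AP anatomy
#' left-right with an independent Poisson noise realization. Output is
#' bit-identical for identical configurations.
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom_sample` with elements `ap_view`,
#'   `pa_view` (numeric matrices in \[0, 255\]), `lesion_mask_ap`,
#'   `lesion_mask_pa` (logical matrices), `silhouette_ap`, `silhouette_pa`
#'   (generator ground-truth body masks), `polarity` (`"positive"` or
#'   `"negative"`), `cohort_tag` and `config`.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop("configuration error: config must be a phantom_config", call. = FALSE)
  local_seed(config$seed, {
    shp <- config$view_shape
    sil <- phantom_silhouette(shp)
    boost <- phantom_uptake_boost(shp)
    base <- stats::runif(1, config$body_intensity_range[1], config$body_intensity_range[2])
    lam_ap <- ifelse(sil, base * boost, config$air_noise_level)
    ap <- matrix(stats::rpois(length(lam_ap), lam_ap), shp[1], shp[2])
    sil_pa <- sil[, rev(seq_len(shp[2]))]
    lam_pa <- lam_ap[, rev(seq_len(shp[2]))]
    pa <- matrix(stats::rpois(length(lam_pa), lam_pa), shp[1], shp[2])
    mask_ap <- matrix(FALSE, shp[1], shp[2])
    mask_pa <- matrix(FALSE, shp[1], shp[2])
    hsr <- config$hot_structure_range
    n_hot <- if (hsr[2] > 0) sample(seq(hsr[1], hsr[2]), 1) else 0L
    if (n_hot > 0) {
      hs <- sample_hot_structures(n_hot, sil, config)
      scratch <- matrix(FALSE, shp[1], shp[2])
      ap <- apply_lesions(ap, scratch, hs, mirror = FALSE)$img
      pa <- apply_lesions(pa, scratch, hs, mirror = TRUE)$img
    }
    if (config$n_lesions > 0) {
      lesions <- sample_lesions(config$n_lesions, sil, config)
      r <- apply_lesions(ap, mask_ap, lesions, mirror = FALSE)
      ap <- r$img; mask_ap <- r$mask
      r <- apply_lesions(pa, mask_pa, lesions, mirror = TRUE)
      pa <- r$img; mask_pa <- r$mask
    }
    ap <- add_artifacts(ap, config)
    pa <- add_artifacts(pa, config)
    structure(list(ap_view = clip(ap, 0, 255), pa_view = clip(pa, 0, 255),
                   lesion_mask_ap = mask_ap, lesion_mask_pa = mask_pa,
                   silhouette_ap = sil, silhouette_pa = sil_pa,
                   polarity = if (config$n_lesions > 0) "positive" else "negative",
                   cohort_tag = config$cohort_tag, config = config),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %s %s, %dx%d per view, %d lesion(s), seed %d\n",
              x$polarity, x$cohort_tag, nrow(x$ap_view), ncol(x$ap_view),
              x$config$n_lesions, x$config$seed))
  invisible(x)
}

#' Generate a deterministic cohort of phantom samples
#'
#' Emulates a clinical cohort composition (e.g. 90 scans with metastasis and
#' 10 without for a breast-cancer-like cohort, or 50/50 for a
#' prostate-cancer-like cohort). Positives come first, then negatives; each
#' sample receives a distinct seed derived from `base_seed` by fixed
#' arithmetic, so cohorts are reproducible at any size.
#'
#' @param n_positive,n_negative non-negative sample counts.
#' @param base_seed integer master seed.
#' @param config template [phantom_config()]; per-sample seed and lesion
#'   count override its `seed`/`n_lesions`.
#' @param n_lesion_range integer interval from which each positive sample's
#'   lesion count is drawn (deterministically from its derived seed).
#' @return list of [generate_phantom()] samples.
#' @export
generate_cohort <- function(n_positive, n_negative, base_seed,
                            config = phantom_config(),
                            n_lesion_range = c(1L, 5L)) {
  if (n_positive < 0 || n_negative < 0)
    stop("configuration error: sample counts must be non-negative", call. = FALSE)
  n <- n_positive + n_negative
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- derive_seed(base_seed, i)
    nl <- if (i <= n_positive)
      n_lesion_range[1] + s %% (n_lesion_range[2] - n_lesion_range[1] + 1L)
    else 0L
    cfg <- config
    cfg$seed <- s
    cfg$n_lesions <- as.integer(nl)
    out[[i]] <- generate_phantom(cfg)
  }
  out
}
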