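#' Configuration of the modified Double U-Net
#'
#' The architecture is two stacked U-Nets. Network 1 encodes the input image,
#' applies atrous (dilated) spatial pooling at its bottleneck, decodes, and
#' emits a per-pixel SoftMax over `n_classes`. Its foreground probability
#' (1 minus the background-channel probability) gates the input by
#' elementwise product, and the gated image feeds network 2, which emits the
#' final SoftMax map. Both outputs are multi-class and both are supervised
#' by default (averaged loss): without direct supervision, the first
#' network's background channel — and with it the input gate — receives
#' gradient only through the elementwise product and can collapse.
#'
#' @param input_shape `c(rows, cols)` of the (single-channel) input; each
#'   dimension must be divisible by the downsampling factor
#'   `2^(length(encoder_widths) - 1)`.
#' @param n_classes number of segmentation classes (>= 2; 3 for BG/NM/M).
#' @param encoder_widths channel counts per resolution level; the last entry
#'   is the bottleneck width. `c(8, 16, 32)` with 64 x 64 inputs is the tiny
#'   CPU preset used in tests.
#' @param use_aspp enable the dilated-convolution spatial pooling block at
#'   network 1's bottleneck.
#' @param dual_output if `TRUE` (default), training supervises both
#'   sub-network outputs with an averaged loss; `FALSE` supervises only the
#'   final output.
#' @return object of class `dunet_config`.
#' @export
network_config <- function(input_shape = c(640L, 512L), n_classes = 3L,
                           encoder_widths = c(16L, 32L, 64L),
                           use_aspp = TRUE, dual_output = TRUE) {
  input_shape <- as.integer(input_shape)
  encoder_widths <- as.integer(encoder_widths)
  if (n_classes < 2) stop("configuration error: n_classes must be >= 2", call. = FALSE)
  if (any(encoder_widths <= 0))
    stop("configuration error: encoder widths must be strictly positive", call. = FALSE)
  factor <- 2L^(length(encoder_widths) - 1L)
  if (any(input_shape %% factor != 0))
    stop(sprintf("configuration error: input dimensions must be divisible by %d",
                 factor), call. = FALSE)
  structure(list(input_shape = input_shape, n_classes = as.integer(n_classes),
                 encoder_widths = encoder_widths, use_aspp = use_aspp,
                 dual_output = dual_output),
            class = "dunet_config")
}

# Parameters of one U-Net: encoder/decoder blocks of
# conv -> instance norm -> ReLU pairs, optional ASPP bottleneck (parallel
# dilated 3x3 convs at rates 1/2/4, summed, normalized), and a 1x1 output
# head. The normalization keeps activation and logit scales bounded, which
# overlap losses (Dice/Tversky) need to avoid early softmax saturation.
unet_init <- function(in_ch, widths, n_classes, aspp) {
  L <- length(widths)
  par <- list()
  prev <- in_ch
  for (i in seq_len(L)) {
    par[[paste0("enc", i, "_1")]] <- conv_init(3L, prev, widths[i])
    par[[paste0("enc", i, "_1n")]] <- norm_init(widths[i])
    par[[paste0("enc", i, "_2")]] <- conv_init(3L, widths[i], widths[i])
    par[[paste0("enc", i, "_2n")]] <- norm_init(widths[i])
    prev <- widths[i]
  }
  if (aspp) {
    for (r in c(1L, 2L, 4L))
      par[[paste0("aspp_d", r)]] <- conv_init(3L, widths[L], widths[L], dilation = r)
    par[["aspp_n"]] <- norm_init(widths[L])
  }
  for (i in rev(seq_len(L - 1L))) {
    par[[paste0("dec", i, "_1")]] <- conv_init(3L, widths[i + 1L] + widths[i], widths[i])
    par[[paste0("dec", i, "_1n")]] <- norm_init(widths[i])
    par[[paste0("dec", i, "_2")]] <- conv_init(3L, widths[i], widths[i])
    par[[paste0("dec", i, "_2n")]] <- norm_init(widths[i])
  }
  par[["head"]] <- conv_init(1L, widths[1L], n_classes)
  par
}

# One conv -> norm -> relu block.
block_fwd <- function(h, par, conv_nm) {
  cv <- conv_fwd(h, par[[conv_nm]])
  nr <- instnorm_fwd(cv$out, par[[paste0(conv_nm, "n")]])
  rl <- relu_fwd(nr$out)
  list(out = rl$out, cache = list(cv = cv$cache, nr = nr$cache, rl = rl$cache))
}

block_bwd <- function(cache, dout, grads, conv_nm) {
  dn <- relu_bwd(cache$rl, dout)
  nb <- instnorm_bwd(cache$nr, dn)
  grads[[paste0(conv_nm, "n")]] <- list(dW = nb$dW, db = nb$db)
  cb <- conv_bwd(cache$cv, nb$dx)
  grads[[conv_nm]] <- list(dW = cb$dW, db = cb$db)
  list(dx = cb$dx, grads = grads)
}

unet_forward <- function(par, x, widths, aspp) {
  L <- length(widths)
  cache <- list(enc = vector("list", L), dec = vector("list", L))
  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    b1 <- block_fwd(h, par, paste0("enc", i, "_1"))
    b2 <- block_fwd(b1$out, par, paste0("enc", i, "_2"))
    cache$enc[[i]] <- list(b1 = b1$cache, b2 = b2$cache)
    skips[[i]] <- b2$out
    if (i < L) {
      pl <- maxpool_fwd(b2$out)
      cache$enc[[i]]$pool <- pl$cache
      h <- pl$out
    } else h <- b2$out
  }
  if (aspp) {
    branches <- lapply(c(1L, 2L, 4L), function(r)
      conv_fwd(h, par[[paste0("aspp_d", r)]]))
    summed <- branches[[1]]$out + branches[[2]]$out + branches[[3]]$out
    nr <- instnorm_fwd(summed, par[["aspp_n"]])
    ra <- relu_fwd(nr$out)
    cache$aspp <- list(branches = lapply(branches, `[[`, "cache"),
                       nr = nr$cache, r = ra$cache)
    h <- ra$out
  }
  for (i in rev(seq_len(L - 1L))) {
    up <- upsample_fwd(h)
    ct <- concat_fwd(up$out, skips[[i]])
    b1 <- block_fwd(ct$out, par, paste0("dec", i, "_1"))
    b2 <- block_fwd(b1$out, par, paste0("dec", i, "_2"))
    cache$dec[[i]] <- list(up = up$cache, ct = ct$cache,
                           b1 = b1$cache, b2 = b2$cache)
    h <- b2$out
  }
  hd <- conv_fwd(h, par[["head"]])
  sm <- softmax_fwd(hd$out)
  cache$head <- hd$cache
  cache$softmax <- sm$cache
  list(probs = sm$out, cache = cache)
}

# Backward through one U-Net given dL/dprobs; returns parameter gradients
# (same names as par) and dL/dinput.
unet_backward <- function(par, cache, dprobs, widths, aspp) {
  L <- length(widths)
  grads <- list()
  dz <- softmax_bwd(cache$softmax, dprobs)
  cb <- conv_bwd(cache$head, dz)
  grads[["head"]] <- list(dW = cb$dW, db = cb$db)
  dh <- cb$dx
  dskips <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    dc <- cache$dec[[i]]
    r <- block_bwd(dc$b2, dh, grads, paste0("dec", i, "_2")); grads <- r$grads
    r <- block_bwd(dc$b1, r$dx, grads, paste0("dec", i, "_1")); grads <- r$grads
    sp <- concat_bwd(dc$ct, r$dx)
    dskips[[i]] <- sp$db
    dh <- upsample_bwd(dc$up, sp$da)
  }
  if (aspp) {
    da <- relu_bwd(cache$aspp$r, dh)
    nb <- instnorm_bwd(cache$aspp$nr, da)
    grads[["aspp_n"]] <- list(dW = nb$dW, db = nb$db)
    dh <- 0
    rates <- c(1L, 2L, 4L)
    for (bi in seq_along(rates)) {
      cb <- conv_bwd(cache$aspp$branches[[bi]], nb$dx)
      grads[[paste0("aspp_d", rates[bi])]] <- list(dW = cb$dW, db = cb$db)
      dh <- dh + cb$dx
    }
  }
  for (i in rev(seq_len(L))) {
    ec <- cache$enc[[i]]
    if (i < L) dh <- maxpool_bwd(ec$pool, dh)
    if (i < L && !is.null(dskips[[i]])) dh <- dh + dskips[[i]]
    r <- block_bwd(ec$b2, dh, grads, paste0("enc", i, "_2")); grads <- r$grads
    r <- block_bwd(ec$b1, r$dx, grads, paste0("enc", i, "_1")); grads <- r$grads
    dh <- r$dx
  }
  list(grads = grads, dx = dh)
}

#' Build a modified Double U-Net with randomly initialized weights
#'
#' @param config a [network_config()].
#' @param seed integer seed for the He-style weight initialization.
#' @return object of class `dunet`: parameter lists for both sub-networks,
#'   the configuration, and an empty training history.
#' @export
build_double_unet <- function(config = network_config(), seed = 1L) {
  if (!inherits(config, "dunet_config"))
    stop("configuration error: config must be a network_config", call. = FALSE)
  local_seed(seed, {
    structure(list(
      net1 = unet_init(1L, config$encoder_widths, config$n_classes, config$use_aspp),
      net2 = unet_init(1L, config$encoder_widths, config$n_classes, aspp = FALSE),
      config = config, init_seed = as.integer(seed),
      trained = FALSE, history = numeric(0)),
      class = "dunet")
  })
}

# Full forward pass; x is an h x w matrix already scaled to [0, 1].
dunet_forward <- function(model, x) {
  cfg <- model$config
  xa <- array(x, dim = c(nrow(x), ncol(x), 1L))
  f1 <- unet_forward(model$net1, xa, cfg$encoder_widths, cfg$use_aspp)
  fg <- 1 - f1$probs[, , 1L]                    # foreground attention gate
  x2 <- array(xa[, , 1L] * fg, dim = dim(xa))
  f2 <- unet_forward(model$net2, x2, cfg$encoder_widths, aspp = FALSE)
  list(p1 = f1$probs, p2 = f2$probs,
       cache = list(f1 = f1$cache, f2 = f2$cache, xa = xa, fg = fg, x2 = x2))
}

# Backward pass given gradients w.r.t. the two probability maps (either may
# be NULL); returns gradients for net1/net2 parameter lists.
dunet_backward <- function(model, fwd, dp2, dp1 = NULL) {
  cfg <- model$config
  b2 <- unet_backward(model$net2, fwd$cache$f2, dp2, cfg$encoder_widths, aspp = FALSE)
  # gate: x2 = x * (1 - p1[,,BG]) => dL/dp1_BG -= x * dL/dx2
  dfg <- b2$dx[, , 1L] * fwd$cache$xa[, , 1L]
  g1 <- if (is.null(dp1)) array(0, dim = dim(fwd$p1)) else dp1
  g1[, , 1L] <- g1[, , 1L] - dfg
  b1 <- unet_backward(model$net1, fwd$cache$f1, g1, cfg$encoder_widths,
                      aspp = cfg$use_aspp)
  list(net1 = b1$grads, net2 = b2$grads)
}

#' Predict a segmentation map for one image
#'
#' @param object a `dunet` model.
#' @param image numeric matrix matching the configured input shape
#'   (a `processed_image` is accepted); intensities in \[0, 255\] are scaled
#'   to \[0, 1\] internally.
#' @param which `"final"` (network 2's output, default) or `"first"`.
#' @param ... unused.
#' @return object of class `prediction_map`: list with `probabilities`
#'   (`h x w x n_classes`, summing to 1 per pixel) and `classes` (0-based
#'   argmax matrix).
#' @export
predict.dunet <- function(object, image, which = c("final", "first"), ...) {
  which <- match.arg(which)
  if (inherits(image, "processed_image")) image <- image$pixels
  check_matrix(image, "image")
  if (!identical(dim(image), as.integer(object$config$input_shape)) &&
      !identical(as.integer(dim(image)), object$config$input_shape))
    stop_dim(sprintf("image is %dx%d but the model expects %dx%d",
                     nrow(image), ncol(image),
                     object$config$input_shape[1], object$config$input_shape[2]))
  fwd <- dunet_forward(object, scale_input(image))
  probs <- if (which == "final") fwd$p2 else fwd$p1
  structure(list(probabilities = probs, classes = class_map(probs)),
            class = "prediction_map")
}

# Inputs are 8-bit grayscale; the network consumes [0, 1].
scale_input <- function(image) {
  if (max(image) > 1) image / 255 else image
}

#' @export
print.prediction_map <- function(x, ...) {
  tab <- tabulate(as.integer(x$classes) + 1L, nbins = dim(x$probabilities)[3])
  cat(sprintf("prediction_map %dx%d, %d classes; argmax pixels: %s\n",
              nrow(x$classes), ncol(x$classes), dim(x$probabilities)[3],
              paste(tab, collapse = "/")))
  invisible(x)
}

n_params <- function(par)
  sum(vapply(par, function(l) length(l$W) + length(l$b), numeric(1)))

#' @export
print.dunet <- function(x, ...) {
  cat(sprintf("Modified Double U-Net: %dx%d input, %d classes, widths [%s]%s\n",
              x$config$input_shape[1], x$config$input_shape[2],
              x$config$n_classes,
              paste(x$config$encoder_widths, collapse = ", "),
              if (x$config$use_aspp) ", ASPP bottleneck" else ""))
  cat(sprintf("  %s; %d parameters\n",
              if (x$trained) sprintf("trained (%d steps, final loss %.4f)",
                                     length(x$history),
                                     x$history[length(x$history)])
              else "untrained",
              n_params(x$net1) + n_params(x$net2)))
  invisible(x)
}

#' @export
summary.dunet <- function(object, ...) {
  out <- list(config = object$config,
              n_params = n_params(object$net1) + n_params(object$net2),
              trained = object$trained, steps = length(object$history),
              final_loss = if (length(object$history))
                object$history[length(object$history)] else NA_real_)
  class(out) <- "summary.dunet"
  out
}

#' @export
print.summary.dunet <- function(x, ...) {
  cat("Modified Double U-Net\n")
  cat(sprintf("  input %dx%d, %d classes, widths [%s], ASPP %s, dual output %s\n",
              x$config$input_shape[1], x$config$input_shape[2],
              x$config$n_classes,
              paste(x$config$encoder_widths, collapse = ", "),
              x$config$use_aspp, x$config$dual_output))
  cat(sprintf("  parameters: %d\n", x$n_params))
  if (x$trained)
    cat(sprintf("  trained %d steps; final training loss %.4f\n",
                x$steps, x$final_loss))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.dunet <- function(object, ...) list(net1 = object$net1, net2 = object$net2)

#' Plot the training loss curve of a fitted Double U-Net
#'
#' @param x a trained `dunet`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dunet <- function(x, ...) {
  if (!length(x$history)) stop("model has no training history", call. = FALSE)
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "gradient step", ylab = "training loss", ...)
  invisible(x)
}
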