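#' Fit a modified Double U-Net to labelled images
#'
#' The model-fitting entry point. Trains the two-stage U-Net with the Adam
#' optimizer under a background-excluded Dice or focal Tversky loss. All
#' randomness (weight initialization, shuffling) derives from `seed`; runs
#' are bit-reproducible.
#'
#' @param x list of input images (numeric matrices, or `processed_image`s);
#'   8-bit intensities are scaled to \[0, 1\] internally.
#' @param y list of matching labels: `label_map`s, integer class matrices
#'   (0-based), or one-hot arrays.
#' @param config a [network_config()]; its input shape must match the images.
#' @param loss `"dice"` or `"focal_tversky"`.
#' @param loss_config a [loss_config()].
#' @param lr Adam learning rate (clinical protocol default 1e-4).
#' @param batch_size images per gradient step (clinical protocol default 4).
#' @param iterations number of training iterations.
#' @param iteration_unit `"epochs"` (default; one iteration is a pass over
#'   the training set, as in the clinical protocol) or `"steps"` (one
#'   iteration is one gradient step, the unit quoted for desk-scale tests).
#' @param seed integer seed.
#' @param init optional `dunet` whose weights warm-start training (transfer
#'   learning); must share the architecture of `config`.
#' @param validation optional list(x, y) monitored per epoch; the returned
#'   model keeps the weights of the best validation loss.
#' @param verbose print per-epoch loss.
#' @return a trained `dunet` with `history` (per-step training loss).
#' @export
train_dunet <- function(x, y, config = network_config(), loss = c("focal_tversky", "dice"),
                        loss_config = default_loss_config(), lr = 1e-4,
                        batch_size = 4L, iterations = 500L,
                        iteration_unit = c("epochs", "steps"), seed = 1L,
                        init = NULL, validation = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  iteration_unit <- match.arg(iteration_unit)
  if (length(x) != length(y) || length(x) == 0)
    stop("x and y must be non-empty lists of equal length", call. = FALSE)
  xs <- lapply(x, function(im) {
    if (inherits(im, "processed_image")) im <- im$pixels
    scale_input(im)
  })
  ys <- lapply(y, function(lab) {
    if (inherits(lab, "label_map")) lab <- one_hot(lab)
    if (is.matrix(lab)) lab <- one_hot(lab, config$n_classes)
    if (!identical(dim(lab)[3], as.integer(config$n_classes)))
      stop_dim("label channels do not match n_classes")
    lab
  })
  model <- if (is.null(init)) build_double_unet(config, seed = seed) else {
    if (!identical(init$config$encoder_widths, config$encoder_widths) ||
        init$config$n_classes != config$n_classes)
      stop("configuration error: init model architecture does not match config",
           call. = FALSE)
    init
  }
  n <- length(xs)
  n_steps <- if (iteration_unit == "steps") as.integer(iterations) else
    as.integer(iterations) * max(1L, ceiling(n / batch_size))

  opt <- list(net1 = adam_state(model$net1), net2 = adam_state(model$net2))
  history <- numeric(0)
  best <- NULL
  best_val <- Inf

  local_seed(derive_seed(seed, 1L), {
    step <- 0L
    order <- integer(0)
    while (step < n_steps) {
      if (length(order) == 0) order <- sample.int(n)
      take <- utils::head(order, batch_size)
      order <- utils::tail(order, -length(take))
      step <- step + 1L
      acc <- list(net1 = NULL, net2 = NULL)
      batch_loss <- 0
      for (i in take) {
        fwd <- dunet_forward(model, xs[[i]])
        li <- masked_multiclass_loss(ys[[i]], fwd$p2, loss_config, base = loss)
        dp2 <- masked_loss_grad(ys[[i]], fwd$p2, loss_config, base = loss)
        dp1 <- NULL
        if (config$dual_output) {
          li <- (li + masked_multiclass_loss(ys[[i]], fwd$p1, loss_config,
                                             base = loss)) / 2
          dp1 <- masked_loss_grad(ys[[i]], fwd$p1, loss_config, base = loss) / 2
          dp2 <- dp2 / 2
        }
        g <- dunet_backward(model, fwd, dp2, dp1)
        batch_loss <- batch_loss + li
        acc <- accumulate_grads(acc, g)
      }
      batch_loss <- batch_loss / length(take)
      history <- c(history, batch_loss)
      for (net in c("net1", "net2")) {
        upd <- adam_update(model[[net]], acc[[net]], opt[[net]], lr,
                           scale = 1 / length(take), t = step)
        model[[net]] <- upd$par
        opt[[net]] <- upd$state
      }
      if (!is.null(validation) && length(order) == 0) {  # end of epoch
        vl <- mean(vapply(seq_along(validation$x), function(j) {
          im <- validation$x[[j]]
          if (inherits(im, "processed_image")) im <- im$pixels
          lab <- validation$y[[j]]
          if (inherits(lab, "label_map")) lab <- one_hot(lab)
          if (is.matrix(lab)) lab <- one_hot(lab, config$n_classes)
          fwd <- dunet_forward(model, scale_input(im))
          masked_multiclass_loss(lab, fwd$p2, loss_config, base = loss)
        }, numeric(1)))
        if (vl < best_val) { best_val <- vl; best <- model[c("net1", "net2")] }
        if (verbose) message(sprintf("step %d: train %.4f val %.4f",
                                     step, batch_loss, vl))
      } else if (verbose && step %% 25L == 0) {
        message(sprintf("step %d: train %.4f", step, batch_loss))
      }
    }
  })
  if (!is.null(best)) { model$net1 <- best$net1; model$net2 <- best$net2 }
  model$trained <- TRUE
  model$history <- history
  model$loss <- loss
  model
}

adam_state <- function(par) {
  lapply(par, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

accumulate_grads <- function(acc, g) {
  for (net in c("net1", "net2")) {
    if (is.null(acc[[net]])) acc[[net]] <- g[[net]]
    else for (nm in names(g[[net]])) {
      acc[[net]][[nm]]$dW <- acc[[net]][[nm]]$dW + g[[net]][[nm]]$dW
      acc[[net]][[nm]]$db <- acc[[net]][[nm]]$db + g[[net]][[nm]]$db
    }
  }
  acc
}

adam_update <- function(par, grads, state, lr, scale = 1, t = 1L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    gW <- grads[[nm]]$dW * scale
    gb <- grads[[nm]]$db * scale
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    par[[nm]]$W <- par[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    par[[nm]]$b <- par[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- st
  }
  list(par = par, state = state)
}
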