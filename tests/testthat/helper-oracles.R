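# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive Otsu: evaluate the between-class variance of every candidate
# threshold directly from the pixel values.
brute_otsu <- function(image) {
  v <- as.integer(pmin(pmax(round(image), 0), 255))
  best_t <- -1L
  best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Scalar-loop Dice loss of one class channel (textbook form, smooth = 0).
brute_dice_channel <- function(y, p) {
  s_yp <- 0; s_y <- 0; s_p <- 0
  for (i in seq_along(y)) {
    s_yp <- s_yp + y[i] * p[i]
    s_y <- s_y + y[i]
    s_p <- s_p + p[i]
  }
  1 - 2 * s_yp / (s_y + s_p)
}

# Scalar-loop focal Tversky loss of one class channel (textbook form).
brute_ftl_channel <- function(y, p, alpha, beta, gamma) {
  s_yp <- 0; s_fp <- 0; s_fn <- 0
  for (i in seq_along(y)) {
    s_yp <- s_yp + y[i] * p[i]
    s_fp <- s_fp + (1 - y[i]) * p[i]
    s_fn <- s_fn + y[i] * (1 - p[i])
  }
  ti <- s_yp / (s_yp + alpha * s_fp + beta * s_fn)
  (1 - ti)^gamma
}

# Mean of the per-channel brute-force losses over non-excluded channels.
brute_masked_loss <- function(y, p, base, cfg) {
  inc <- setdiff(seq_len(dim(y)[3]) - 1L, cfg$excluded_classes) + 1L
  vals <- vapply(inc, function(k) {
    if (base == "dice") brute_dice_channel(as.numeric(y[, , k]), as.numeric(p[, , k]))
    else brute_ftl_channel(as.numeric(y[, , k]), as.numeric(p[, , k]),
                           cfg$alpha, cfg$beta, cfg$gamma)
  }, numeric(1))
  mean(vals)
}

# Random one-hot truth and simplex prediction arrays.
random_truth <- function(h, w, k) one_hot(matrix(sample(0:(k - 1), h * w, TRUE), h, w), k)
random_probs <- function(h, w, k) {
  m <- matrix(stats::rexp(h * w * k), h * w, k)
  array(m / rowSums(m), dim = c(h, w, k))
}

# 8-connected component count by flood fill (oracle for lesion masks).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    h <- nrow(mask)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% h + 1L; cc <- (cur - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= ncol(mask)) {
          id <- (c2 - 1L) * h + rr
          if (mask[id] && lab[id] == 0L) { lab[id] <- n; queue <- c(queue, id) }
        }
      }
    }
  }
  n
}

# Tiny network preset shared by training tests.
tiny_net <- function(size = c(32L, 32L), widths = c(4L, 8L), n_classes = 3L)
  network_config(input_shape = size, n_classes = n_classes,
                 encoder_widths = widths)

# Published aggregate row of one experiment/loss as a metrics_record.
published_mean <- function(tab, experiment, loss) {
  row <- tab[tab$experiment == experiment & tab$loss == loss & tab$fold == "mean", ]
  metrics_record(row$precision, row$sensitivity, row$f1)
}

fold_rows <- function(tab, experiment, loss)
  tab[tab$experiment == experiment & tab$loss == loss & tab$fold != "mean", ]
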