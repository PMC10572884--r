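# Low-level differentiable image operations used by the Double U-Net.
# Tensors are base-R arrays (height x width x channels), column-major with
# the channel dimension last; convolutions are im2col + BLAS gemm. Each
# *_fwd returns list(out, cache); each *_bwd takes (cache, dout) and returns
# the input gradient (plus parameter gradients for conv layers). Gradients
# are verified against finite differences in the test suite.

conv_init <- function(k, in_ch, out_ch, dilation = 1L) {
  # He-style initialization; caller controls the RNG stream.
  fan_in <- k * k * in_ch
  list(W = matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch), k = as.integer(k), dilation = as.integer(dilation))
}

# im2col for 'same' padding: returns (H*W) x (k*k*Cin) matrix.
im2col <- function(x, k, dilation) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], k, dilation)
}

col2im <- function(dX, h, w, cin, k, dilation) {
  array(cpp_col2im(dX, h, w, cin, k, dilation), dim = c(h, w, cin))
}

conv_fwd <- function(x, layer) {
  d <- dim(x)
  if (layer$k == 1L) {
    X <- matrix(x, d[1] * d[2], d[3])
  } else {
    X <- im2col(x, layer$k, layer$dilation)
  }
  out <- X %*% layer$W + rep(layer$b, each = d[1] * d[2])
  list(out = array(out, dim = c(d[1], d[2], ncol(layer$W))),
       cache = list(X = X, dims = d, layer = layer))
}

conv_bwd <- function(cache, dout) {
  d <- cache$dims; layer <- cache$layer
  dmat <- matrix(dout, d[1] * d[2], length(layer$b))
  dW <- crossprod(cache$X, dmat)
  db <- colSums(dmat)
  dX <- dmat %*% t(layer$W)
  dx <- if (layer$k == 1L) array(dX, dim = d) else
    col2im(dX, d[1], d[2], d[3], layer$k, layer$dilation)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(out = x * (x > 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# Instance normalization (batch-size-1 batch normalization): per-channel
# standardization over the spatial dimensions, with learned scale/shift
# stored as W (scale, init 1) and b (shift, init 0) so the optimizer treats
# norm layers like any other parameterized layer.
norm_init <- function(ch) {
  list(W = rep(1, ch), b = numeric(ch), norm = TRUE)
}

instnorm_fwd <- function(x, layer, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  m <- matrix(x, n, d[3])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = n)
  sig <- sqrt(colMeans(xc^2) + eps)
  xhat <- xc / rep(sig, each = n)
  out <- xhat * rep(layer$W, each = n) + rep(layer$b, each = n)
  list(out = array(out, dim = d),
       cache = list(xhat = xhat, sig = sig, g = layer$W, d = d))
}

instnorm_bwd <- function(cache, dout) {
  d <- cache$d
  n <- d[1] * d[2]
  dy <- matrix(dout, n, d[3])
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(cache$g, each = n)
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) /
    rep(cache$sig, each = n)
  list(dx = array(dx, dim = d), dW = dg, db = db)
}

maxpool_fwd <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  h2 <- h %/% 2L; w2 <- w %/% 2L
  io <- rep(seq_len(h2), times = w2 * ch)
  jo <- rep(rep(seq_len(w2), each = h2), times = ch)
  ko <- rep(seq_len(ch), each = h2 * w2)
  base <- (2L * jo - 2L) * h + (ko - 1L) * h * w
  lin <- cbind(base + 2L * io - 1L,             # (dr, dc) = (0, 0)
               base + 2L * io,                  # (1, 0)
               base + h + 2L * io - 1L,         # (0, 1)
               base + h + 2L * io)              # (1, 1)
  M <- matrix(x[lin], ncol = 4L)
  k <- max.col(M, ties.method = "first")
  sel <- lin[cbind(seq_along(k), k)]
  list(out = array(M[cbind(seq_along(k), k)], dim = c(h2, w2, ch)),
       cache = list(sel = sel, dims = d))
}

maxpool_bwd <- function(cache, dout) {
  dx <- numeric(prod(cache$dims))
  dx[cache$sel] <- as.numeric(dout)
  array(dx, dim = cache$dims)
}

upsample_fwd <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
               drop = FALSE],
       cache = d)
}

upsample_bwd <- function(cache, dout) {
  h <- cache[1]; w <- cache[2]
  odd_r <- seq(1L, 2L * h, 2L); odd_c <- seq(1L, 2L * w, 2L)
  dout[odd_r, odd_c, , drop = FALSE] + dout[odd_r + 1L, odd_c, , drop = FALSE] +
    dout[odd_r, odd_c + 1L, , drop = FALSE] +
    dout[odd_r + 1L, odd_c + 1L, , drop = FALSE]
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  list(out = array(c(a, b), dim = c(da[1], da[2], da[3] + db[3])),
       cache = c(da[3], db[3]))
}

concat_bwd <- function(cache, dout) {
  list(da = dout[, , seq_len(cache[1]), drop = FALSE],
       db = dout[, , cache[1] + seq_len(cache[2]), drop = FALSE])
}

softmax_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  rmax <- m[, 1]
  for (j in seq_len(d[3])[-1]) rmax <- pmax(rmax, m[, j])
  e <- exp(m - rmax)
  p <- e / rowSums(e)
  list(out = array(p, dim = d), cache = p)
}

softmax_bwd <- function(cache, dp) {
  d <- dim(dp)
  p <- cache
  dpm <- matrix(dp, nrow(p), ncol(p))
  dz <- p * (dpm - rowSums(dpm * p))
  array(dz, dim = d)
}
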