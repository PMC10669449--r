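# Low-level differentiable layer primitives.
#
# Feature maps are H x W x C numeric arrays; single-channel rasters may be
# plain matrices and are promoted with as_fmap(). Every op here has a
# matching *_bw() so the network backward pass is exact.

as_fmap <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Same-size 2-D convolution of a feature map
#'
#' Zero-padded, stride-1 convolution with weights stored as a
#' `Cout x (Cin*k*k)` matrix (the layout used by the compiled kernel).
#'
#' @param x H x W x Cin array (a matrix is treated as one channel).
#' @param W weight matrix, `Cout` rows.
#' @param b bias vector of length `Cout`.
#' @param k odd kernel side in pixels.
#' @return H x W x Cout array.
#' @keywords internal
conv2d <- function(x, W, b, k) {
  x <- as_fmap(x)
  cpp_conv2d(x, W, b, as.integer(k))
}

conv2d_bw <- function(x, W, dy, k) {
  cpp_conv2d_backward(as_fmap(x), W, dy, as.integer(k))
}

# index (1-based) into a weight-matrix column for input channel ci,
# kernel row offset ky, col offset kx (all 0-based); used by tests that
# hand-craft kernels.
conv_w_index <- function(ci, ky, kx, k) ci * k * k + kx * k + ky + 1L

conv_w_init <- function(cin, cout, k, gain = 2) {
  n <- cin * k * k
  matrix(stats::rnorm(cout * n, sd = sqrt(gain / n)), nrow = cout)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
relu_bw <- function(x, dy) dy * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

## -- resolution changes ------------------------------------------------

# 2x2 average pooling, stride 2 (halves each spatial side; sides must be even)
down2 <- function(x) {
  x <- as_fmap(x)
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  o <- seq(1L, d[1], 2L); p <- seq(1L, d[2], 2L)
  (x[o, p, , drop = FALSE] + x[o + 1L, p, , drop = FALSE] +
     x[o, p + 1L, , drop = FALSE] + x[o + 1L, p + 1L, , drop = FALSE]) / 4
}

down2_bw <- function(dy) up2(dy) / 4

# 2x nearest-neighbour upsampling
up2 <- function(x) {
  x <- as_fmap(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_bw <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], 2L); p <- seq(1L, d[2], 2L)
  dy[o, p, , drop = FALSE] + dy[o + 1L, p, , drop = FALSE] +
    dy[o, p + 1L, , drop = FALSE] + dy[o + 1L, p + 1L, , drop = FALSE]
}

# size-preserving 2x2 mean (zero pad at the bottom/right edge); this is the
# stride-1 reading of the refinement path's 2x2 average pooling
pool2_same <- function(x) {
  x <- as_fmap(x)
  (x + shift_up0(x) + shift_left0(x) + shift_up0(shift_left0(x))) / 4
}

pool2_same_bw <- function(dy) {
  (dy + shift_down0(dy) + shift_right0(dy) + shift_down0(shift_right0(dy))) / 4
}

shift_up0 <- function(x) {    # row r of output = row r+1 of input
  d <- dim(x); y <- array(0, d)
  if (d[1] > 1) y[seq_len(d[1] - 1L), , ] <- x[-1L, , , drop = FALSE]
  y
}
shift_down0 <- function(x) {
  d <- dim(x); y <- array(0, d)
  if (d[1] > 1) y[-1L, , ] <- x[seq_len(d[1] - 1L), , , drop = FALSE]
  y
}
shift_left0 <- function(x) {
  d <- dim(x); y <- array(0, d)
  if (d[2] > 1) y[, seq_len(d[2] - 1L), ] <- x[, -1L, , drop = FALSE]
  y
}
shift_right0 <- function(x) {
  d <- dim(x); y <- array(0, d)
  if (d[2] > 1) y[, -1L, ] <- x[, seq_len(d[2] - 1L), , drop = FALSE]
  y
}

## -- feature normalization ---------------------------------------------

# Per-channel spatial normalization with learnable scale/shift: each
# channel of one sample is standardized over its H*W pixels.  Used after
# every primary convolution; batch-size independent and deterministic.
norm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, nrow = n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colSums(xc^2) / n
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, d = d, n = n))
}

norm_bw <- function(cache, gamma, dy) {
  n <- cache$n
  dym <- matrix(dy, nrow = n)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  # standard normalization backward, per channel
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2L, cache$inv, `*`)
  list(dx = array(dx, cache$d), dgamma = dgamma, dbeta = dbeta)
}

## -- global average pool (squeeze) --------------------------------------

gap_fw <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, nrow = d[1] * d[2]))
}

gap_bw <- function(ds, d) {
  array(rep(ds, each = d[1] * d[2]) / (d[1] * d[2]), d)
}

# channel-wise multiply of an H x W x C map by a length-C weight vector
chan_scale <- function(x, w) {
  d <- dim(x)
  array(sweep(matrix(x, ncol = d[3]), 2L, w, `*`), d)
}
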