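# Convolutional building blocks: ghost convolution, squeeze-and-excitation
# (SE) channel attention, the SE-ghost module, and sequential spatial +
# channel attention (SCA). Blocks are parameterized by plain lists created
# with *_init(); forward functions are pure in (x, params). Blocks used
# inside the trainable network also carry an exact *_bw() backward.

#' Ghost convolution configuration
#'
#' A ghost convolution produces `out_channels` feature channels cheaply: a
#' primary ordinary convolution makes `m = ceiling(out_channels * ratio)`
#' channels, and the remaining `out_channels - m` channels are inexpensive
#' per-channel (depthwise) linear transforms of the primary output.
#'
#' @param out_channels total output channels (>= 2).
#' @param ratio fraction of channels from the primary convolution.
#' @param primary_kernel,cheap_kernel odd kernel sides in pixels.
#' @export
ghost_config <- function(out_channels, ratio = 0.5, primary_kernel = 3L,
                         cheap_kernel = 3L) {
  out_channels <- as.integer(out_channels)
  if (out_channels < 2L) stop("out_channels must be >= 2")
  if (primary_kernel %% 2L == 0L || cheap_kernel %% 2L == 0L)
    stop("kernel sizes must be odd")
  m <- as.integer(ceiling(out_channels * ratio))
  if (m < 1L || out_channels - m < 1L)
    stop("ratio leaves an empty primary or cheap branch")
  structure(list(out_channels = out_channels, ratio = ratio, m = m,
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel)),
            class = "ghost_config")
}

#' Squeeze-and-excitation configuration
#'
#' @param channels number of channels the block gates.
#' @param reduction bottleneck divisor; the hidden width is
#'   `max(1, channels %/% reduction)`.
#' @export
se_config <- function(channels, reduction = 4L) {
  channels <- as.integer(channels)
  if (channels < 1L) stop("channels must be positive")
  structure(list(channels = channels, reduction = as.integer(reduction),
                 bottleneck = max(1L, channels %/% as.integer(reduction))),
            class = "se_config")
}

## -- plain ghost convolution (Fig-style original module) -----------------

ghost_init <- function(in_channels, cfg) {
  m <- cfg$m; nc <- cfg$out_channels - m
  list(
    Wp = conv_w_init(in_channels, m, cfg$primary_kernel),
    bp = rep(0, m),
    # one depthwise kernel per cheap channel, acting on primary channel
    # ((j - 1) %% m) + 1
    Wc = lapply(seq_len(nc), function(j)
      conv_w_init(1L, 1L, cfg$cheap_kernel)),
    bc = rep(0, nc),
    in_channels = as.integer(in_channels), cfg = cfg)
}

#' Ghost convolution forward pass
#'
#' @param x H x W x Cin feature map.
#' @param cfg a [ghost_config()].
#' @param params block parameters from `ghost_init()`; freshly initialized
#'   from the current RNG state when `NULL`.
#' @return H x W x `out_channels` array: primary-convolution channels first,
#'   then the cheap depthwise channels.
#' @export
ghost_conv <- function(x, cfg, params = NULL) {
  x <- as_fmap(x)
  if (is.null(params)) params <- ghost_init(dim(x)[3], cfg)
  P <- relu(conv2d(x, params$Wp, params$bp, cfg$primary_kernel))
  nc <- cfg$out_channels - cfg$m
  d <- dim(P)
  out <- array(0, c(d[1], d[2], cfg$out_channels))
  out[, , seq_len(cfg$m)] <- P
  for (j in seq_len(nc)) {
    src <- ((j - 1L) %% cfg$m) + 1L
    out[, , cfg$m + j] <- conv2d(P[, , src, drop = FALSE],
                                 params$Wc[[j]], params$bc[j],
                                 cfg$cheap_kernel)[, , 1]
  }
  out
}

#' Learnable-parameter counts for ghost vs. plain convolution
#'
#' Counts convolution weights and biases only (normalization and attention
#' parameters are excluded so the comparison isolates the ghost trick).
#'
#' @param in_channels input channel count.
#' @param cfg a [ghost_config()].
#' @return named vector with components `ghost` and `plain` (a plain
#'   `primary_kernel`-sized convolution to the same `out_channels`).
#' @export
ghost_param_count <- function(in_channels, cfg) {
  m <- cfg$m; nc <- cfg$out_channels - m
  ghost <- in_channels * m * cfg$primary_kernel^2 + m +
    nc * (cfg$cheap_kernel^2 + 1L)
  plain <- in_channels * cfg$out_channels * cfg$primary_kernel^2 +
    cfg$out_channels
  c(ghost = ghost, plain = plain)
}

## -- squeeze-and-excitation ----------------------------------------------

se_init <- function(cfg) {
  C <- cfg$channels; B <- cfg$bottleneck
  list(W1 = matrix(stats::rnorm(C * B, sd = sqrt(2 / C)), C, B),
       b1 = rep(0, B),
       W2 = matrix(stats::rnorm(B * C, sd = sqrt(1 / B)), B, C),
       b2 = rep(0, C),
       cfg = cfg)
}

#' Squeeze-and-excitation channel weights
#'
#' Squeeze: global average pooling per channel. Excitation: a bottleneck
#' affine map, rectifier, restoring affine map, and logistic sigmoid, so
#' every weight lies strictly in (0, 1).
#'
#' @param x H x W x C feature map with `C = cfg$channels`.
#' @param cfg an [se_config()].
#' @param params from `se_init()`; freshly initialized when `NULL`.
#' @return numeric vector of `C` channel weights in (0, 1).
#' @export
se_block <- function(x, cfg, params = NULL) {
  x <- as_fmap(x)
  if (dim(x)[3] != cfg$channels)
    stop("feature map has ", dim(x)[3], " channels, expected ", cfg$channels)
  if (is.null(params)) params <- se_init(cfg)
  se_fw(x, params)$w
}

se_fw <- function(x, p) {
  s <- gap_fw(x)
  z1 <- drop(crossprod(p$W1, s)) + p$b1
  h <- pmax(z1, 0)
  z2 <- drop(crossprod(p$W2, h)) + p$b2
  w <- sigmoid(z2)
  list(w = w, cache = list(s = s, z1 = z1, h = h, w = w, d = dim(x)))
}

se_bw <- function(p, cache, dw) {
  dz2 <- dw * cache$w * (1 - cache$w)
  dW2 <- outer(cache$h, dz2)
  db2 <- dz2
  dh <- drop(p$W2 %*% dz2)
  dz1 <- dh * (cache$z1 > 0)
  dW1 <- outer(cache$s, dz1)
  db1 <- dz1
  ds <- drop(p$W1 %*% dz1)
  list(dx = gap_bw(ds, cache$d), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

## -- SE-ghost module -------------------------------------------------------

se_ghost_init <- function(in_channels, cfg, se_reduction = 4L) {
  m <- cfg$m
  list(Wp = conv_w_init(in_channels, m, cfg$primary_kernel),
       bp = rep(0, m),
       gamma = rep(1, m), beta = rep(0, m),
       se = se_init(se_config(m, se_reduction)),
       in_channels = as.integer(in_channels), cfg = cfg)
}

#' SE-ghost module forward pass
#'
#' The ghost module with its cheap linear branch replaced by channel
#' attention: the primary convolution result (after per-channel spatial
#' normalization and a rectifier) is reweighted channel-wise by an SE block
#' and concatenated with itself unweighted.
#'
#' @inheritParams ghost_conv
#' @param se an [se_config()] for the primary channels; defaults to
#'   reduction 4.
#' @param params from `se_ghost_init()`; freshly initialized when `NULL`.
#' @return H x W x `out_channels` array (primary channels, then reweighted
#'   channels).
#' @export
se_ghost_module <- function(x, cfg, se = NULL, params = NULL) {
  x <- as_fmap(x)
  if (is.null(params)) {
    red <- if (is.null(se)) 4L else se$reduction
    params <- se_ghost_init(dim(x)[3], cfg, red)
  }
  se_ghost_fw(x, params)$y
}

se_ghost_fw <- function(x, p) {
  cfg <- p$cfg
  P0 <- conv2d(x, p$Wp, p$bp, cfg$primary_kernel)
  nrm <- norm_fw(P0, p$gamma, p$beta)
  P <- relu(nrm$y)
  sef <- se_fw(P, p$se)
  S <- chan_scale(P, sef$w)
  d <- dim(P)
  nsec <- cfg$out_channels - cfg$m
  y <- array(0, c(d[1], d[2], cfg$out_channels))
  y[, , seq_len(cfg$m)] <- P
  y[, , cfg$m + seq_len(nsec)] <- S[, , seq_len(nsec)]
  list(y = y,
       cache = list(x = x, P0 = P0, nrm = nrm$cache, Pn = nrm$y, P = P,
                    se = sef$cache, w = sef$w))
}

se_ghost_bw <- function(p, cache, dy) {
  cfg <- p$cfg
  m <- cfg$m; nsec <- cfg$out_channels - m
  dP <- dy[, , seq_len(m), drop = FALSE]
  dS <- dy[, , m + seq_len(nsec), drop = FALSE]
  # secondary branch: S_j = P_j * w_j for j = 1..nsec
  w <- cache$w
  dw <- rep(0, m)
  for (j in seq_len(nsec)) {
    dP[, , j] <- dP[, , j] + dS[, , j] * w[j]
    dw[j] <- dw[j] + sum(dS[, , j] * cache$P[, , j])
  }
  seb <- se_bw(p$se, cache$se, dw)
  dP <- dP + seb$dx
  dPn <- relu_bw(cache$Pn, dP)
  nb <- norm_bw(cache$nrm, p$gamma, dPn)
  cb <- conv2d_bw(cache$x, p$Wp, nb$dx, cfg$primary_kernel)
  list(dx = cb$dx,
       grads = list(Wp = cb$dW, bp = drop(cb$db),
                    gamma = nb$dgamma, beta = nb$dbeta,
                    se.W1 = seb$dW1, se.b1 = seb$db1,
                    se.W2 = seb$dW2, se.b2 = seb$db2))
}

## -- spatial + channel attention (SCA) ------------------------------------

sca_init <- function(channels, reduction = 4L, spatial_kernel = 3L) {
  list(se = se_init(se_config(channels, reduction)),
       Ws = conv_w_init(1L, 1L, spatial_kernel, gain = 1),
       bs = 0,
       spatial_kernel = as.integer(spatial_kernel),
       channels = as.integer(channels))
}

#' Sequential channel-then-spatial attention
#'
#' Channel reweighting by an SE block, followed by a single-channel spatial
#' gate in (0, 1) computed from the channel-pooled map: the channel mean of
#' the reweighted features is passed through a small convolution and a
#' sigmoid, and multiplies every channel. Output shape equals input shape;
#' with both gates in (0, 1), no entry's magnitude can grow.
#'
#' @param x H x W x C feature map.
#' @param params from `sca_init()`; freshly initialized when `NULL`.
#' @param reduction SE bottleneck divisor used when initializing.
#' @return array with the same dimensions as `x`.
#' @export
sca_attention <- function(x, params = NULL, reduction = 4L) {
  x <- as_fmap(x)
  if (is.null(params)) params <- sca_init(dim(x)[3], reduction)
  sca_fw(x, params)$y
}

sca_fw <- function(x, p) {
  sef <- se_fw(x, p$se)
  xc <- chan_scale(x, sef$w)
  d <- dim(x)
  m <- array(rowMeans(matrix(xc, ncol = d[3])), c(d[1], d[2], 1L))
  zg <- conv2d(m, p$Ws, p$bs, p$spatial_kernel)
  g <- sigmoid(zg)
  y <- xc * as.vector(g)        # broadcast H*W gate over channels
  list(y = y,
       cache = list(x = x, se = sef$cache, w = sef$w, xc = xc, m = m,
                    g = g, d = d))
}

sca_bw <- function(p, cache, dy) {
  d <- cache$d
  g <- as.vector(cache$g)
  dxc <- dy * g
  dg <- array(rowSums(matrix(dy * cache$xc, ncol = d[3])), c(d[1], d[2], 1L))
  dzg <- dg * cache$g * (1 - cache$g)
  cb <- conv2d_bw(cache$m, p$Ws, dzg, p$spatial_kernel)
  dxc <- dxc + array(as.vector(cb$dx) / d[3], d)   # mean over channels
  # channel gate: xc = x * w
  dx <- chan_scale(dxc, cache$w)
  dw <- colSums(matrix(dxc * cache$x, ncol = d[3]))
  seb <- se_bw(p$se, cache$se, dw)
  dx <- dx + seb$dx
  list(dx = dx,
       grads = list(se.W1 = seb$dW1, se.b1 = seb$db1,
                    se.W2 = seb$dW2, se.b2 = seb$db2,
                    Ws = cb$dW, bs = drop(cb$db)))
}
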