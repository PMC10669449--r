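#' Gabor wavelet filter bank
#'
#' A 2-D Gabor wavelet is a Gaussian envelope multiplying a complex plane
#' wave, with a compensation term that removes the filter's response to
#' constant (DC) input. The kernel at pixel displacement `z = (x, y)` is
#'
#' \deqn{G_{u,v}(z) = \frac{\|k\|^2}{\sigma^2}
#'   e^{-\|k\|^2\|z\|^2 / (2\sigma^2)}
#'   \left[ e^{i k \cdot z} - e^{-\sigma^2/2} \right]}
#'
#' where the wave vector `k` has magnitude `k_v = (pi/2) / 2^(v-1)` (an
#' octave-spaced radial frequency, `v = 1` the finest) and direction
#' `phi_u = u * pi / U` for orientation index `u` in `0..U-1`. The envelope
#' width is fixed at `sigma = 2*pi`, which matches the printed compensation
#' term and gives roughly one-octave frequency bandwidth.
#'
#' The compensation term makes the continuous wavelet zero-mean, but a
#' sampled kernel truncated to `kernel_size` pixels retains a residual DC
#' component (large at coarse scales, whose envelope outgrows the grid).
#' With `dc_correct = TRUE` (the default) the sampled mean is subtracted so
#' every kernel is exactly zero-mean on its grid, preserving the band-pass
#' property that makes the bank insensitive to overall image brightness.
#'
#' @param u orientation index, integer in `[0, U-1]`; `u = 0` is a
#'   horizontal wave vector (vertical stripes).
#' @param v scale index, integer `>= 1`; radial frequency `(pi/2)/2^(v-1)`.
#' @param U total number of orientations.
#' @param kernel_size odd kernel side in pixels.
#' @param sigma envelope width in radians.
#' @return `gabor_params()`: a validated parameter list of class
#'   `"gabor_params"`.
#' @export
gabor_params <- function(u, v, U = 8L, kernel_size = 15L, sigma = 2 * pi) {
  U <- as.integer(U); u <- as.integer(u); v <- as.integer(v)
  kernel_size <- as.integer(kernel_size)
  if (U < 1L) stop("U must be a positive integer")
  if (u < 0L || u >= U) stop("orientation index u must lie in [0, U-1]")
  if (v < 1L) stop("scale index v must be >= 1")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd positive integer")
  structure(list(u = u, v = v, U = U, kernel_size = kernel_size,
                 sigma = sigma),
            class = "gabor_params")
}

#' @rdname gabor_params
#' @export
gabor_freq <- function(v) (pi / 2) / 2^(v - 1)

#' @rdname gabor_params
#' @export
gabor_angle <- function(u, U) u * pi / U

#' Sample a single Gabor kernel
#'
#' @param params a [gabor_params()] object.
#' @param dc_correct subtract the sampled mean so the kernel is exactly
#'   zero-mean on its truncated grid (default `TRUE`).
#' @return a complex `kernel_size x kernel_size` matrix centered at the
#'   origin (rows = y, columns = x).
#' @export
gabor_kernel <- function(params, dc_correct = TRUE) {
  stopifnot(inherits(params, "gabor_params"))
  s <- params$kernel_size
  sigma <- params$sigma
  kv <- gabor_freq(params$v)
  phi <- gabor_angle(params$u, params$U)
  kx <- kv * cos(phi); ky <- kv * sin(phi)
  h <- (s - 1) / 2
  co <- seq(-h, h)
  zx <- matrix(co, s, s, byrow = TRUE)   # column displacement
  zy <- matrix(co, s, s)                 # row displacement
  env <- (kv^2 / sigma^2) * exp(-kv^2 * (zx^2 + zy^2) / (2 * sigma^2))
  ker <- env * (exp(1i * (kx * zx + ky * zy)) - exp(-sigma^2 / 2))
  if (dc_correct) ker <- ker - mean(ker)
  ker
}

#' Build a Gabor filter bank
#'
#' Kernels are ordered scale-major, orientation-minor: all `U` orientations
#' of the first scale, then of the second, and so on. The default bank
#' (8 orientations, 4 octave-spaced scales) has 32 kernels, matching the
#' 32-channel Gabor-path feature maps of the detection network.
#'
#' @inheritParams gabor_params
#' @param scales integer vector of scale indices (each `>= 1`).
#' @param response_mode how [gabor_conv()] turns the complex response into
#'   real channels: `"magnitude"` (default; one channel per kernel),
#'   `"real"` (one channel), or `"real_imag"` (two channels per kernel:
#'   all real parts in bank order, then all imaginary parts).
#' @param dc_correct as in [gabor_kernel()].
#' @return an object of class `"gabor_bank"`.
#' @export
gabor_bank <- function(U = 8L, scales = 1:4, kernel_size = 15L,
                       sigma = 2 * pi,
                       response_mode = c("magnitude", "real", "real_imag"),
                       dc_correct = TRUE) {
  response_mode <- match.arg(response_mode)
  U <- as.integer(U)
  scales <- as.integer(scales)
  if (length(scales) < 1L) stop("scales must be non-empty")
  if (any(scales < 1L)) stop("scale indices must be >= 1")
  kernels <- vector("list", U * length(scales))
  meta <- vector("list", U * length(scales))
  i <- 0L
  for (v in scales) {
    for (u in seq_len(U) - 1L) {
      i <- i + 1L
      kernels[[i]] <- gabor_kernel(
        gabor_params(u, v, U, kernel_size, sigma), dc_correct = dc_correct)
      meta[[i]] <- c(u = u, v = v)
    }
  }
  k2 <- kernel_size * kernel_size
  Wre <- matrix(0, length(kernels), k2)
  Wim <- matrix(0, length(kernels), k2)
  for (j in seq_along(kernels)) {
    # weight-matrix layout: column kx*k + ky + 1 (see conv_w_index); a
    # convolution *correlates* with the flipped kernel, so flip here to get
    # a true convolution with the sampled wavelet
    kk <- kernels[[j]][kernel_size:1, kernel_size:1]
    Wre[j, ] <- as.vector(Re(kk))
    Wim[j, ] <- as.vector(Im(kk))
  }
  structure(list(kernels = kernels, index = do.call(rbind, meta),
                 U = U, scales = scales, kernel_size = kernel_size,
                 sigma = sigma, response_mode = response_mode,
                 dc_correct = dc_correct, Wre = Wre, Wim = Wim),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "Gabor bank: %d kernels (%d orientations x %d scales), %dx%d px, mode=%s\n",
    length(x$kernels), x$U, length(x$scales), x$kernel_size, x$kernel_size,
    x$response_mode))
  invisible(x)
}

#' Number of response channels a bank produces
#' @param bank a [gabor_bank()].
#' @export
gabor_n_channels <- function(bank) {
  n <- length(bank$kernels)
  if (bank$response_mode == "real_imag") 2L * n else n
}

#' Convolve an image with a Gabor bank
#'
#' Same-size, zero-padded spatial convolution of a single-channel image with
#' every kernel of the bank. The bank is fixed (non-learned): it acts as a
#' direction- and frequency-indexed feature extractor in front of the
#' network. Because the kernels are zero-mean, the response to a constant
#' image vanishes away from the zero-padded border.
#'
#' @param image numeric matrix (H x W) or H x W x 1 array, values in `[0,1]`.
#' @param bank a [gabor_bank()].
#' @return H x W x C array with `C = gabor_n_channels(bank)`, channels in
#'   bank order.
#' @export
gabor_conv <- function(image, bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  image <- as_fmap(image)
  if (dim(image)[3] != 1L) stop("gabor_conv expects a single-channel image")
  nk <- length(bank$kernels)
  z <- rep(0, nk)
  re <- cpp_conv2d(image, bank$Wre, z, bank$kernel_size)
  if (bank$response_mode == "real") return(re)
  im <- cpp_conv2d(image, bank$Wim, z, bank$kernel_size)
  switch(bank$response_mode,
         magnitude = sqrt(re^2 + im^2),
         real_imag = {
           d <- dim(re)
           out <- array(0, c(d[1], d[2], 2L * nk))
           out[, , seq_len(nk)] <- re
           out[, , nk + seq_len(nk)] <- im
           out
         })
}

#' Export / import a bank's defining metadata as JSON
#'
#' Only the generating parameters are stored; kernels are resampled on
#' import, so the round trip is exact.
#'
#' @param bank a [gabor_bank()].
#' @param path file path for the JSON metadata.
#' @export
write_gabor_bank <- function(bank, path) {
  meta <- list(U = bank$U, scales = bank$scales,
               kernel_size = bank$kernel_size, sigma = bank$sigma,
               response_mode = bank$response_mode,
               dc_correct = bank$dc_correct)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gabor_bank
#' @export
read_gabor_bank <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  gabor_bank(U = m$U, scales = m$scales, kernel_size = m$kernel_size,
             sigma = m$sigma, response_mode = m$response_mode,
             dc_correct = m$dc_correct)
}

# expected best-responding orientation index (0-based) for a line whose
# direction in the (row, col) frame is (cos theta, sin theta): the wave
# vector (angle phi_u in the (x = col, y = row) frame) must align with the
# line's intensity gradient, giving phi = -theta mod pi; ties break toward
# the lower index
gabor_line_channel <- function(theta, U) {
  want <- (-theta) %% pi
  ang <- gabor_angle(seq_len(U) - 1L, U)
  d <- abs(ang - want)
  d <- pmin(d, pi - d)
  which(d == min(d))[1] - 1L
}
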