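# shared fixtures: tiny network configs, analytic test images, and the
# brute-force pixel-set oracles used against the geometric metric code

tiny_cfg <- function(input_size = 16L) {
  dafdnet_config(input_size = input_size, stage_channels = c(2L, 4L, 4L),
                 pf_channels = c(2L, 4L, 4L), gabor_scales = 1:2,
                 gabor_kernel = 7L)
}

reduced_cfg <- function(input_size = 128L) {
  dafdnet_config(input_size = input_size, stage_channels = c(8L, 16L, 32L),
                 pf_channels = c(8L, 16L, 32L), gabor_scales = c(1L, 2L))
}

# dark line through the image center with direction (cos theta, sin theta)
# in the (row, col) frame
line_image <- function(s, theta, width = 2, bg = 0.6, fg = 0.3) {
  img <- matrix(bg, s, s)
  ctr <- (s + 1) / 2
  dperp <- abs((row(img) - ctr) * cos(theta + pi / 2) +
                 (col(img) - ctr) * sin(theta + pi / 2))
  img[dperp <= width / 2] <- fg
  img
}

# pixel-set IOU oracle: rasterize both half-open boxes and count
pixel_box_iou <- function(a, b, lim = max(a, b) + 1) {
  grid <- function(bx) {
    m <- matrix(FALSE, lim, lim)
    if (bx[3] > bx[1] && bx[4] > bx[2])
      m[(bx[1] + 1):bx[3], (bx[2] + 1):bx[4]] <- TRUE
    m
  }
  ga <- grid(a); gb <- grid(b)
  un <- sum(ga | gb)
  if (un == 0) return(0)
  sum(ga & gb) / un
}

random_mask <- function(s, p = 0.3) matrix(stats::runif(s * s) < p, s, s)

# deterministic probability-map stub usable as a pipeline model
stub_model <- function(prob, input_size = nrow(prob)) {
  f <- function(image) prob
  attr(f, "input_size") <- input_size
  f
}
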