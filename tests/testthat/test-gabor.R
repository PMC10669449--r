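test_that("kernel center value matches the closed form (envelope and phase are 1 at the origin)", {
  sigma <- 2 * pi
  for (v in 1:3) {
    p <- gabor_params(u = 2, v = v, U = 8, kernel_size = 9)
    k <- gabor_kernel(p, dc_correct = FALSE)
    ctr <- k[5, 5]
    kv <- gabor_freq(v)
    expect_equal(Im(ctr), 0, tolerance = 1e-12)
    expect_equal(Re(ctr), (kv^2 / sigma^2) * (1 - exp(-sigma^2 / 2)),
                 tolerance = 1e-12)
  }
})

test_that("orthogonal orientations are exact 90-degree rotations of each other", {
  k0 <- gabor_kernel(gabor_params(0, 1, U = 8, kernel_size = 15))
  k4 <- gabor_kernel(gabor_params(4, 1, U = 8, kernel_size = 15))
  # rotating the sample grid by 90 degrees maps sample points to sample
  # points, so the equality is exact up to rounding; with the wave vector
  # along the x axis the rotated kernel is the transpose
  expect_lt(max(Mod(k4 - t(k0))), 1e-12)
})

test_that("parameter validation rejects bad orientation, scale and kernel size", {
  expect_error(gabor_params(8, 1, U = 8), "orientation")
  expect_error(gabor_params(-1, 1, U = 8), "orientation")
  expect_error(gabor_params(0, 0, U = 8), "scale")
  expect_error(gabor_params(0, 1, U = 8, kernel_size = 10), "odd")
  expect_error(gabor_bank(scales = integer(0)), "non-empty")
})

test_that("bank layout: counts, scale-major order, and orientation angles", {
  b <- gabor_bank()
  expect_length(b$kernels, 32L)
  expect_equal(gabor_n_channels(b), 32L)
  expect_length(gabor_bank(U = 1, scales = 1)$kernels, 1L)
  b8 <- gabor_bank(U = 8, scales = 1)
  expect_length(b8$kernels, 8L)
  expect_equal(gabor_angle(0:7, 8), (0:7) * pi / 8)
  # scale-major, orientation-minor indexing
  expect_equal(unname(b$index[1:9, "u"]), c(0:7, 0))
  expect_equal(unname(b$index[1:9, "v"]), c(rep(1L, 8), 2L))
  expect_equal(gabor_n_channels(gabor_bank(U = 4, scales = 1:2,
                                           response_mode = "real_imag")),
               16L)
})

test_that("every sampled kernel is zero-mean to 1e-6 of its norm", {
  b <- gabor_bank()
  for (k in b$kernels)
    expect_lt(Mod(sum(k)), 1e-6 * sqrt(sum(Mod(k)^2)))
})

test_that("scale law is positive and strictly decreasing in v", {
  kv <- gabor_freq(1:6)
  expect_true(all(kv > 0))
  expect_true(all(diff(kv) < 0))
  expect_equal(kv[1], pi / 2)
  expect_equal(kv[2], pi / 4)
})

test_that("constant image yields (interior) responses near zero", {
  b <- gabor_bank(U = 4, scales = 1:2)
  img <- matrix(0.7, 48, 48)
  resp <- gabor_conv(img, b)
  inner <- 9:40   # half-kernel border excluded: zero padding breaks
                  # zero-mean cancellation in the border band
  expect_lt(max(abs(resp[inner, inner, ])), 1e-4 * 0.7)
})

test_that("gabor_conv shape contract and channel ordering", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dim(gabor_conv(img, gabor_bank())), c(64, 64, 32))
  b <- gabor_bank(U = 2, scales = 1, response_mode = "real_imag")
  expect_equal(dim(gabor_conv(img, b)), c(64, 64, 4))
})

test_that("response is linear in the image (real/imag parts)", {
  set.seed(5)
  b <- gabor_bank(U = 4, scales = 1:2, kernel_size = 9,
                  response_mode = "real_imag")
  i1 <- matrix(runif(32 * 32), 32, 32)
  i2 <- matrix(runif(32 * 32), 32, 32)
  r <- gabor_conv(2.5 * i1 - 1.25 * i2, b)
  expect_equal(r, 2.5 * gabor_conv(i1, b) - 1.25 * gabor_conv(i2, b),
               tolerance = 1e-10)
})

test_that("a dark line excites the orientation channel nearest its direction", {
  b <- gabor_bank(U = 8, scales = 1)
  for (theta in c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2, 5 * pi / 8, 0.4)) {
    img <- line_image(65, theta)
    resp <- gabor_conv(img, b)
    inner <- 12:54
    m <- apply(resp[inner, inner, , drop = FALSE], 3, mean)
    # brute-force winner over the generated line image vs. the analytic
    # nearest-orientation prediction
    expect_equal(which.max(m) - 1L,
                 dafdnet:::gabor_line_channel(theta, 8L),
                 info = sprintf("theta = %.3f", theta))
  }
})

test_that("bank metadata JSON round-trips to an identical bank", {
  b <- gabor_bank(U = 4, scales = c(1, 3), kernel_size = 9,
                  response_mode = "real")
  path <- withr::local_tempfile(fileext = ".json")
  write_gabor_bank(b, path)
  b2 <- read_gabor_bank(path)
  expect_equal(b$Wre, b2$Wre, tolerance = 1e-14)
  expect_equal(b$Wim, b2$Wim, tolerance = 1e-14)
  expect_identical(b$response_mode, b2$response_mode)
})
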