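test_that("ghost convolution emits the configured channel count with the smallest split allowed", {
  set.seed(21)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(dim(ghost_conv(x, ghost_config(32)))[3], 32)
  y <- ghost_conv(x, ghost_config(2))      # 1 primary + 1 cheap channel
  expect_equal(dim(y)[3], 2)
  expect_error(ghost_config(1), "out_channels")
})

test_that("ghost convolution spends strictly fewer parameters than a plain convolution", {
  # arithmetic parameter-count oracle, written out per branch
  for (C in c(8L, 16L, 32L, 64L, 128L)) {
    cfg <- ghost_config(C, ratio = 0.5)
    m <- ceiling(C / 2)
    oracle_ghost <- C * m * 9 + m + (C - m) * (9 + 1)
    oracle_plain <- C * C * 9 + C
    got <- ghost_param_count(C, cfg)
    expect_equal(unname(got["ghost"]), oracle_ghost)
    expect_equal(unname(got["plain"]), oracle_plain)
    expect_lt(got["ghost"], 0.6 * got["plain"])
  }
})

test_that("SE weights: sigmoid(0) = 0.5 under zero parameters, always in (0,1), exact squeeze of constants", {
  cfg <- se_config(6, reduction = 2)
  x <- array(runif(8 * 8 * 6), c(8, 8, 6))
  p0 <- dafdnet:::se_init(cfg)
  p0$W1[] <- 0; p0$W2[] <- 0; p0$b1[] <- 0; p0$b2[] <- 0
  expect_equal(se_block(x, cfg, p0), rep(0.5, 6))
  set.seed(3)
  w <- se_block(x, cfg)
  expect_true(all(w > 0 & w < 1))
  # spatially constant channels squeeze to exactly those constants
  const <- array(rep(c(0.1, 0.4, 0.9), each = 64), c(8, 8, 3))
  sq <- dafdnet:::gap_fw(const)
  expect_equal(sq, c(0.1, 0.4, 0.9))
  expect_error(se_block(x, se_config(4)), "channels")
})

test_that("SE-ghost module: channel contract and identity reweighting when gates are forced open", {
  set.seed(22)
  x <- array(runif(16 * 16 * 32), c(16, 16, 32))
  cfg <- ghost_config(64)
  p <- dafdnet:::se_ghost_init(32, cfg)
  y <- se_ghost_module(x, cfg, params = p)
  expect_equal(dim(y), c(16, 16, 64))
  # force the excitation logits far positive: sigmoid -> 1, so the module
  # degenerates to concatenating the primary result with itself
  p1 <- p; p1$se$W1[] <- 0; p1$se$W2[] <- 0; p1$se$b1[] <- 0
  p1$se$b2[] <- 60
  y1 <- se_ghost_module(x, cfg, params = p1)
  expect_equal(y1[, , 1:32], y1[, , 33:64], tolerance = 1e-12)
})

test_that("SE-ghost module on a zero input still produces gates in (0,1)", {
  x <- array(0, c(8, 8, 4))
  cfg <- ghost_config(8)
  set.seed(4)
  p <- dafdnet:::se_ghost_init(4, cfg)
  fw <- dafdnet:::se_ghost_fw(x, p)
  expect_true(all(fw$cache$w > 0 & fw$cache$w < 1))
  expect_equal(dim(fw$y), c(8, 8, 8))
})

test_that("SCA attention preserves shape, never amplifies, and is identity when gates are forced open", {
  set.seed(23)
  x <- array(runif(12 * 12 * 8, -1, 1), c(12, 12, 8))
  p <- dafdnet:::sca_init(8)
  y <- sca_attention(x, p)
  expect_equal(dim(y), dim(x))
  # gates lie in (0,1), so magnitudes can only shrink (elementwise oracle)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  # forcing both gates to ~1 makes the attention an identity
  p1 <- p
  p1$se$W1[] <- 0; p1$se$W2[] <- 0; p1$se$b1[] <- 0; p1$se$b2[] <- 60
  p1$Ws[] <- 0; p1$bs <- 60
  expect_equal(sca_attention(x, p1), x, tolerance = 1e-12)
})

test_that("blocks are deterministic given fixed parameters", {
  set.seed(24)
  x <- array(runif(10 * 10 * 4), c(10, 10, 4))
  cfg <- ghost_config(8)
  p <- dafdnet:::se_ghost_init(4, cfg)
  expect_identical(se_ghost_module(x, cfg, params = p),
                   se_ghost_module(x, cfg, params = p))
  ps <- dafdnet:::sca_init(4)
  expect_identical(sca_attention(x, ps), sca_attention(x, ps))
})
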