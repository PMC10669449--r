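test_that("configuration validates divisibility and scales sizes without touching channels", {
  expect_error(dafdnet_config(input_size = 130), "divisible")
  c1 <- dafdnet_config(input_size = 128)
  c2 <- dafdnet_config(input_size = 256)
  expect_equal(c1$stage_channels, c2$stage_channels)
})

test_that("forward probe shapes follow the size contract at a small input", {
  model <- build_dafdnet(tiny_cfg(16), seed = 2)
  pr <- dafdnet_probe(model)
  expect_equal(pr$size[pr$layer == "Input"], 16)
  expect_equal(pr$size[pr$layer == "GhoM2"], 8)
  expect_equal(pr$size[pr$layer == "A3"], 4)
  expect_equal(pr$size[pr$layer == "Output"], 16)
  expect_equal(pr$channels[pr$layer == "Output"], 1)
  # channel arithmetic: GG = gabor + ghost; A = ghost + pf
  expect_equal(pr$channels[pr$layer == "GG1"], 16 + 2)
  expect_equal(pr$channels[pr$layer == "A1"], 2 + 2)
})

test_that("forward output is a probability map: [0,1], input-sized, bit-reproducible", {
  model <- build_dafdnet(tiny_cfg(16), seed = 3)
  img <- matrix(runif(16 * 16), 16, 16)
  p1 <- dafdnet_forward(model, img)$prob
  p2 <- dafdnet_forward(model, img)$prob
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(16, 16))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(dafdnet_forward(model, matrix(0, 8, 8)), "expected")
})

test_that("mean-squared-error loss matches direct arithmetic", {
  a <- matrix(0.5, 4, 4); z <- matrix(0, 4, 4); o <- matrix(1, 4, 4)
  expect_equal(mse_loss(z, z), 0)
  expect_equal(mse_loss(o, z), 1)
  expect_equal(mse_loss(a, z), 0.25)
  expect_error(mse_loss(a, matrix(0, 4, 5)), "shape")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  model <- build_dafdnet(tiny_cfg(16), seed = 7)
  img <- matrix(runif(16 * 16), 16, 16)
  gt <- matrix(0, 16, 16); gt[6:9, 4:12] <- 1
  fw <- dafdnet_forward(model, img, keep_cache = TRUE)
  gr <- dafdnet:::dafdnet_backward(model, fw$cache,
                                   2 * (fw$prob - gt) / length(gt))
  flat <- dafdnet:::flatten_params(model$params)
  expect_setequal(names(gr), names(flat))
  loss_at <- function(flat2) {
    m2 <- model
    m2$params <- dafdnet:::assign_params(m2$params, flat2)
    mse_loss(dafdnet_forward(m2, img)$prob, gt)
  }
  eps <- 1e-6
  # spot-check a few entries in every parameter group family
  for (k in c("gh1.Wp", "gh2.se.W2", "gh3.gamma", "pf2.W", "pf1.beta",
              "sca1.Ws", "sca3.se.W1", "dec2.W", "dec1.b", "out.W",
              "out.b")) {
    for (rep in 1:2) {
      j <- sample(length(flat[[k]]), 1)
      f1 <- flat; f1[[k]][j] <- f1[[k]][j] + eps
      f2 <- flat; f2[[k]][j] <- f2[[k]][j] - eps
      num <- (loss_at(f1) - loss_at(f2)) / (2 * eps)
      expect_equal(gr[[k]][j], num, tolerance = 1e-3,
                   info = paste("param", k, "entry", j))
    }
  }
})

test_that("one Adam step on a fixed batch strictly decreases that batch's loss", {
  set.seed(13)
  model <- build_dafdnet(tiny_cfg(16), seed = 5)
  img <- matrix(runif(16 * 16), 16, 16)
  gt <- matrix(0, 16, 16); gt[4:10, 8:12] <- 1
  l0 <- mse_loss(dafdnet_forward(model, img)$prob, gt)
  fit <- dafdnet_train(model, list(img), list(gt),
                       train_config(batch_size = 1, lr_init = 1e-4,
                                    lr_max = 1e-4, lr_step = 0,
                                    epochs = 1, seed = 1))
  l1 <- mse_loss(dafdnet_forward(fit$model, img)$prob, gt)
  expect_lt(l1, l0)
})

test_that("checkpoints round-trip through disk with their config sidecar", {
  model <- build_dafdnet(tiny_cfg(16), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_dafdnet(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_dafdnet(path)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_identical(dafdnet_forward(model, img)$prob,
                   dafdnet_forward(m2, img)$prob)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$input_size, 16)
})
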