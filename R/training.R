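#' Training configuration
#'
#' Mirrors the published optimization recipe: Adam, batches of 12 randomly
#' chosen images, and a learning rate warmed up from 1e-5 to 4e-5 in 1e-5
#' steps (per epoch) and held there.
#'
#' @param batch_size images per optimization step.
#' @param lr_init,lr_max,lr_step warm-up schedule; `lr_max - lr_init` must
#'   be an integer multiple of `lr_step` (a `lr_step` of 0 gives a constant
#'   rate).
#' @param epochs maximum number of epochs.
#' @param seed integer seed covering shuffling (weight initialization and
#'   augmentation draw from the same global stream when run in sequence).
#' @param shuffle reshuffle the dataset each epoch.
#' @param patience early-stopping patience on validation loss (epochs);
#'   only active when a validation set is supplied.
#' @export
train_config <- function(batch_size = 12L, lr_init = 1e-5, lr_max = 4e-5,
                         lr_step = 1e-5, epochs = 100L, seed = 1L,
                         shuffle = TRUE, patience = 20L) {
  if (lr_init > lr_max) stop("lr_init must not exceed lr_max")
  if (lr_step > 0) {
    k <- (lr_max - lr_init) / lr_step
    if (abs(k - round(k)) > 1e-8)
      stop("(lr_max - lr_init) must be an integer multiple of lr_step")
  } else if (lr_step == 0 && lr_max != lr_init) {
    stop("lr_step = 0 requires lr_max == lr_init")
  }
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_max = lr_max, lr_step = lr_step,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), patience = as.integer(patience)),
            class = "train_config")
}

#' Warm-up learning-rate schedule
#'
#' `lr_init + epoch * lr_step`, capped at `lr_max`; epochs count from 0.
#'
#' @param epoch non-negative integer epoch index.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(all(epoch >= 0))
  pmin(cfg$lr_init + epoch * cfg$lr_step, cfg$lr_max)
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    gk <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Train the detection network
#'
#' Mini-batch Adam optimization of the mean-squared error between the
#' network's probability map and a binary target mask. The frozen Gabor
#' features of every image are computed once up front and reused across
#' epochs. Fully reproducible given `(seed, dataset, cfg)`.
#'
#' @param model a `dafdnet` model from [build_dafdnet()].
#' @param images list of input matrices (side `cfg$input_size`).
#' @param masks list of binary matrices aligned to `images`.
#' @param cfg a [train_config()].
#' @param val_images,val_masks optional validation set; enables
#'   patience-based early stopping.
#' @param verbose log one line per epoch (epoch, loss, lr) to stderr.
#' @return list with the trained `model` and `history`, a data.frame with
#'   one row per epoch (`epoch`, `loss`, `val_loss`, `lr`).
#' @export
dafdnet_train <- function(model, images, masks, cfg = train_config(),
                          val_images = NULL, val_masks = NULL,
                          verbose = FALSE) {
  n <- length(images)
  if (n == 0L) stop("empty training dataset")
  if (length(masks) != n) stop("images and masks differ in length")
  s <- model$cfg$input_size
  for (i in seq_len(n)) {
    if (!all(dim(images[[i]]) == c(s, s)))
      stop("image ", i, " is not ", s, "x", s)
    if (!all(dim(masks[[i]]) == dim(images[[i]])))
      stop("mask ", i, " is not aligned to its image")
  }
  set.seed(cfg$seed)
  gab <- lapply(images, function(im) dafdnet_gabor_features(model, im))
  gab_val <- if (!is.null(val_images))
    lapply(val_images, function(im) dafdnet_gabor_features(model, im))
  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  bs <- max(1L, min(cfg$batch_size, n))
  hist <- vector("list", cfg$epochs)
  best_val <- Inf; wait <- 0L
  npix <- s * s
  for (e in seq_len(cfg$epochs)) {
    lr <- lr_schedule(e - 1L, cfg)
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    losses <- c()
    for (b0 in seq(1L, n, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1L, n)]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        fw <- dafdnet_forward(model, images[[i]], gab = gab[[i]],
                              keep_cache = TRUE)
        bl <- bl + mse_loss(fw$prob, masks[[i]])
        dprob <- 2 * (fw$prob - masks[[i]]) / npix
        gr <- dafdnet_backward(model, fw$cache, dprob)
        if (is.null(acc)) acc <- gr
        else for (k in names(acc)) acc[[k]] <- acc[[k]] + gr[[k]]
      }
      for (k in names(acc)) acc[[k]] <- acc[[k]] / length(idx)
      st <- adam_step(flat, acc, state, lr)
      flat <- st$flat; state <- st$state
      model$params <- assign_params(model$params, flat)
      losses <- c(losses, bl / length(idx))
    }
    vl <- NA_real_
    if (!is.null(val_images)) {
      vl <- mean(vapply(seq_along(val_images), function(i)
        mse_loss(dafdnet_forward(model, val_images[[i]],
                                 gab = gab_val[[i]])$prob,
                 val_masks[[i]]), numeric(1)))
      if (vl < best_val - 1e-9) { best_val <- vl; wait <- 0L }
      else wait <- wait + 1L
    }
    hist[[e]] <- data.frame(epoch = e, loss = mean(losses), val_loss = vl,
                            lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val %.5f  lr %.2e",
                      e, mean(losses), vl, lr))
    if (!is.null(val_images) && wait >= cfg$patience) break
  }
  list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                            logical(1))]))
}
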