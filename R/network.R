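#' Direction-aware fracture-detection network configuration
#'
#' The network is a three-stage encoder-decoder. The encoder runs two
#' parallel paths: a ghost path (SE-ghost modules separated by 2x2
#' average-pool downsampling) and a direction-aware path (a fixed Gabor
#' filter bank applied to the input, downsampled alongside). At each stage
#' the two are concatenated (`GG_i`), refined by a size-preserving 2x2 mean,
#' a 3x3 convolution and feature normalization (`PF_i`), re-joined with the
#' ghost features and passed through channel-then-spatial attention
#' (`A_i`). The decoder upsamples the coarsest attention map, concatenates
#' stage by stage, and ends in a 1x1 convolution and sigmoid, giving a
#' per-pixel fracture probability at input resolution.
#'
#' @param input_size spatial side in pixels; must be divisible by 4 so the
#'   two down/up-sampling rounds are exact. 1024 is the full clinical-scale
#'   default; 128 is the customary desk-scale test size.
#' @param stage_channels ghost-path channels per stage.
#' @param pf_channels refinement-path channels per stage.
#' @param gabor_U,gabor_scales,gabor_kernel Gabor bank layout (8
#'   orientations x 4 octave scales = 32 channels by default).
#' @param ghost_ratio primary-branch fraction in each SE-ghost module.
#' @param se_reduction SE bottleneck divisor.
#' @param upsample `"nearest"` (default) or `"smoothed"` (nearest followed
#'   by a size-preserving 2x2 mean).
#' @return a `dafdnet_config` list.
#' @export
dafdnet_config <- function(input_size = 1024L,
                           stage_channels = c(32L, 64L, 128L),
                           pf_channels = stage_channels,
                           gabor_U = 8L, gabor_scales = 1:4,
                           gabor_kernel = 15L,
                           ghost_ratio = 0.5, se_reduction = 4L,
                           upsample = c("nearest", "smoothed")) {
  upsample <- match.arg(upsample)
  input_size <- as.integer(input_size)
  if (input_size %% 4L != 0L)
    stop("input_size must be divisible by 4 (two 2x downsampling rounds)")
  stopifnot(length(stage_channels) == 3L, length(pf_channels) == 3L)
  structure(list(input_size = input_size,
                 stage_channels = as.integer(stage_channels),
                 pf_channels = as.integer(pf_channels),
                 gabor_U = as.integer(gabor_U),
                 gabor_scales = as.integer(gabor_scales),
                 gabor_kernel = as.integer(gabor_kernel),
                 ghost_ratio = ghost_ratio,
                 se_reduction = as.integer(se_reduction),
                 upsample = upsample, n_stages = 3L),
            class = "dafdnet_config")
}

#' Build the detection network
#'
#' Initializes all learnable parameters (He-scaled weights, zero biases,
#' unit normalization scale). The terminal 1x1 convolution's bias starts at
#' -4 so an untrained network predicts the background prior rather than
#' 0.5 everywhere, which shortens mean-squared-error training on sparse
#' masks.
#'
#' @param cfg a [dafdnet_config()].
#' @param seed optional integer; when given, parameter initialization is
#'   reproducible.
#' @return a `dafdnet` model object.
#' @export
build_dafdnet <- function(cfg = dafdnet_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- cfg$stage_channels; pc <- cfg$pf_channels
  bank <- gabor_bank(cfg$gabor_U, cfg$gabor_scales, cfg$gabor_kernel)
  gc_ <- gabor_n_channels(bank)
  in_ch <- c(1L, sc[1], sc[2])
  p <- list()
  for (i in 1:3)
    p[[paste0("gh", i)]] <- se_ghost_init(
      in_ch[i], ghost_config(sc[i], cfg$ghost_ratio), cfg$se_reduction)
  gg_ch <- sc + gc_
  for (i in 1:3)
    p[[paste0("pf", i)]] <- list(W = conv_w_init(gg_ch[i], pc[i], 3L),
                                 b = rep(0, pc[i]),
                                 gamma = rep(1, pc[i]), beta = rep(0, pc[i]))
  a_ch <- sc + pc
  for (i in 1:3)
    p[[paste0("sca", i)]] <- sca_init(a_ch[i], cfg$se_reduction)
  p$dec2 <- list(W = conv_w_init(a_ch[3] + a_ch[2], sc[2], 3L),
                 b = rep(0, sc[2]))
  p$dec1 <- list(W = conv_w_init(sc[2] + a_ch[1], sc[1], 3L),
                 b = rep(0, sc[1]))
  p$out <- list(W = conv_w_init(sc[1], 1L, 1L, gain = 1), b = -4)
  structure(list(cfg = cfg, bank = bank, params = p), class = "dafdnet")
}

#' @export
print.dafdnet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "dafdnet: input %dx%d, stages [%s], gabor %d ch, %d parameters\n",
    cfg$input_size, cfg$input_size,
    paste(cfg$stage_channels, collapse = ", "),
    gabor_n_channels(x$bank), n_params(x)))
  invisible(x)
}

#' @rdname print.dafdnet
#' @param model a `dafdnet` model.
#' @export
n_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

## flatten/unflatten the nested parameter list (metadata keys excluded)
.param_meta_keys <- c("cfg", "in_channels", "spatial_kernel", "channels")

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    if (nm %in% .param_meta_keys) next
    v <- p[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v) && is.null(attr(v, "class")))
      out <- c(out, flatten_params(v, key))
    else if (is.numeric(v)) out[[key]] <- v
  }
  out
}

assign_params <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

up_fw <- function(x, mode) {
  if (mode == "smoothed") pool2_same(up2(x)) else up2(x)
}
up_bw <- function(dy, mode) {
  if (mode == "smoothed") up2_bw(pool2_same_bw(dy)) else up2_bw(dy)
}

cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' Forward pass
#'
#' Deterministic given fixed parameters. With `probe = TRUE` the named
#' intermediate feature maps (`Gab1..3`, `GhoM1..3`, `GG1..3`, `PF1..3`,
#' `A1..3`) are returned alongside the probability map so architecture
#' conformance can be checked on a live pass.
#'
#' @param model a `dafdnet` model.
#' @param image numeric matrix of side `cfg$input_size`, values in `[0,1]`.
#' @param probe keep intermediate feature maps.
#' @param gab optional precomputed Gabor features (list `Gab1..3`) for the
#'   same image; the Gabor path is fixed, so training loops cache it.
#' @param keep_cache keep everything needed for [dafdnet_backward()].
#' @return list with `prob` (H x W matrix in `[0,1]`), and optionally
#'   `probes` and `cache`.
#' @export
dafdnet_forward <- function(model, image, probe = FALSE, gab = NULL,
                            keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  x <- as_fmap(image)
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 1L)
    stop("expected a ", cfg$input_size, "x", cfg$input_size,
         " single-channel image, got ", d[1], "x", d[2], "x", d[3])
  if (is.null(gab)) gab <- dafdnet_gabor_features(model, image)

  gh <- vector("list", 3); GhoM <- vector("list", 3)
  Lin <- vector("list", 3)
  Lin[[1]] <- x
  for (i in 1:3) {
    gh[[i]] <- se_ghost_fw(Lin[[i]], p[[paste0("gh", i)]])
    GhoM[[i]] <- gh[[i]]$y
    if (i < 3) Lin[[i + 1]] <- down2(GhoM[[i]])
  }
  GG <- PFc <- PF <- Ain <- sca <- A <- vector("list", 3)
  for (i in 1:3) {
    GG[[i]] <- cat3(gab[[i]], GhoM[[i]])
    pa <- pool2_same(GG[[i]])
    pp <- p[[paste0("pf", i)]]
    c0 <- conv2d(pa, pp$W, pp$b, 3L)
    nf <- norm_fw(c0, pp$gamma, pp$beta)
    PF[[i]] <- relu(nf$y)
    PFc[[i]] <- list(pa = pa, c0 = c0, nrm = nf$cache, y = nf$y)
    Ain[[i]] <- cat3(GhoM[[i]], PF[[i]])
    sca[[i]] <- sca_fw(Ain[[i]], p[[paste0("sca", i)]])
    A[[i]] <- sca[[i]]$y
  }
  U3 <- up_fw(A[[3]], cfg$upsample)
  C2 <- cat3(U3, A[[2]])
  D2c <- conv2d(C2, p$dec2$W, p$dec2$b, 3L)
  D2 <- relu(D2c)
  U2 <- up_fw(D2, cfg$upsample)
  C1 <- cat3(U2, A[[1]])
  D1c <- conv2d(C1, p$dec1$W, p$dec1$b, 3L)
  D1 <- relu(D1c)
  logit <- conv2d(D1, p$out$W, p$out$b, 1L)
  prob <- sigmoid(logit[, , 1])

  out <- list(prob = prob)
  if (probe) {
    pr <- list(Input = x)
    for (i in 1:3) pr[[paste0("Gab", i)]] <- gab[[i]]
    for (i in 1:3) pr[[paste0("GhoM", i)]] <- GhoM[[i]]
    for (i in 1:3) pr[[paste0("GG", i)]] <- GG[[i]]
    for (i in 1:3) pr[[paste0("PF", i)]] <- PF[[i]]
    for (i in 1:3) pr[[paste0("A", i)]] <- A[[i]]
    pr$Output <- array(prob, c(dim(prob), 1L))
    out$probes <- pr
  }
  if (keep_cache)
    out$cache <- list(x = x, gab = gab, gh = gh, GhoM = GhoM, Lin = Lin,
                      GG = GG, PFc = PFc, PF = PF, Ain = Ain, sca = sca,
                      A = A, U3 = U3, C2 = C2, D2c = D2c, D2 = D2, U2 = U2,
                      C1 = C1, D1c = D1c, D1 = D1, prob = prob)
  out
}

#' Gabor-path features for one image
#'
#' The Gabor path is frozen, so its three per-stage feature maps depend only
#' on the image; training caches them per sample.
#'
#' @inheritParams dafdnet_forward
#' @export
dafdnet_gabor_features <- function(model, image) {
  g1 <- gabor_conv(as_fmap(image)[, , 1], model$bank)
  g2 <- down2(g1)
  list(g1, g2, down2(g2))
}

# gradient of everything learnable; dprob is dLoss/dprob (H x W)
dafdnet_backward <- function(model, cache, dprob) {
  cfg <- model$cfg; p <- model$params
  g <- list()
  prob <- cache$prob
  dlogit <- array(dprob * prob * (1 - prob), c(dim(prob), 1L))
  cb <- conv2d_bw(cache$D1, p$out$W, dlogit, 1L)
  g[["out.W"]] <- cb$dW; g[["out.b"]] <- drop(cb$db)
  dD1 <- relu_bw(cache$D1c, cb$dx)
  cb <- conv2d_bw(cache$C1, p$dec1$W, dD1, 3L)
  g[["dec1.W"]] <- cb$dW; g[["dec1.b"]] <- drop(cb$db)
  nU2 <- dim(cache$U2)[3]
  dU2 <- cb$dx[, , seq_len(nU2), drop = FALSE]
  dA <- vector("list", 3)
  dA[[1]] <- cb$dx[, , nU2 + seq_len(dim(cache$A[[1]])[3]), drop = FALSE]
  dD2 <- relu_bw(cache$D2c, up_bw(dU2, cfg$upsample))
  cb <- conv2d_bw(cache$C2, p$dec2$W, dD2, 3L)
  g[["dec2.W"]] <- cb$dW; g[["dec2.b"]] <- drop(cb$db)
  nU3 <- dim(cache$U3)[3]
  dU3 <- cb$dx[, , seq_len(nU3), drop = FALSE]
  dA[[2]] <- cb$dx[, , nU3 + seq_len(dim(cache$A[[2]])[3]), drop = FALSE]
  dA[[3]] <- up_bw(dU3, cfg$upsample)

  dGhoM <- vector("list", 3)
  for (i in 3:1) {
    sb <- sca_bw(p[[paste0("sca", i)]], cache$sca[[i]]$cache, dA[[i]])
    for (nm in names(sb$grads))
      g[[paste0("sca", i, ".", nm)]] <- sb$grads[[nm]]
    nG <- dim(cache$GhoM[[i]])[3]
    dGhoM_i <- sb$dx[, , seq_len(nG), drop = FALSE]
    dPF <- sb$dx[, , nG + seq_len(dim(cache$PF[[i]])[3]), drop = FALSE]
    pfc <- cache$PFc[[i]]; pp <- p[[paste0("pf", i)]]
    dPFn <- relu_bw(pfc$y, dPF)
    nb <- norm_bw(pfc$nrm, pp$gamma, dPFn)
    cb <- conv2d_bw(pfc$pa, pp$W, nb$dx, 3L)
    g[[paste0("pf", i, ".W")]] <- cb$dW
    g[[paste0("pf", i, ".b")]] <- drop(cb$db)
    g[[paste0("pf", i, ".gamma")]] <- nb$dgamma
    g[[paste0("pf", i, ".beta")]] <- nb$dbeta
    dGG <- pool2_same_bw(cb$dx)
    nGab <- dim(cache$gab[[i]])[3]
    dGhoM_i <- dGhoM_i + dGG[, , nGab + seq_len(nG), drop = FALSE]
    dGhoM[[i]] <- dGhoM_i
  }
  # ghost chain (stage i feeds stage i+1 through down2)
  for (i in 3:1) {
    d_i <- dGhoM[[i]]
    if (i < 3) d_i <- d_i + attr(dGhoM, paste0("chain", i))
    gb <- se_ghost_bw(p[[paste0("gh", i)]], cache$gh[[i]]$cache, d_i)
    for (nm in names(gb$grads))
      g[[paste0("gh", i, ".", nm)]] <- gb$grads[[nm]]
    if (i > 1) attr(dGhoM, paste0("chain", i - 1)) <- down2_bw(gb$dx)
  }
  g
}

#' Mean-squared-error loss between a probability map and a binary mask
#'
#' @param pred numeric matrix in `[0,1]` (a forward pass's `prob`).
#' @param gt binary matrix of the same shape.
#' @return non-negative scalar; zero iff `pred == gt` everywhere.
#' @export
mse_loss <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("prediction and ground truth shapes differ")
  mean((pred - gt)^2)
}

#' Probe intermediate shapes of a forward pass
#'
#' @inheritParams dafdnet_forward
#' @return data.frame with one row per named intermediate: stage name,
#'   spatial side, channel count.
#' @export
dafdnet_probe <- function(model, image = NULL) {
  if (is.null(image))
    image <- matrix(0.5, model$cfg$input_size, model$cfg$input_size)
  pr <- dafdnet_forward(model, image, probe = TRUE)$probes
  data.frame(layer = names(pr),
             size = vapply(pr, function(a) dim(a)[1], numeric(1)),
             channels = vapply(pr, function(a) dim(a)[3], numeric(1)),
             row.names = NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the serialized model plus a JSON sidecar carrying the
#' configuration, so a checkpoint is self-describing.
#'
#' @param model a `dafdnet` model.
#' @param path checkpoint file path (`.rds`).
#' @export
save_dafdnet <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$cfg
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dafdnet
#' @export
load_dafdnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dafdnet"))
  model
}
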