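# On-disk artifacts: grayscale image readers/writers (PNG/TIFF, 8- or
# 16-bit), binary mask PNGs, run configuration (YAML/JSON with strict
# keys), and the command-line dispatcher.

#' Load a grayscale image
#'
#' PNG or TIFF, 8- or 16-bit, 1 or 3 channels; 3-channel images are
#' converted to luminance (Rec. 601 weights). Values are normalized to
#' `[0,1]` from the container's bit depth (png/tiff readers already emit
#' that scale).
#'
#' @param path image file path.
#' @return numeric matrix in `[0,1]` (rows = image rows).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format (need png/tif/tiff): ", path))
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a
}

#' Save a grayscale image / a binary mask as 8-bit PNG
#'
#' Masks are written with foreground 255 and background 0.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param mask logical (or 0/1) matrix.
#' @param path output path.
#' @export
save_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname save_image
#' @export
save_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Run configuration
#'
#' One flat YAML/JSON file covering the network, training, and
#' augmentation settings plus paths and the master seed. Every field has a
#' default (an empty file is valid); unknown keys are rejected.
#'
#' @param path optional YAML (`.yml`/`.yaml`) or JSON file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return named list of settings.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    vals <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(vals)) vals <- list()
  }
  for (src in list(vals, overrides)) {
    bad <- setdiff(names(src), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(src)] <- src
  }
  cfg
}

default_run_config <- function() {
  list(input_size = 128L, stage_channels = c(32L, 64L, 128L),
       gabor_U = 8L, gabor_scales = 1:4, gabor_kernel = 15L,
       batch_size = 12L, lr_init = 1e-5, lr_max = 4e-5, lr_step = 1e-5,
       epochs = 50L, seed = 1L,
       rotation_range = c(-15, 15), scale_factor = 0.95, n_variants = 8L,
       image_size = 256L, threshold = 0.5, margin = 0.1)
}

## -- command-line interface ----------------------------------------------

dafd_log <- function(level, ..., verbosity = 1L) {
  lv <- c(error = 0L, info = 1L, debug = 2L)[[level]]
  if (lv <= verbosity)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), paste0(...)))
}

parse_flags <- function(args, allowed) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("-q", "-v")) {
      out$verbosity <- if (a == "-q") 0L else 2L
      i <- i + 1L; next
    }
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (!key %in% allowed) stop("unknown flag: --", key)
    if (i == length(args)) stop("flag --", key, " needs a value")
    out[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write an augmented phantom dataset),
#' `train` (train an ROI- or fracture-stage network on a generated
#' dataset), `predict` (run the two-phase pipeline on one image),
#' `evaluate` (score predicted masks against label masks). A thin wrapper
#' script at `inst/cli/dafdnet.R` forwards `commandArgs()` here.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 1 runtime failure, 2 usage
#'   error).
#' @export
dafd_main <- function(argv = character()) {
  usage <- paste(
    "usage: dafdnet <generate|train|predict|evaluate> [flags]",
    "  generate --n N --out DIR [--seed S] [--size PX] [--variants K]",
    "  train    --data DIR --out MODEL.rds --stage <roi|frac>",
    "           [--config FILE] [--epochs N] [--seed S] [--size PX]",
    "  predict  --image IMG --roi-model CKPT --frac-model CKPT --out JSON",
    "           [--overlay PNG] [--label-mask PNG] [--threshold P]",
    "  evaluate --pred-dir DIR --label-dir DIR --out PREFIX", sep = "\n")
  if (length(argv) == 0L || argv[1] %in% c("-h", "--help")) {
    message(usage); return(if (length(argv)) 0L else 2L)
  }
  cmd <- argv[1]
  rest <- argv[-1]
  res <- tryCatch({
    switch(cmd,
           generate = cli_generate(rest),
           train = cli_train(rest),
           predict = cli_predict(rest),
           evaluate = cli_evaluate(rest),
           { message("unknown subcommand: ", cmd, "\n", usage)
             return(2L) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("unknown flag|unexpected argument|needs a value",
              conditionMessage(e))) 2L else 1L
  })
  res
}

cli_generate <- function(args) {
  fl <- parse_flags(args, c("n", "out", "seed", "size", "variants",
                            "split"))
  if (is.null(fl$n) || is.null(fl$out)) stop("generate needs --n and --out")
  verb <- fl$verbosity %||% 1L
  n <- as.integer(fl$n)
  aug <- augment_spec(n_variants = as.integer(fl$variants %||% 8L))
  ds <- make_phantom_dataset(
    n_base = n,
    split_fraction = as.numeric(fl$split %||% (3000 / 3840)),
    image_size = as.integer(fl$size %||% 256L), aug = aug,
    seed = as.integer(fl$seed %||% 1L), keep = "manifest",
    out_dir = fl$out)
  dafd_log("info", sprintf("wrote %d images (%d train / %d test) to %s",
                           nrow(ds$manifest), length(ds$train),
                           length(ds$test), fl$out), verbosity = verb)
  invisible(NULL)
}

cli_train <- function(args) {
  fl <- parse_flags(args, c("data", "out", "stage", "config", "epochs",
                            "seed", "size", "batch"))
  if (is.null(fl$data) || is.null(fl$out) || is.null(fl$stage))
    stop("train needs --data, --out and --stage")
  if (!fl$stage %in% c("roi", "frac")) stop("--stage must be roi or frac")
  verb <- fl$verbosity %||% 1L
  rc <- load_run_config(fl$config)
  size <- as.integer(fl$size %||% rc$input_size)
  man <- file.path(fl$data, "manifest.jsonl")
  if (!file.exists(man)) stop("no manifest.jsonl under ", fl$data)
  rows <- lapply(readLines(man), function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE))
  suffix <- if (fl$stage == "roi") "_roi.png" else "_frac.png"
  images <- list(); masks <- list()
  for (r in rows) {
    if (r$split != "train") next
    stem <- sprintf("b%04d_v%02d", r$base_id, r$variant)
    im <- load_image(file.path(fl$data, paste0(stem, ".png")))
    mk <- load_image(file.path(fl$data, paste0(stem, suffix))) >= 0.5
    images[[length(images) + 1L]] <- resize_mat(im, size, size)
    masks[[length(masks) + 1L]] <- resize_mat(mk * 1, size, size) >= 0.5
  }
  cfg <- dafdnet_config(input_size = size,
                        stage_channels = rc$stage_channels,
                        gabor_U = rc$gabor_U,
                        gabor_scales = rc$gabor_scales,
                        gabor_kernel = rc$gabor_kernel)
  seed <- as.integer(fl$seed %||% rc$seed)
  model <- build_dafdnet(cfg, seed = seed)
  tc <- train_config(batch_size = as.integer(fl$batch %||% rc$batch_size),
                     lr_init = rc$lr_init, lr_max = rc$lr_max,
                     lr_step = rc$lr_step,
                     epochs = as.integer(fl$epochs %||% rc$epochs),
                     seed = seed)
  fit <- dafdnet_train(model, images, masks, tc, verbose = verb >= 2L)
  save_dafdnet(fit$model, fl$out)
  utils::write.csv(fit$history, paste0(fl$out, ".history.csv"),
                   row.names = FALSE)
  dafd_log("info", sprintf("trained %s stage on %d images; final loss %.5f",
                           fl$stage, length(images),
                           utils::tail(fit$history$loss, 1)),
           verbosity = verb)
  invisible(NULL)
}

cli_predict <- function(args) {
  fl <- parse_flags(args, c("image", "roi-model", "frac-model", "out",
                            "overlay", "label-mask", "threshold"))
  if (is.null(fl$image) || is.null(fl$roi_model) || is.null(fl$frac_model)
      || is.null(fl$out))
    stop("predict needs --image, --roi-model, --frac-model and --out")
  img <- load_image(fl$image)
  roi_model <- load_dafdnet(fl$roi_model)
  frac_model <- load_dafdnet(fl$frac_model)
  det <- run_pipeline(img, roi_model, frac_model,
                      threshold = as.numeric(fl$threshold %||% 0.5))
  out <- list(image = fl$image, found = isTRUE(det$found),
              no_roi = isTRUE(det$no_roi),
              max_probability = det$max_probability,
              fracture_box_crop = det$fracture_box_crop,
              fracture_box_full = det$fracture_box_full,
              roi_box = if (!isTRUE(det$no_roi)) det$roi$crop_box)
  jsonlite::write_json(out, fl$out, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(fl$overlay)) {
    lab_box <- NULL
    if (!is.null(fl$label_mask))
      lab_box <- mask_bbox(load_image(fl$label_mask) >= 0.5)
    write_overlay(img, pred_box = det$fracture_box_full,
                  label_box = lab_box, path = fl$overlay)
  }
  invisible(NULL)
}

cli_evaluate <- function(args) {
  fl <- parse_flags(args, c("pred-dir", "label-dir", "out"))
  if (is.null(fl$pred_dir) || is.null(fl$label_dir) || is.null(fl$out))
    stop("evaluate needs --pred-dir, --label-dir and --out")
  preds <- sort(list.files(fl$pred_dir, pattern = "\\.png$"))
  if (!length(preds)) stop("no mask PNGs under ", fl$pred_dir)
  recs <- list()
  for (f in preds) {
    lab_path <- file.path(fl$label_dir, f)
    if (!file.exists(lab_path)) next
    recs[[f]] <- eval_record(load_image(file.path(fl$pred_dir, f)) >= 0.5,
                             load_image(lab_path) >= 0.5, id = f)
  }
  if (!length(recs)) stop("no prediction/label pairs matched by filename")
  records <- do.call(rbind, recs)
  utils::write.csv(records, paste0(fl$out, "_per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_eval(records), paste0(fl$out, "_summary.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

# grayscale image + predicted (yellow) / label (red) boxes -> RGB PNG
write_overlay <- function(image, pred_box = NULL, label_box = NULL, path) {
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), c(dim(image), 3L))
  if (!is.null(label_box)) rgb <- draw_box(rgb, label_box, c(1, 0, 0))
  if (!is.null(pred_box)) rgb <- draw_box(rgb, pred_box, c(1, 1, 0))
  png::writePNG(rgb, path)
  invisible(path)
}

draw_box <- function(rgb, box, col) {
  if (is.null(box) || box[3] <= box[1] || box[4] <= box[2]) return(rgb)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  r0 <- max(1L, box[1] + 1L); r1 <- min(H, box[3])
  c0 <- max(1L, box[2] + 1L); c1 <- min(W, box[4])
  for (ch in 1:3) {
    rgb[r0:r1, c(c0, c1), ch] <- col[ch]
    rgb[c(r0, r1), c0:c1, ch] <- col[ch]
  }
  rgb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
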