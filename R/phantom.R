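# Synthetic radiograph phantoms: a smooth bone-like background, a brighter
# elliptical "femoral neck" region of interest, and a thin low-contrast
# dark crack crossing it at a random orientation, plus additive noise.
# Paired ground-truth masks (ROI ellipse, crack) make every stage of the
# system testable with zero external data.

#' Phantom generation parameters
#'
#' All geometry is in pixels, intensities in `[0,1]`. The defaults emulate
#' the qualitative appearance of a cropped femoral-neck radiograph: the
#' crack is 1-3 px wide and its contrast (fractional intensity drop) is
#' drawn from `crack_contrast` when a range is given, spanning
#' barely-visible (0.03) to plainly visible (0.10).
#'
#' @param image_size square image side.
#' @param roi_center,roi_axes,roi_angle ellipse pose (center, semi-axes,
#'   rotation in radians); defaults place the ellipse mid-image.
#' @param crack_orientation direction of the crack chord in radians;
#'   drawn uniformly in `[0, pi)` when `NULL`.
#' @param crack_width crack thickness in pixels (1-3).
#' @param crack_contrast scalar, or length-2 range to sample from.
#' @param crack_curvature perpendicular bow of the crack as a fraction of
#'   its chord length.
#' @param roi_brightness intensity lift inside the ellipse.
#' @param roi_margin the generator's contract for how much brighter (mean
#'   intensity) the ROI interior is than the exterior.
#' @param background_scale smoothing length of the background texture in
#'   pixels.
#' @param noise_sd additive Gaussian noise level.
#' @param seed integer; generation is deterministic given the seed.
#' @export
phantom_spec <- function(image_size = 256L,
                         roi_center = NULL, roi_axes = NULL, roi_angle = 0,
                         crack_orientation = NULL, crack_width = 2,
                         crack_contrast = c(0.03, 0.10),
                         crack_curvature = 0.08,
                         roi_brightness = 0.25, roi_margin = 0.15,
                         background_scale = image_size / 8,
                         noise_sd = 0.015, seed = 1L) {
  s <- as.integer(image_size)
  if (s < 32L) stop("image_size must be at least 32")
  if (is.null(roi_center)) roi_center <- c(0.5, 0.5) * s
  if (is.null(roi_axes)) roi_axes <- c(0.32, 0.20) * s
  if (crack_width < 1 || crack_width > 3)
    stop("crack_width must lie in [1, 3] pixels")
  if (any(crack_contrast <= 0) || any(crack_contrast >= 0.5))
    stop("crack_contrast must lie in (0, 0.5)")
  if (any(roi_center - roi_axes[1] < 1) || any(roi_center + roi_axes[1] > s))
    stop("ROI ellipse must lie within image bounds")
  structure(list(image_size = s, roi_center = roi_center,
                 roi_axes = roi_axes, roi_angle = roi_angle,
                 crack_orientation = crack_orientation,
                 crack_width = crack_width, crack_contrast = crack_contrast,
                 crack_curvature = crack_curvature,
                 roi_brightness = roi_brightness, roi_margin = roi_margin,
                 background_scale = background_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic phantom
#'
#' @param spec a [phantom_spec()].
#' @param with_crack set `FALSE` to render the identical phantom without
#'   the intensity drop (the crack mask is still returned), e.g. to isolate
#'   the crack's contribution.
#' @return a `phantom_record`: list with `image` (matrix in `[0,1]`),
#'   `roi_mask`, `fracture_mask` (logical matrices) and `meta` (the drawn
#'   orientation, contrast, seed, ...).
#' @export
generate_phantom <- function(spec, with_crack = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  s <- spec$image_size

  # smooth bone-like background
  z <- matrix(stats::rnorm(s * s), s, s)
  sm <- ebi_mat(EBImage::gblur(z, sigma = spec$background_scale / 2,
                               boundary = "replicate"))
  sm <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
  img <- 0.35 + 0.05 * sm

  # bright elliptical ROI with a soft rim
  rc <- row(img) - spec$roi_center[1]
  cc <- col(img) - spec$roi_center[2]
  ca <- cos(spec$roi_angle); sa <- sin(spec$roi_angle)
  u <- (rc * ca + cc * sa) / spec$roi_axes[1]
  v <- (-rc * sa + cc * ca) / spec$roi_axes[2]
  E <- u^2 + v^2
  img <- img + spec$roi_brightness * sigmoid((1 - E) * 8)
  roi_mask <- E <= 1

  # thin, slightly curved crack: a quadratic Bezier chord across the ROI
  theta <- spec$crack_orientation
  if (is.null(theta)) theta <- stats::runif(1, 0, pi)
  dirv <- c(cos(theta), sin(theta))          # (row, col) direction
  # ellipse radius along the chord direction
  ur <- (dirv[1] * ca + dirv[2] * sa) / spec$roi_axes[1]
  vr <- (-dirv[1] * sa + dirv[2] * ca) / spec$roi_axes[2]
  rad <- 1 / sqrt(ur^2 + vr^2)
  p0 <- spec$roi_center - 0.8 * rad * dirv
  p2 <- spec$roi_center + 0.8 * rad * dirv
  perp <- c(-dirv[2], dirv[1])
  bow <- spec$crack_curvature * (2 * stats::rbinom(1, 1, 0.5) - 1)
  p1 <- (p0 + p2) / 2 + bow * 1.6 * rad * perp
  tt <- seq(0, 1, length.out = 6L * s)
  bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
    outer(tt^2, p2)
  fracture_mask <- matrix(FALSE, s, s)
  half <- spec$crack_width / 2
  rr <- pmin(pmax(round(bez[, 1]), 1L), s)
  ccx <- pmin(pmax(round(bez[, 2]), 1L), s)
  off <- expand.grid(dr = -2:2, dc = -2:2)
  keep_off <- sqrt(off$dr^2 + off$dc^2) <= max(half, 0.5)
  off <- off[keep_off, ]
  for (k in seq_len(nrow(off))) {
    r2 <- pmin(pmax(rr + off$dr[k], 1L), s)
    c2 <- pmin(pmax(ccx + off$dc[k], 1L), s)
    fracture_mask[cbind(r2, c2)] <- TRUE
  }
  fracture_mask <- fracture_mask & (E <= 0.9)

  contrast <- if (length(spec$crack_contrast) > 1L)
    stats::runif(1, spec$crack_contrast[1], spec$crack_contrast[2])
  else spec$crack_contrast
  if (with_crack && contrast > 0) {
    prof <- ebi_mat(EBImage::gblur(fracture_mask * 1, sigma = 0.7,
                                   boundary = "replicate"))
    if (max(prof) > 0) prof <- prof / max(prof)
    img <- img - contrast * prof
  }

  img <- img + stats::rnorm(s * s, sd = spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, roi_mask = roi_mask,
                 fracture_mask = fracture_mask,
                 meta = list(image_size = s, orientation = theta,
                             contrast = contrast,
                             crack_width = spec$crack_width,
                             seed = spec$seed, spec = spec)),
            class = "phantom_record")
}

# strip an EBImage result back to a plain matrix
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Augmentation parameters
#'
#' The augmentation procedure applies, to the image and both masks alike,
#' a rotation drawn uniformly from `rotation_range` and a fixed rescale of
#' `scale_factor` (0.95 = a 0.05x magnification reduction). Masks are
#' re-binarized at 0.5 after interpolation.
#'
#' @param rotation_range degrees, default `c(-15, 15)`.
#' @param scale_factor fixed rescale applied to every variant.
#' @param n_variants variants generated per base image (8 by default, so
#'   480 base images yield 3840).
#' @param seed optional integer seed.
#' @export
augment_spec <- function(rotation_range = c(-15, 15), scale_factor = 0.95,
                         n_variants = 8L, seed = NULL) {
  if (n_variants < 1L) stop("n_variants must be >= 1")
  stopifnot(length(rotation_range) == 2L,
            rotation_range[1] <= rotation_range[2])
  structure(list(rotation_range = rotation_range,
                 scale_factor = scale_factor,
                 n_variants = as.integer(n_variants), seed = seed),
            class = "augment_spec")
}

# rotate about the center and rescale a raster, keeping its size;
# bilinear interpolation, zero fill
transform_raster <- function(m, angle_deg, scale, binary = FALSE) {
  s <- nrow(m)
  out <- m
  if (scale != 1) {
    s2 <- max(2L, round(s * scale))
    out <- ebi_mat(EBImage::resize(out, w = s2, h = s2))
    pad <- matrix(0, s, s)
    if (s2 <= s) {
      o <- floor((s - s2) / 2)
      pad[o + seq_len(s2), o + seq_len(s2)] <- out
    } else {
      o <- floor((s2 - s) / 2)
      pad <- out[o + seq_len(s), o + seq_len(s)]
    }
    out <- pad
  }
  if (angle_deg != 0)
    out <- ebi_mat(EBImage::rotate(out, angle_deg, output.dim = c(s, s),
                                   bg.col = 0))
  if (binary) out >= 0.5 else out
}

# inverse of transform_raster (used to check mask alignment)
invert_transform_raster <- function(m, angle_deg, scale, binary = FALSE) {
  s <- nrow(m)
  out <- m
  if (angle_deg != 0)
    out <- ebi_mat(EBImage::rotate(out, -angle_deg, output.dim = c(s, s),
                                   bg.col = 0))
  if (scale != 1) out <- transform_raster(out, 0, 1 / scale)
  if (binary) out >= 0.5 else out
}

#' Augment a phantom record
#'
#' @param record a `phantom_record`.
#' @param spec an [augment_spec()].
#' @return list of `n_variants` phantom records; each carries the applied
#'   rotation angle and scale in its `meta`.
#' @export
augment <- function(record, spec = augment_spec()) {
  stopifnot(inherits(record, "phantom_record"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lapply(seq_len(spec$n_variants), function(j) {
    ang <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2])
    sc <- spec$scale_factor
    out <- record
    out$image <- transform_raster(record$image, ang, sc)
    out$roi_mask <- transform_raster(record$roi_mask * 1, ang, sc,
                                     binary = TRUE)
    out$fracture_mask <- transform_raster(record$fracture_mask * 1, ang, sc,
                                          binary = TRUE)
    out$meta$variant <- j
    out$meta$angle <- ang
    out$meta$scale <- sc
    out
  })
}

#' Generate an augmented, split phantom dataset
#'
#' Generates `n_base` phantoms with randomized poses, orientations and
#' contrasts, augments each with `aug$n_variants` rotate-and-rescale
#' variants, and splits at the base-image level: every variant of one base
#' phantom lands on the same side, so no augmented copy of a test image can
#' leak into training.
#'
#' @param n_base number of base phantoms (>= 2).
#' @param split_fraction training share of the *base* images; the default
#'   `3000/3840` reproduces a 3000/840 train/test split at 480 bases and 8
#'   variants.
#' @param image_size square image side.
#' @param aug an [augment_spec()].
#' @param seed master seed; the whole dataset is reproducible from it.
#' @param contrast `crack_contrast` passed to every base spec.
#' @param keep `"records"` returns pixel data; `"manifest"` drops pixels
#'   and keeps metadata only (for count/leakage checks at scale).
#' @param out_dir when given, images and masks are written there as PNG
#'   with a JSON-lines manifest.
#' @return list with `train` and `test` (lists of records or metadata
#'   rows), plus `manifest`, a data.frame of per-variant metadata.
#' @export
make_phantom_dataset <- function(n_base, split_fraction = 3000 / 3840,
                                 image_size = 256L, aug = augment_spec(),
                                 seed = 1L, contrast = c(0.03, 0.10),
                                 keep = c("records", "manifest"),
                                 out_dir = NULL) {
  keep <- match.arg(keep)
  if (n_base < 2L) stop("n_base must be >= 2")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie strictly between 0 and 1")
  set.seed(seed)
  base_seeds <- sample.int(.Machine$integer.max - 1L, n_base)
  n_train <- round(split_fraction * n_base)
  if (n_train < 1L || n_train >= n_base) stop("degenerate split")
  train_ids <- sort(sample.int(n_base, n_train))
  is_train <- seq_len(n_base) %in% train_ids
  aug_seeds <- sample.int(.Machine$integer.max - 1L, n_base)

  train <- list(); test <- list(); rows <- list()
  for (i in seq_len(n_base)) {
    sp <- phantom_spec(image_size = image_size, crack_contrast = contrast,
                       seed = base_seeds[i])
    base <- generate_phantom(sp)
    base$meta$base_id <- i
    a <- aug
    a$seed <- aug_seeds[i]
    vars <- augment(base, a)
    split <- if (is_train[i]) "train" else "test"
    for (v in vars) {
      v$meta$base_id <- i
      v$meta$split <- split
      rows[[length(rows) + 1L]] <- data.frame(
        base_id = i, variant = v$meta$variant, split = split,
        angle = v$meta$angle, scale = v$meta$scale,
        orientation = v$meta$orientation, contrast = v$meta$contrast)
      if (!is.null(out_dir)) write_phantom(v, out_dir)
      item <- if (keep == "records") v else v["meta"]
      if (is_train[i]) train[[length(train) + 1L]] <- item
      else test[[length(test) + 1L]] <- item
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    con <- file(file.path(out_dir, "manifest.jsonl"), "w")
    on.exit(close(con))
    for (r in seq_len(nrow(manifest)))
      writeLines(jsonlite::toJSON(as.list(manifest[r, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  list(train = train, test = test, manifest = manifest)
}

write_phantom <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("b%04d_v%02d", rec$meta$base_id, rec$meta$variant)
  png::writePNG(rec$image, file.path(dir, paste0(stem, ".png")))
  save_mask(rec$roi_mask, file.path(dir, paste0(stem, "_roi.png")))
  save_mask(rec$fracture_mask, file.path(dir, paste0(stem, "_frac.png")))
  invisible(stem)
}
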