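# Two-phase detection: (1) localize the femoral-neck ROI on the full
# image, (2) crop, resample, and detect the fracture line on the crop,
# then map the detection back to original-image coordinates exactly.

# a "model" anywhere in the pipeline is either a dafdnet or a plain
# function(image_matrix) -> probability matrix (handy for stubs)
predict_prob <- function(model, image) {
  if (inherits(model, "dafdnet")) dafdnet_forward(model, image)$prob
  else if (is.function(model)) model(image)
  else stop("model must be a dafdnet or a function")
}

model_input_size <- function(model, default = NA_integer_) {
  if (inherits(model, "dafdnet")) model$cfg$input_size
  else if (!is.null(attr(model, "input_size"))) attr(model, "input_size")
  else default
}

# largest 8-connected foreground component (ties: first in scan order,
# i.e. the left-most then top-most component); NULL when mask is empty
largest_component <- function(mask) {
  lab <- cpp_label8(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

resize_mat <- function(m, h, w) {
  if (all(dim(m) == c(h, w))) return(m)
  ebi_mat(EBImage::resize(m, w = h, h = w))
}

#' Localize the region of interest on a full image
#'
#' Runs the ROI segmentation model (resampling the image to the model's
#' input size on entry if needed), thresholds its probability map at 0.5,
#' keeps the largest 8-connected component, pads its bounding box by
#' `margin`, and resamples the padded crop to the detection network's
#' input size with an aspect-preserving fit (the longer side is scaled to
#' fit; the shorter side is zero-padded symmetrically).
#'
#' @param image numeric matrix in `[0,1]`.
#' @param roi_model segmentation model (a `dafdnet`, or a function
#'   mapping an image matrix to a probability matrix).
#' @param crop_size side of the emitted crop in pixels.
#' @param threshold probability threshold for the ROI mask.
#' @param margin bounding-box padding as a fraction of each box side.
#' @return a `roi_result`: `found`, `roi_mask` (full image), `crop_box`
#'   (full-image coordinates), `crop` (`crop_size` square), and
#'   `transform` (the crop/resample mapping used by [crop_to_full()]).
#'   An all-background probability map gives `found = FALSE` ("no ROI"),
#'   not an error.
#' @export
localize_roi <- function(image, roi_model, crop_size = 128L,
                         threshold = 0.5, margin = 0.1) {
  H <- nrow(image); W <- ncol(image)
  ms <- model_input_size(roi_model)
  work <- image
  sr <- sc <- 1
  if (!is.na(ms) && (H != ms || W != ms)) {
    work <- resize_mat(image, ms, ms)
    sr <- ms / H; sc <- ms / W
  }
  prob <- predict_prob(roi_model, work)
  comp <- largest_component(prob >= threshold)
  if (is.null(comp))
    return(structure(list(found = FALSE, roi_mask = NULL, crop_box = NULL,
                          crop = NULL, transform = NULL),
                     class = "roi_result"))
  bb <- mask_bbox(comp)
  # back to full-image coordinates, then pad by the margin
  bb <- c(bb[1] / sr, bb[2] / sc, bb[3] / sr, bb[4] / sc)
  mh <- margin * (bb[3] - bb[1]); mw <- margin * (bb[4] - bb[2])
  box <- c(max(0, floor(bb[1] - mh)), max(0, floor(bb[2] - mw)),
           min(H, ceiling(bb[3] + mh)), min(W, ceiling(bb[4] + mw)))
  roi_mask <- resize_mat(comp * 1, H, W) >= 0.5
  cr <- crop_resample(image, box, crop_size)
  structure(list(found = TRUE, roi_mask = roi_mask, crop_box = box,
                 crop = cr$crop, transform = cr$transform),
            class = "roi_result")
}

# crop `box` out of `image` and fit it into a crop_size square,
# preserving aspect (scale to the longer side, zero-pad the shorter)
crop_resample <- function(image, box, crop_size) {
  h <- box[3] - box[1]; w <- box[4] - box[2]
  sub <- image[(box[1] + 1):box[3], (box[2] + 1):box[4], drop = FALSE]
  s <- crop_size / max(h, w)
  h2 <- max(1L, round(h * s)); w2 <- max(1L, round(w * s))
  rs <- resize_mat(sub, h2, w2)
  pad_r <- floor((crop_size - h2) / 2)
  pad_c <- floor((crop_size - w2) / 2)
  crop <- matrix(0, crop_size, crop_size)
  crop[pad_r + seq_len(h2), pad_c + seq_len(w2)] <- rs
  list(crop = crop,
       transform = list(row0 = box[1], col0 = box[2], scale = s,
                        pad_r = pad_r, pad_c = pad_c,
                        crop_size = crop_size, full_dim = dim(image)))
}

#' Map boxes between crop and full-image coordinates
#'
#' The crop transform is `crop = (full - origin) * scale + pad`.
#' [crop_to_full()] transforms the corners, rounds to integer pixels and
#' clips (detection boxes live on the full-image pixel grid);
#' [full_to_crop()] keeps continuous crop coordinates so that a
#' full-to-crop-to-full round trip is exact up to the final rounding —
#' within one pixel per corner regardless of the crop scale. An identity
#' transform maps every box to itself.
#'
#' @param box `(row0, col0, row1, col1)` half-open box.
#' @param transform the `transform` element of a `roi_result`.
#' @export
crop_to_full <- function(box, transform) {
  t <- transform
  r <- (c(box[1], box[3]) - t$pad_r) / t$scale + t$row0
  cl <- (c(box[2], box[4]) - t$pad_c) / t$scale + t$col0
  out <- c(r[1], cl[1], r[2], cl[2])
  clip_box(round(out), t$full_dim)
}

#' @rdname crop_to_full
#' @export
full_to_crop <- function(box, transform) {
  t <- transform
  r <- (c(box[1], box[3]) - t$row0) * t$scale + t$pad_r
  cl <- (c(box[2], box[4]) - t$col0) * t$scale + t$pad_c
  clip_box(c(r[1], cl[1], r[2], cl[2]), c(t$crop_size, t$crop_size))
}

identity_transform <- function(dim) {
  list(row0 = 0, col0 = 0, scale = 1, pad_r = 0, pad_c = 0,
       crop_size = dim[1], full_dim = dim)
}

clip_box <- function(b, dim) {
  b <- c(max(0, b[1]), max(0, b[2]), min(dim[1], b[3]), min(dim[2], b[4]))
  if (b[3] < b[1]) b[3] <- b[1]
  if (b[4] < b[2]) b[4] <- b[2]
  b
}

#' Detect the fracture line on a cropped region
#'
#' Thresholds the detection model's probability map (strictly above
#' `threshold`), keeps the largest 8-connected component, and reports its
#' bounding box together with the map's maximum probability. An
#' all-background map yields a "no fracture" result (empty box,
#' `found = FALSE`) with `max_probability` still reported.
#'
#' @param crop square matrix matching the model's input size.
#' @param frac_model detection model (`dafdnet` or function).
#' @param threshold detection probability threshold.
#' @return a `detection_result` in crop coordinates.
#' @export
detect_fracture <- function(crop, frac_model, threshold = 0.5) {
  ms <- model_input_size(frac_model)
  if (!is.na(ms) && !all(dim(crop) == c(ms, ms)))
    stop("crop side must equal the detection model input size (", ms, ")")
  prob <- predict_prob(frac_model, crop)
  maxp <- max(prob)
  comp <- largest_component(prob > threshold)
  if (is.null(comp))
    return(structure(list(found = FALSE,
                          fracture_mask_crop = matrix(FALSE, nrow(prob),
                                                      ncol(prob)),
                          fracture_box_crop = c(0, 0, 0, 0),
                          fracture_box_full = NULL,
                          max_probability = maxp),
                     class = "detection_result"))
  structure(list(found = TRUE, fracture_mask_crop = comp,
                 fracture_box_crop = mask_bbox(comp),
                 fracture_box_full = NULL, max_probability = maxp),
            class = "detection_result")
}

#' Run the full two-phase detection pipeline
#'
#' Localizes the ROI, detects the fracture on the crop, and maps the
#' detection box back to original-image coordinates. "No ROI" and "no
#' fracture" conditions propagate as flags, not errors.
#'
#' @inheritParams localize_roi
#' @param frac_model detection model applied to the ROI crop.
#' @param threshold detection threshold for the fracture stage.
#' @return a `detection_result` carrying both crop- and full-image
#'   coordinates, plus the `roi` result.
#' @export
run_pipeline <- function(image, roi_model, frac_model,
                         threshold = 0.5, margin = 0.1) {
  crop_size <- model_input_size(frac_model, default = 128L)
  roi <- localize_roi(image, roi_model, crop_size = crop_size,
                      margin = margin)
  if (!roi$found)
    return(structure(list(found = FALSE, no_roi = TRUE, roi = roi,
                          max_probability = NA_real_),
                     class = "detection_result"))
  det <- detect_fracture(roi$crop, frac_model, threshold = threshold)
  det$roi <- roi
  det$no_roi <- FALSE
  if (det$found)
    det$fracture_box_full <- crop_to_full(det$fracture_box_crop,
                                          roi$transform)
  det
}
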