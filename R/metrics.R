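# Region-overlap evaluation. Boxes are 0-based, half-open
# (row0, col0, row1, col1): a box covers pixel rows [row0, row1) and
# columns [col0, col1). Box IOU is computed on bounding rectangles; Dice
# and Jaccard on pixel masks (J = D / (2 - D) relates the two).

check_box <- function(b) {
  if (length(b) != 4L || any(!is.finite(b)))
    stop("a box is (row0, col0, row1, col1)")
  if (b[3] < b[1] || b[4] < b[2])
    stop("malformed box: need row1 >= row0 and col1 >= col0")
  b
}

#' Intersection-over-union of two axis-aligned boxes
#'
#' @param a,b boxes `(row0, col0, row1, col1)`, 0-based, half-open.
#' @return IOU in `[0,1]`; 0 when the boxes are disjoint or either is
#'   empty.
#' @export
box_iou <- function(a, b) {
  a <- check_box(a); b <- check_box(b)
  ih <- min(a[3], b[3]) - max(a[1], b[1])
  iw <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(0, ih) * max(0, iw)
  area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Dice coefficient of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; 1 when both masks are empty (nothing to find,
#' nothing found), 0 when exactly one is empty.
#'
#' @param a,b logical (or 0/1) matrices of identical shape.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Jaccard index of two binary masks
#'
#' `|A∩B| / |A∪B|`, with the same empty-mask conventions as [dice()].
#'
#' @inheritParams dice
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Bounding box of a mask's foreground
#'
#' @param mask logical matrix.
#' @return `(row0, col0, row1, col1)`, 0-based half-open; the empty box
#'   `c(0,0,0,0)` when the mask has no foreground.
#' @export
mask_bbox <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0L) return(c(0, 0, 0, 0))
  c(min(w[, 1]) - 1, min(w[, 2]) - 1, max(w[, 1]), max(w[, 2]))
}

#' Per-image evaluation record
#'
#' Box IOU is computed between the bounding rectangles of the two masks
#' (the rectangle convention of the reported figures); Dice and Jaccard on
#' the pixel masks themselves. `detected` is TRUE when the predicted mask
#' overlaps the label at all.
#'
#' @param pred,label logical matrices (prediction, ground truth).
#' @param id image identifier.
#' @return one-row data.frame: `id`, `iou`, `dice`, `jaccard`, `detected`.
#' @export
eval_record <- function(pred, label, id = NA_character_) {
  data.frame(id = as.character(id),
             iou = box_iou(mask_bbox(pred), mask_bbox(label)),
             dice = dice(pred, label),
             jaccard = jaccard(pred, label),
             detected = any(pred > 0 & label > 0))
}

#' Binned summary of evaluation records
#'
#' IOU values are binned at `{0.2, 0.5}`, lower-inclusive, so an IOU of
#' exactly 0.5 counts in the top bin. All quantities are emitted as
#' percentages (73.1 means 73.1%).
#'
#' @param records data.frame with columns `iou`, `dice`, `jaccard`,
#'   `detected` (rows from [eval_record()]).
#' @return one-row data.frame: `pct_iou_50_100`, `pct_iou_20_50`,
#'   `pct_iou_0_20`, `mean_iou`, `mean_dice`, `mean_jaccard`,
#'   `detection_rate`, `n`.
#' @export
summarize_eval <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no evaluation records to summarize")
  iou <- records$iou
  n <- length(iou)
  data.frame(pct_iou_50_100 = 100 * mean(iou >= 0.5),
             pct_iou_20_50 = 100 * mean(iou >= 0.2 & iou < 0.5),
             pct_iou_0_20 = 100 * mean(iou < 0.2),
             mean_iou = 100 * mean(iou),
             mean_dice = 100 * mean(records$dice),
             mean_jaccard = 100 * mean(records$jaccard),
             detection_rate = 100 * mean(records$detected),
             n = n)
}
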