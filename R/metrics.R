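# Segmentation evaluation: overlap metrics and the 95th-percentile
# Hausdorff distance.

#' Per-class segmentation metrics
#'
#' Computes IoU, Dice (DSC), precision and sensitivity per class, plus the
#' across-class mean.  A class empty in both masks scores 1 on all four
#' metrics (nothing to find, nothing found); precision and sensitivity with
#' an empty denominator but a non-empty counterpart score 0.
#'
#' @param pred Integer label mask (`0..n_classes`).
#' @param gt Ground-truth label mask of identical shape.
#' @param n_classes Number of foreground classes (default: maximum label in
#'   either mask, at least 1).
#' @return A data frame with one row per class and a `"mean"` row, columns
#'   `class`, `iou`, `dsc`, `precision`, `sensitivity`.
#' @export
seg_metrics <- function(pred, gt, n_classes = NULL) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth must have identical shapes")
  if (is.null(n_classes)) n_classes <- max(1L, max(pred), max(gt))
  rows <- lapply(seq_len(n_classes), function(c) {
    p <- pred == c; g <- gt == c
    tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
    if (tp + fp + fn == 0)
      return(data.frame(class = as.character(c), iou = 1, dsc = 1,
                        precision = 1, sensitivity = 1))
    data.frame(class = as.character(c),
               iou = tp / (tp + fp + fn),
               dsc = 2 * tp / (2 * tp + fp + fn),
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(class = "mean", iou = mean(out$iou),
                         dsc = mean(out$dsc), precision = mean(out$precision),
                         sensitivity = mean(out$sensitivity))
  rbind(out, mean_row)
}

boundary_pixels <- function(mask) {
  # foreground pixels with at least one background 4-neighbor (image border
  # counts as background)
  d <- dim(mask)
  m <- matrix(FALSE, d[1] + 2, d[2] + 2)
  m[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  core <- m[2:(d[1] + 1), 2:(d[2] + 1)]
  inner <- m[1:d[1], 2:(d[2] + 1)] & m[3:(d[1] + 2), 2:(d[2] + 1)] &
    m[2:(d[1] + 1), 1:d[2]] & m[2:(d[1] + 1), 3:(d[2] + 2)]
  which(core & !inner, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts boundary pixels (foreground pixels with a background 4-neighbor),
#' computes the two directed Euclidean nearest-distance sets, takes each
#' one's 95th percentile (linear interpolation) and returns the larger one.
#' Both masks empty gives 0; exactly one empty gives `Inf`.
#'
#' @param pred,gt Binary masks (logical or 0/1) of identical shape.
#' @param percentile Percentile of the directed distance sets, default 95.
#' @return Distance in pixels.
#' @export
hd95 <- function(pred, gt, percentile = 95) {
  if (!identical(dim(pred), dim(gt)))
    stop("masks must have identical shapes")
  pe <- !any(pred != 0); ge <- !any(gt != 0)
  if (pe && ge) return(0)
  if (pe || ge) return(Inf)
  a <- boundary_pixels(pred != 0)
  b <- boundary_pixels(gt != 0)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dist_ab <- sqrt(apply(d2, 1, min))
  dist_ba <- sqrt(apply(d2, 2, min))
  q <- percentile / 100
  max(stats::quantile(dist_ab, q, names = FALSE, type = 7),
      stats::quantile(dist_ba, q, names = FALSE, type = 7))
}
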