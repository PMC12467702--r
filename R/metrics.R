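#' Intersection over Union of two binary masks
#'
#' `|X ∩ Y| / |X ∪ Y|` for the foreground class. Defined as 1 when both
#' masks are empty (no foreground anywhere in either mask).
#'
#' @param pred_mask,true_mask Binary (0/1) matrices of identical shape.
#' @return Numeric in \[0, 1\].
#' @export
iou <- function(pred_mask, true_mask) {
  check_mask_pair(pred_mask, true_mask)
  inter <- sum(pred_mask == 1 & true_mask == 1)
  union <- sum(pred_mask == 1 | true_mask == 1)
  if (union == 0) return(1)
  inter / union
}

#' Dice coefficient of two binary masks
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`; algebraically equal to
#' `2 IoU / (1 + IoU)`. Defined as 1 when both masks are empty.
#'
#' @inheritParams iou
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(pred_mask, true_mask) {
  check_mask_pair(pred_mask, true_mask)
  inter <- sum(pred_mask == 1 & true_mask == 1)
  tot <- sum(pred_mask == 1) + sum(true_mask == 1)
  if (tot == 0) return(1)
  2 * inter / tot
}

check_mask_pair <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop_maaseg("mask shapes differ", class = "maaseg_dimension_error")
  }
  if (!is_binary_mask(pred_mask) || !is_binary_mask(true_mask)) {
    stop_maaseg("masks must be binary 0/1", class = "maaseg_value_error")
  }
  invisible(NULL)
}

#' Convert an IoU value to the corresponding Dice value
#'
#' Uses the identity `Dice = 2 IoU / (1 + IoU)`.
#'
#' @param iou_value Numeric vector with entries in \[0, 1\].
#' @param percent If `TRUE`, treat input as a percentage (0-100) and
#'   return a percentage rounded to two decimals.
#' @return Dice value(s) on the same scale as the input.
#' @export
dice_from_iou <- function(iou_value, percent = FALSE) {
  x <- if (percent) iou_value / 100 else iou_value
  if (any(x < 0 | x > 1)) {
    stop_maaseg("IoU values must lie in [0, 1] (or [0, 100] with percent=TRUE)",
                class = "maaseg_value_error")
  }
  d <- 2 * x / (1 + x)
  if (percent) round(100 * d, 2) else d
}

#' Evaluate stitched predictions against ground-truth masks
#'
#' Computes per-image foreground IoU and Dice for prediction/truth mask
#' pairs matched by file name, then summarizes as mean and standard
#' deviation in percent.
#'
#' @param pred_dir Directory of predicted binary mask PNGs.
#' @param truth_dir Directory of ground-truth mask PNGs with the same file
#'   names.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list of class `segmentation_report`: `per_image` data frame
#'   (id, iou, dice), and `mean_iou`, `std_iou`, `mean_dice`, `std_dice`
#'   in percent.
#' @export
evaluate_masks <- function(pred_dir, truth_dir, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  truths <- sort(list.files(truth_dir, pattern = "\\.png$"))
  unpaired <- c(setdiff(preds, truths), setdiff(truths, preds))
  if (length(unpaired)) {
    stop_maaseg("unpaired mask ids: ", paste(unpaired, collapse = ", "),
                class = "maaseg_value_error")
  }
  if (!length(preds)) {
    stop_maaseg("no mask pairs found", class = "maaseg_value_error")
  }
  rows <- lapply(preds, function(f) {
    p <- read_mask(file.path(pred_dir, f))
    t <- read_mask(file.path(truth_dir, f))
    data.frame(id = f, iou = iou(p, t), dice = dice(p, t),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  summarize_report(per_image, sd_type)
}

summarize_report <- function(per_image, sd_type = "sample") {
  sdev <- function(x) {
    if (length(x) < 2L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  structure(list(per_image = per_image,
                 mean_iou = 100 * mean(per_image$iou),
                 std_iou = 100 * sdev(per_image$iou),
                 mean_dice = 100 * mean(per_image$dice),
                 std_dice = 100 * sdev(per_image$dice)),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("Segmentation report over %d image(s)\n", nrow(x$per_image)))
  cat(sprintf("  IoU : %.2f +/- %.2f %%\n", x$mean_iou, x$std_iou))
  cat(sprintf("  Dice: %.2f +/- %.2f %%\n", x$mean_dice, x$std_dice))
  invisible(x)
}
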