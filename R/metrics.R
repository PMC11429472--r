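# Segmentation evaluation: per-image IoU and Dice, dataset mean +/- sd.

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty (a correct empty prediction is
#' perfect).
#'
#' @param X,Y binary arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(X, Y) {
  check_same_shape(X, Y)
  inter <- sum(X * Y)
  uni <- sum(pmax(X, Y))
  if (uni == 0) 1 else inter / uni
}

#' Dice coefficient of two binary masks
#'
#' `2|X n Y| / (|X| + |Y|)`; 1 when both masks are empty.  Related to IoU by
#' `Dice = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou
#' @return scalar in `[0, 1]`.
#' @export
dice_coef <- function(X, Y) {
  check_same_shape(X, Y)
  s <- sum(X) + sum(Y)
  if (s == 0) 1 else 2 * sum(X * Y) / s
}

#' Evaluate probability maps against reference masks
#'
#' Binarises each prediction at `threshold`, computes per-image IoU and Dice,
#' and reports their mean and sample (n-1) standard deviation across images.
#'
#' @param preds named list of probability matrices.
#' @param refs named list of binary reference matrices; names must match
#'   `preds`.
#' @param threshold binarisation cutoff in `(0, 1)`.
#' @return object of class `eval_report`: `per_image` data frame
#'   (`id`, `iou`, `dice`), `miou`, `mdice`, `std_iou`, `std_dice`,
#'   `threshold`.
#' @export
evaluate_masks <- function(preds, refs, threshold = 0.5) {
  ids <- names(preds)
  if (is.null(ids) || is.null(names(refs))) stop("preds and refs must be named")
  missing_ids <- setdiff(ids, names(refs))
  extra_ids <- setdiff(names(refs), ids)
  if (length(missing_ids) || length(extra_ids)) {
    stop("id mismatch between predictions and references: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  }
  per <- data.frame(id = ids,
                    iou = NA_real_, dice = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    pb <- (preds[[ids[i]]] >= threshold) * 1
    yb <- refs[[ids[i]]]
    per$iou[i] <- iou(yb, pb)
    per$dice[i] <- dice_coef(yb, pb)
  }
  n <- nrow(per)
  structure(list(
    per_image = per,
    miou = mean(per$iou), mdice = mean(per$dice),
    std_iou = if (n > 1) stats::sd(per$iou) else 0,
    std_dice = if (n > 1) stats::sd(per$dice) else 0,
    threshold = threshold
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mIoU %.4f ± %.4f / mDice %.4f ± %.4f (n = %d, threshold %.2f)\n",
              x$miou, x$std_iou, x$mdice, x$std_dice,
              nrow(x$per_image), x$threshold))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report an `eval_report`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      miou = report$miou, mdice = report$mdice,
      std_iou = report$std_iou, std_dice = report$std_dice,
      threshold = report$threshold,
      per_image = report$per_image
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  }
  invisible(report)
}
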