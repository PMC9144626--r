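# ---- segmentation evaluation ----------------------------------------------

#' Confusion matrix between predicted and ground-truth masks
#'
#' Entry `(i, j)` counts pixels with ground-truth class `i` and predicted
#' class `j`; rows are truth, columns prediction, in the order Outer,
#' Stroma, Epithelial.
#'
#' @param pred,truth Label masks of equal shape.
#' @return 3x3 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(pred, truth) {
  pred <- check_mask(pred); truth <- check_mask(truth)
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  lv <- c("Outer", "Stroma", "Epithelial")
  cm <- table(factor(as.vector(truth), levels = 0:2, labels = lv),
              factor(as.vector(pred), levels = 0:2, labels = lv))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(truth = lv, pred = lv))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Total pixel accuracy from a confusion matrix
#'
#' @param cm A [confusion()] matrix.
#' @return Fraction of pixels on the diagonal.
#' @export
total_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Per-class intersection over union
#'
#' `IoU_k = cm[k,k] / (row_k + col_k - cm[k,k])`. Classes absent from both
#' truth and prediction have an undefined IoU and are returned as `NA`
#' (excluded from aggregates).
#'
#' @param cm A [confusion()] matrix.
#' @param k Class index 1..3 or `NULL` for all classes.
#' @return Named numeric vector (or scalar) of IoU values.
#' @export
class_iou <- function(cm, k = NULL) {
  iou <- vapply(1:3, function(i) {
    uni <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
    if (uni == 0) NA_real_ else cm[i, i] / uni
  }, numeric(1))
  names(iou) <- rownames(cm)
  if (is.null(k)) iou else iou[[k]]
}

#' Area-weighted IoU
#'
#' The ground-truth-area weighted sum of per-class IoU values, taken over
#' classes with defined IoU (weights renormalised over those classes).
#'
#' @param cm A [confusion()] matrix.
#' @return Weighted IoU in `[0, 1]`.
#' @export
weighted_iou <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  iou <- class_iou(cm)
  w <- rowSums(cm) / tot
  ok <- !is.na(iou)
  if (!any(ok)) stop("IoU undefined for every class")
  sum(w[ok] * iou[ok]) / sum(w[ok])
}

#' False-negative / false-positive difference image
#'
#' Renders disagreement with respect to one reference class the way
#' segmentation difference panels are usually shown: magenta where the truth
#' is the reference class but the prediction is not (false negative), green
#' where the prediction is the reference class but the truth is not (false
#' positive), grayscale ground truth elsewhere.
#'
#' @param pred,truth Label masks of equal shape.
#' @param reference_class Class defining FN/FP (default Stroma = 1).
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
difference_image <- function(pred, truth, reference_class = 1L) {
  pred <- check_mask(pred); truth <- check_mask(truth)
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  fn <- truth == reference_class & pred != reference_class
  fp <- pred == reference_class & truth != reference_class
  g <- truth / 2
  R <- g; G <- g; B <- g
  R[fn] <- 1; G[fn] <- 0; B[fn] <- 1
  R[fp] <- 0; G[fp] <- 1; B[fp] <- 0
  array(c(R, G, B), dim = c(nrow(truth), ncol(truth), 3))
}

#' Evaluate a model over one manifest split
#'
#' Computes per-image total accuracy and weighted IoU (plus per-class IoU)
#' for every image of the split, then the mean and sample standard deviation
#' across images. Pooled-pixel variants over the whole split are also
#' reported.
#'
#' @param model A fitted [segnet()] model.
#' @param manifest Split manifest data frame.
#' @param split `"train"` or `"test"`.
#' @return Object of class `eval_report`: list with `per_image` data frame,
#'   `summary` (mean/sd), `pooled` metrics and the split label.
#' @export
evaluate_split <- function(model, manifest, split = "test") {
  rows <- which(manifest$split == split)
  if (!length(rows)) stop("split '", split, "' is empty")
  per <- vector("list", length(rows))
  pooled <- matrix(0L, 3, 3)
  for (j in seq_along(rows)) {
    i <- rows[j]
    img <- read_mpm_image(manifest_path(manifest, "image_path", i),
                          bit_depth = if ("bit_depth" %in% names(manifest))
                            manifest$bit_depth[i] else 12L)
    truth <- read_mask(manifest_path(manifest, "mask_path", i))
    pred <- predict(model, img)
    cm <- confusion(pred, truth)
    pooled <- pooled + cm
    iou <- class_iou(cm)
    per[[j]] <- data.frame(image_id = manifest$image_id[i],
                           total_accuracy = total_accuracy(cm),
                           weighted_iou = weighted_iou(cm),
                           iou_outer = iou[1], iou_stroma = iou[2],
                           iou_epithelial = iou[3],
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  class(pooled) <- c("confusion_matrix", class(pooled))
  structure(list(
    split = split,
    per_image = per,
    summary = data.frame(
      metric = c("total_accuracy", "weighted_iou"),
      mean = c(mean(per$total_accuracy), mean(per$weighted_iou)),
      sd = c(sd0(per$total_accuracy), sd0(per$weighted_iou))),
    pooled = list(confusion = pooled,
                  total_accuracy = total_accuracy(pooled),
                  weighted_iou = weighted_iou(pooled))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Segmentation evaluation (", x$split, " split, n = ",
      nrow(x$per_image), " images)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s mean %.4f  sd %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  pooled: accuracy %.4f, weighted IoU %.4f\n",
              x$pooled$total_accuracy, x$pooled$weighted_iou))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Per-image rows to CSV and the summary to JSON.
#'
#' @param report An [evaluate_split()] report.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      split = report$split,
      summary = report$summary,
      pooled = list(total_accuracy = report$pooled$total_accuracy,
                    weighted_iou = report$pooled$weighted_iou)),
      json_path, digits = NA, auto_unbox = TRUE)
  invisible(report)
}
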