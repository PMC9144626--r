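# ---- FA/PT discrimination in the two-score feature space ------------------

#' Build block-level feature points
#'
#' Tiles every image of the manifest into `block_px` blocks, drops blocks
#' without stromal pixels, samples exactly `n_per_class` eligible blocks per
#' lesion uniformly without replacement, and computes both scores per block.
#' If a class has fewer eligible blocks than requested, all are taken with a
#' warning.
#'
#' @param manifest Manifest data frame.
#' @param source `"ground_truth"` or `"predicted"` masks.
#' @param block_px Block side in pixels.
#' @param n_per_class Blocks sampled per lesion class.
#' @param seed Integer sampling seed.
#' @return Data frame of feature points: `area_ratio`, `shg_stroma_mean`,
#'   `lesion`, `patient_id`, `image_id`, `granularity = "block"`.
#' @export
build_block_features <- function(manifest,
                                 source = c("ground_truth", "predicted"),
                                 block_px = 128L, n_per_class = 500L,
                                 seed = 1L) {
  source <- match.arg(source)
  col <- if (source == "ground_truth") "mask_path" else "pred_mask_path"
  if (!col %in% names(manifest)) stop("manifest has no ", col, " column")
  pts <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- convert_to_8bit(read_mpm_image(
      manifest_path(manifest, "image_path", i),
      bit_depth = if ("bit_depth" %in% names(manifest))
        manifest$bit_depth[i] else 12L))
    mask <- read_mask(manifest_path(manifest, col, i))
    for (bl in tile_image(img, mask, block_px)) {
      n_str <- sum(bl$mask == LBL_STROMA)
      if (n_str == 0L) next  # zero-stroma blocks are excluded
      pts[[length(pts) + 1L]] <- data.frame(
        area_ratio = sum(bl$mask == LBL_EPITHELIAL) / n_str,
        shg_stroma_mean = mean(bl$shg[bl$mask == LBL_STROMA]),
        lesion = manifest$lesion[i], patient_id = manifest$patient_id[i],
        image_id = manifest$image_id[i], granularity = "block",
        stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) stop("no eligible blocks in any class")
  with_seed(seed, function() {
    keep <- unlist(lapply(c("FA", "PT"), function(cls) {
      idx <- which(pts$lesion == cls)
      if (!length(idx)) stop("no eligible blocks for class ", cls)
      if (length(idx) < n_per_class) {
        warning("only ", length(idx), " eligible ", cls,
                " blocks (requested ", n_per_class, "); taking all")
        idx
      } else idx[sample.int(length(idx), n_per_class)]
    }))
    pts[keep, , drop = FALSE]
  })
}

#' Image-level feature points from a score report
#'
#' @param report A [score_dataset()] report.
#' @return Feature-point data frame with `granularity = "full_image"`.
#' @export
image_features <- function(report) {
  r <- report$records
  data.frame(area_ratio = r$area_ratio, shg_stroma_mean = r$shg_stroma_mean,
             lesion = r$lesion, patient_id = r$patient_id,
             image_id = r$image_id, granularity = "full_image",
             stringsAsFactors = FALSE)
}

#' Fisher linear discriminant for the two-score feature space
#'
#' Two-class LDA with `w = S_pooled^{-1} (mu_PT - mu_FA)` and the boundary
#' through the midpoint of the class means (equal priors). Features are
#' z-standardized by default (statistics computed from the fitted points)
#' so the boundary-orientation diagnostic is scale-free; a small ridge is
#' added when the pooled covariance is near-singular.
#'
#' @param points Feature-point data frame with columns `area_ratio`,
#'   `shg_stroma_mean`, `lesion`.
#' @param standardize Z-scale both features before fitting.
#' @param ridge Relative ridge added to a near-singular pooled covariance.
#' @return Object of class `mpm_lda` with `print`, `coef` and `predict`
#'   methods. `w` and `b` act on (possibly standardized) feature vectors
#'   `(area_ratio, shg_stroma_mean)`; the decision rule is
#'   `PT if w . x + b > 0`.
#' @export
fit_lda <- function(points, standardize = TRUE, ridge = 1e-6) {
  X <- as.matrix(points[, c("area_ratio", "shg_stroma_mean")])
  cls <- points$lesion
  if (!all(c("FA", "PT") %in% cls)) stop("both classes must be present")
  ctr <- c(0, 0); scl <- c(1, 1)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- pmax(apply(X, 2, sd), .Machine$double.eps)
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  mu_fa <- colMeans(X[cls == "FA", , drop = FALSE])
  mu_pt <- colMeans(X[cls == "PT", , drop = FALSE])
  n_fa <- sum(cls == "FA"); n_pt <- sum(cls == "PT")
  S <- (cov_scatter(X[cls == "FA", , drop = FALSE]) +
        cov_scatter(X[cls == "PT", , drop = FALSE])) / (n_fa + n_pt - 2)
  if (rcond_2x2(S) < 1e-10) S <- S + diag(2) * ridge * sum(diag(S)) / 2
  w <- tryCatch(solve(S, mu_pt - mu_fa), error = function(e) {
    solve(S + diag(2) * ridge * sum(diag(S)) / 2, mu_pt - mu_fa)
  })
  b <- -sum(w * (mu_fa + mu_pt) / 2)
  degenerate <- sqrt(sum(w^2)) < 1e-12
  if (degenerate) warning("identical class means: zero weight vector")
  structure(list(w = w, b = b, class_means = rbind(FA = mu_fa, PT = mu_pt),
                 pooled_cov = S, center = ctr, scale = scl,
                 standardize = standardize, degenerate = degenerate,
                 n = c(FA = n_fa, PT = n_pt)),
            class = "mpm_lda")
}

cov_scatter <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc)
}

rcond_2x2 <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @export
print.mpm_lda <- function(x, ...) {
  cat("Fisher LDA on (area ratio, stromal SHG)",
      if (x$standardize) "[standardized features]" else "[raw features]", "\n")
  cat(sprintf("  w = (%.4f, %.4f), b = %.4f\n", x$w[1], x$w[2], x$b))
  cat(sprintf("  boundary angle to SHG axis: %.1f degrees\n",
              boundary_angle_to_shg_axis(x)))
  invisible(x)
}

#' @export
coef.mpm_lda <- function(object, ...) {
  c(object$w, intercept = object$b)
}

#' Classify feature points with a fitted LDA
#'
#' @param object A fitted [fit_lda()] model.
#' @param points Feature-point data frame (newdata).
#' @param ... Unused.
#' @return `points` with a `predicted` column, plus attributes `accuracy`
#'   (overall), `per_class` and `per_granularity` accuracies when true
#'   labels are present.
#' @export
predict.mpm_lda <- function(object, points, ...) {
  X <- as.matrix(points[, c("area_ratio", "shg_stroma_mean")])
  if (object$standardize)
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  score <- as.vector(X %*% object$w) + object$b
  points$predicted <- ifelse(score > 0, "PT", "FA")
  if ("lesion" %in% names(points)) {
    ok <- points$predicted == points$lesion
    attr(points, "accuracy") <- mean(ok)
    attr(points, "per_class") <- tapply(ok, points$lesion, mean)
    if ("granularity" %in% names(points))
      attr(points, "per_granularity") <- tapply(ok, points$granularity, mean)
  }
  points
}

#' Angle between the LDA decision boundary and the SHG-intensity axis
#'
#' The separating line has direction `(-w2, w1)`; the angle to the SHG axis
#' (the second feature axis) is folded into `[0, 90]` degrees. An angle near
#' 90 means the boundary is almost perpendicular to the SHG axis, i.e. the
#' SHG intensity carries the discrimination. Meaningful on standardized
#' features.
#'
#' @param model A fitted [fit_lda()] model.
#' @return Angle in degrees in `[0, 90]`.
#' @export
boundary_angle_to_shg_axis <- function(model) {
  w <- model$w
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) stop("zero weight vector: boundary angle undefined")
  d <- c(-w[2], w[1]) / nrm           # direction of the separating line
  angle <- acos(min(abs(d[2]), 1)) * 180 / pi  # vs SHG axis = (0, 1)
  angle
}

#' Scatter plot of the two-score feature space with the LDA boundary
#'
#' Filled symbols = FA, open symbols = PT, colored by patient; the fitted
#' decision boundary is drawn on the raw feature scale.
#'
#' @param points Feature-point data frame.
#' @param model Optional fitted [fit_lda()] model.
#' @param path Output PNG path, or `NULL` for the current device.
#' @return `points`, invisibly.
#' @export
plot_feature_space <- function(points, model = NULL, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 700, 600); on.exit(grDevices::dev.off()) }
  pats <- sort(unique(points$patient_id))
  cols <- grDevices::rainbow(length(pats))
  names(cols) <- pats
  pch <- ifelse(points$lesion == "FA", 19, 21)
  plot(points$area_ratio, points$shg_stroma_mean, col = cols[points$patient_id],
       pch = pch, xlab = "epithelial / stromal area ratio",
       ylab = "mean stromal SHG (8-bit)")
  if (!is.null(model) && !model$degenerate) {
    # map the (standardized) boundary w.x + b = 0 back to raw coordinates
    w_raw <- model$w / model$scale
    b_raw <- model$b - sum(model$w * model$center / model$scale)
    if (abs(w_raw[2]) > 1e-12)
      abline(a = -b_raw / w_raw[2], b = -w_raw[1] / w_raw[2], lty = 2)
    else abline(v = -b_raw / w_raw[1], lty = 2)
  }
  legend("topright", legend = c("FA", "PT"), pch = c(19, 21), bty = "n")
  invisible(points)
}

#' Leave-one-patient-out LDA accuracy
#'
#' Stricter patient-level alternative to resubstitution accuracy: each
#' patient's points are held out in turn, the model refitted, and the held
#' out points classified.
#'
#' @param points Feature-point data frame.
#' @param ... Passed to [fit_lda()].
#' @return Overall held-out accuracy.
#' @export
lda_loo_patient <- function(points, ...) {
  ok <- logical(0)
  for (p in unique(points$patient_id)) {
    tr <- points[points$patient_id != p, , drop = FALSE]
    te <- points[points$patient_id == p, , drop = FALSE]
    if (length(unique(tr$lesion)) < 2L) next
    pr <- predict(fit_lda(tr, ...), te)
    ok <- c(ok, pr$predicted == pr$lesion)
  }
  mean(ok)
}
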