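# ---- per-image quantitative signatures ------------------------------------
# Two morphometric scores per frame: the epithelial-to-stromal area ratio
# (elevated in phyllodes tumor) and the mean SHG intensity within the
# stromal region (elevated in fibroadenoma, reflecting collagen
# organisation). Scores are computed on 8-bit images, the analysis scale.

#' Epithelial-to-stromal area ratio
#'
#' Quotient of epithelial over stromal pixel counts; Outer pixels are
#' excluded entirely. Undefined (NA) when the mask has no stromal pixels —
#' such frames/blocks are excluded from downstream analyses rather than
#' scored as zero.
#'
#' @param mask Label mask over \{0, 1, 2\}.
#' @param as_fraction If `TRUE` return epithelial / (epithelial + stroma)
#'   instead of the literal quotient.
#' @return Non-negative scalar, or `NA` if no stroma.
#' @export
#' @examples
#' m <- matrix(c(rep(2, 100), rep(1, 400)), 25, 20)
#' area_ratio(m)  # 0.25
area_ratio <- function(mask, as_fraction = FALSE) {
  mask <- check_mask(mask)
  n_epi <- sum(mask == LBL_EPITHELIAL)
  n_str <- sum(mask == LBL_STROMA)
  if (as_fraction) {
    if (n_epi + n_str == 0L) return(NA_real_)
    return(n_epi / (n_epi + n_str))
  }
  if (n_str == 0L) return(NA_real_)
  n_epi / n_str
}

#' Mean SHG intensity within the stromal region
#'
#' Arithmetic mean of the SHG channel over Stroma-labeled pixels, on the
#' 8-bit analysis scale (12-bit input is converted first). `NA` when the
#' mask has no stroma.
#'
#' @param image An [mpm_image()].
#' @param mask Matching label mask.
#' @return Mean intensity in `[0, 255]`, or `NA`.
#' @export
mean_shg_in_stroma <- function(image, mask) {
  stopifnot(inherits(image, "mpm_image"))
  mask <- check_mask(mask)
  if (!identical(dim(image$shg), dim(mask))) stop("image/mask shape mismatch")
  image <- convert_to_8bit(image)
  sel <- mask == LBL_STROMA
  if (!any(sel)) return(NA_real_)
  mean(image$shg[sel])
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' `D` is the supremum of the ECDF difference, evaluated over the pooled
#' sorted sample points (tie-safe). For `n_x + n_y <= max_exact` the p-value
#' is the exact permutation probability over all label assignments;
#' otherwise the asymptotic Kolmogorov distribution with effective sample
#' size `n_x n_y / (n_x + n_y)` is used.
#'
#' @param x,y Numeric samples.
#' @param max_exact Combined size up to which the exact permutation p-value
#'   is computed.
#' @return `list(D = , p = , method = )`.
#' @export
#' @examples
#' ks_two_sample(1:5, 6:10)$D  # 1: fully separated samples
ks_two_sample <- function(x, y, max_exact = 20L) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  D <- ks_statistic(x, y)
  if (nx + ny <= max_exact) {
    pooled <- c(x, y)
    combos <- utils::combn(nx + ny, nx)
    hits <- 0L
    for (j in seq_len(ncol(combos))) {
      d <- ks_statistic(pooled[combos[, j]], pooled[-combos[, j]])
      if (d >= D - 1e-12) hits <- hits + 1L
    }
    p <- hits / ncol(combos)
    method <- "exact permutation"
  } else {
    ne <- nx * ny / (nx + ny)
    p <- kolmogorov_sf(sqrt(ne) * D)
    method <- "asymptotic"
  }
  list(D = D, p = min(max(p, .Machine$double.xmin), 1), method = method)
}

# sup |ECDF_x - ECDF_y| over the pooled sample points
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# survival function of the Kolmogorov distribution
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  s <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(s, 0), 1)
}

#' Score every image of a dataset and summarise by lesion
#'
#' Computes both signatures per image from ground-truth or predicted masks,
#' then per-lesion means and standard deviations and the FA-vs-PT
#' Kolmogorov--Smirnov test for each score. The two mask sources let the
#' agreement between ground-truth and model-predicted scores be compared.
#'
#' @param manifest Manifest data frame; for `source = "predicted"` it must
#'   carry a `pred_mask_path` column (see [predict_manifest()]).
#' @param source `"ground_truth"` or `"predicted"`.
#' @return Object of class `score_report`: `records` data frame (one row per
#'   image with defined scores) and `stats` (per-lesion summaries + KS
#'   results).
#' @export
score_dataset <- function(manifest, source = c("ground_truth", "predicted")) {
  source <- match.arg(source)
  col <- if (source == "ground_truth") "mask_path" else "pred_mask_path"
  if (!col %in% names(manifest))
    stop("manifest has no ", col, " column; run the prediction stage first")
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    mp <- manifest_path(manifest, col, i)
    if (is.na(mp) || !file.exists(mp)) {
      warning("missing ", source, " mask for ", manifest$image_id[i],
              "; record skipped")
      next
    }
    mask <- read_mask(mp)
    img <- read_mpm_image(manifest_path(manifest, "image_path", i),
                          bit_depth = if ("bit_depth" %in% names(manifest))
                            manifest$bit_depth[i] else 12L)
    recs[[length(recs) + 1L]] <- data.frame(
      image_id = manifest$image_id[i], patient_id = manifest$patient_id[i],
      lesion = manifest$lesion[i],
      area_ratio = area_ratio(mask),
      shg_stroma_mean = mean_shg_in_stroma(img, mask),
      source = source, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  undef <- is.na(records$area_ratio) | is.na(records$shg_stroma_mean)
  if (any(undef)) {
    warning(sum(undef), " image(s) with undefined scores excluded")
    records <- records[!undef, , drop = FALSE]
  }
  structure(list(records = records, stats = group_stats(records)),
            class = "score_report")
}

#' Per-lesion summary statistics and KS tests for a score table
#'
#' @param records Data frame with columns `lesion`, `area_ratio`,
#'   `shg_stroma_mean`.
#' @return Object of class `group_stats`: per-lesion mean/sd for each score
#'   and the FA-vs-PT KS `D` and p per score.
#' @export
group_stats <- function(records) {
  out <- list()
  for (score in c("area_ratio", "shg_stroma_mean")) {
    fa <- records[[score]][records$lesion == "FA"]
    pt <- records[[score]][records$lesion == "PT"]
    ks <- if (length(fa) && length(pt)) ks_two_sample(fa, pt)
          else list(D = NA_real_, p = NA_real_, method = "undefined")
    out[[score]] <- list(
      mean = c(FA = mean(fa), PT = mean(pt)),
      sd = c(FA = sd(fa), PT = sd(pt)),
      ks_D = ks$D, ks_p = ks$p, ks_method = ks$method)
  }
  structure(out, class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  for (score in names(x)) {
    s <- x[[score]]
    cat(sprintf("%s: FA %.3f +/- %.3f, PT %.3f +/- %.3f (KS D = %.3f, p = %.3g%s)\n",
                score, s$mean[["FA"]], s$sd[["FA"]], s$mean[["PT"]],
                s$sd[["PT"]], s$ks_D, s$ks_p,
                if (!is.na(s$ks_p) && s$ks_p < 0.05) ", *" else ""))
  }
  invisible(x)
}

#' @export
print.score_report <- function(x, ...) {
  cat("Per-image scores (", nrow(x$records), " images, source: ",
      x$records$source[1], ")\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Bar plot of group scores (mean +/- sd with significance asterisk)
#'
#' @param report A [score_dataset()] report.
#' @param path Output PNG path, or `NULL` to draw on the current device.
#' @return `report`, invisibly.
#' @export
plot_score_bars <- function(report, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 900, 450); on.exit(grDevices::dev.off()) }
  op <- par(mfrow = c(1, 2), mar = c(3, 4, 3, 1))
  on.exit(par(op), add = TRUE)
  labs <- c(area_ratio = "epithelial / stromal area ratio",
            shg_stroma_mean = "mean stromal SHG (8-bit)")
  for (score in names(report$stats)) {
    s <- report$stats[[score]]
    bp <- barplot(s$mean, ylim = c(0, max(s$mean + s$sd) * 1.25),
                  col = c("gray30", "white"), ylab = labs[[score]])
    segments(bp, s$mean - s$sd, bp, s$mean + s$sd)
    if (!is.na(s$ks_p) && s$ks_p < 0.05)
      text(mean(bp), max(s$mean + s$sd) * 1.15, "*", cex = 2)
  }
  invisible(report)
}
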