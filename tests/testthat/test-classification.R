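test_that("block features exclude zero-stroma blocks and sample per class", {
  man <- tiny_cohort()
  pts <- build_block_features(man, "ground_truth", block_px = 16L,
                              n_per_class = 10L, seed = 1)
  expect_equal(as.vector(table(pts$lesion)), c(10, 10))
  expect_true(all(is.finite(pts$area_ratio)))     # no zero-stroma block
  expect_true(all(is.finite(pts$shg_stroma_mean)))
  # deterministic per seed
  pts2 <- build_block_features(man, "ground_truth", block_px = 16L,
                               n_per_class = 10L, seed = 1)
  expect_identical(pts$area_ratio, pts2$area_ratio)
  # requesting more than eligible takes all, with a warning
  warns <- capture_warnings(
    all_pts <- build_block_features(man, "ground_truth", block_px = 32L,
                                    n_per_class = 10000L, seed = 1))
  expect_match(warns, "taking all", all = TRUE)
  expect_lte(nrow(all_pts), 8 * 4)
})

test_that("an all-Outer image contributes no eligible blocks", {
  d <- withr::local_tempdir()
  mask <- matrix(0L, 32, 32)
  img <- render_mpm_image(mask, optics_params(frame_size = 32), seed = 1)
  write_mpm_image(img, file.path(d, "i.tif"))
  write_mask(mask, file.path(d, "m.png"))
  man <- data.frame(image_id = "i", patient_id = "p", lesion = "FA",
                    image_path = "i.tif", mask_path = "m.png",
                    seed = 1, bit_depth = 12L)
  attr(man, "root") <- d
  expect_error(build_block_features(man, "ground_truth", block_px = 16L,
                                    n_per_class = 5L, seed = 1),
               "no eligible blocks")
})

test_that("LDA solves the hand-computable separable toy problem", {
  pts <- data.frame(area_ratio = c(0, 0, 4, 4),
                    shg_stroma_mean = c(0, 1, 0, 1),
                    lesion = c("FA", "FA", "PT", "PT"))
  fit <- fit_lda(pts, standardize = FALSE)
  pred <- predict(fit, pts)
  expect_equal(attr(pred, "accuracy"), 1.0)
  # boundary sits at first-feature = 2: w2 = 0, -b/w1 = 2
  expect_equal(unname(fit$w[2]), 0, tolerance = 1e-8)
  expect_equal(unname(-fit$b / fit$w[1]), 2, tolerance = 1e-8)
  probe <- data.frame(area_ratio = c(1.9, 2.1), shg_stroma_mean = c(0.5, 0.5),
                      lesion = c("FA", "PT"))
  expect_equal(predict(fit, probe)$predicted, c("FA", "PT"))
})

test_that("LDA direction maximizes the Fisher criterion (grid-search oracle)", {
  fisher_J <- function(theta, feats, grp) {
    d <- c(cos(theta), sin(theta))
    z <- as.vector(feats %*% d)
    m1 <- mean(z[grp == "FA"]); m2 <- mean(z[grp == "PT"])
    v <- (sum((z[grp == "FA"] - m1)^2) + sum((z[grp == "PT"] - m2)^2))
    (m2 - m1)^2 / v
  }
  for (s in 1:15) {
    set.seed(s)
    X <- rbind(cbind(rnorm(20, 0, 1), rnorm(20, 0, 2)),
               cbind(rnorm(20, 2, 1), rnorm(20, 1, 2)))
    pts <- data.frame(area_ratio = X[, 1], shg_stroma_mean = X[, 2],
                      lesion = rep(c("FA", "PT"), each = 20))
    fit <- fit_lda(pts, standardize = FALSE)
    grid <- seq(0, pi, length.out = 3601)
    J <- vapply(grid, fisher_J, numeric(1), feats = X, grp = pts$lesion)
    best <- grid[which.max(J)]
    ang_fit <- atan2(fit$w[2], fit$w[1]) %% pi
    expect_lt(min(abs(ang_fit - best), pi - abs(ang_fit - best)), 0.01)
  }
})

test_that("LDA direction agrees with the reference implementation", {
  set.seed(2)
  X <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
             cbind(rnorm(30, 1.5), rnorm(30, 1)))
  pts <- data.frame(area_ratio = X[, 1], shg_stroma_mean = X[, 2],
                    lesion = rep(c("FA", "PT"), each = 30))
  fit <- fit_lda(pts, standardize = FALSE)
  ref <- MASS::lda(X, grouping = pts$lesion)
  cosang <- sum(fit$w * ref$scaling) /
    sqrt(sum(fit$w^2) * sum(ref$scaling^2))
  expect_gt(abs(cosang), 0.9999)
})

test_that("classification accuracy complements under label flip and matches
           the confusion tally", {
  set.seed(4)
  X <- rbind(cbind(rnorm(25, 0), rnorm(25, 0)),
             cbind(rnorm(25, 1), rnorm(25, 1)))
  pts <- data.frame(area_ratio = X[, 1], shg_stroma_mean = X[, 2],
                    lesion = rep(c("FA", "PT"), each = 25))
  fit <- fit_lda(pts)
  pred <- predict(fit, pts)
  acc <- attr(pred, "accuracy")
  flipped <- pts
  flipped$lesion <- ifelse(pts$lesion == "FA", "PT", "FA")
  expect_equal(attr(predict(fit, flipped), "accuracy"), 1 - acc)
  # accuracy equals the confusion-matrix trace fraction
  tab <- table(pred$predicted, pred$lesion)
  expect_equal(acc, sum(diag(tab)) / sum(tab))
})

test_that("identical class means give a flagged degenerate fit", {
  pts <- data.frame(area_ratio = c(0, 1, 0, 1),
                    shg_stroma_mean = c(0, 1, 1, 0),
                    lesion = c("FA", "FA", "PT", "PT"))
  expect_warning(fit <- fit_lda(pts), "zero weight")
  expect_true(fit$degenerate)
  expect_error(boundary_angle_to_shg_axis(fit), "zero weight")
})

test_that("boundary angle follows the arctangent geometry", {
  mk <- function(w) structure(list(w = w), class = "mpm_lda")
  expect_equal(boundary_angle_to_shg_axis(mk(c(0, 1))), 90)
  expect_equal(boundary_angle_to_shg_axis(mk(c(1, 0))), 0)
  for (s in 1:50) {
    set.seed(s)
    w <- rnorm(2)
    want <- atan2(abs(w[2]), abs(w[1])) * 180 / pi
    expect_equal(boundary_angle_to_shg_axis(mk(w)), want, tolerance = 1e-10)
  }
})

test_that("LDA decisions are invariant to affine feature rescaling", {
  set.seed(6)
  X <- rbind(cbind(rnorm(20, 0), rnorm(20, 50, 5)),
             cbind(rnorm(20, 1), rnorm(20, 40, 5)))
  pts <- data.frame(area_ratio = X[, 1], shg_stroma_mean = X[, 2],
                    lesion = rep(c("FA", "PT"), each = 20))
  scaled <- pts
  scaled$shg_stroma_mean <- pts$shg_stroma_mean * 3.7 + 12
  for (std in c(TRUE, FALSE)) {
    p1 <- predict(fit_lda(pts, standardize = std), pts)$predicted
    p2 <- predict(fit_lda(scaled, standardize = std), scaled)$predicted
    expect_identical(p1, p2)
  }
})

test_that("leave-one-patient-out accuracy is computable on a cohort", {
  man <- tiny_cohort()
  rep <- score_dataset(man, "ground_truth")
  acc <- lda_loo_patient(image_features(rep))
  expect_true(acc >= 0 && acc <= 1)
})
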