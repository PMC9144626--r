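test_that("area ratio is the epithelial/stromal pixel quotient", {
  m <- matrix(c(rep(2L, 100), rep(1L, 400)), 25, 20)
  expect_equal(area_ratio(m), 0.25)
  expect_equal(area_ratio(matrix(1L, 4, 4)), 0)
  expect_true(is.na(area_ratio(matrix(2L, 4, 4))))      # zero stroma
  expect_true(is.na(area_ratio(matrix(0L, 4, 4))))
  expect_equal(area_ratio(m, as_fraction = TRUE), 0.2)
  for (s in 1:20) {
    set.seed(s)
    m <- random_mask(7)
    n_epi <- 0L; n_str <- 0L
    for (v in as.vector(m)) {
      if (v == 2L) n_epi <- n_epi + 1L
      if (v == 1L) n_str <- n_str + 1L
    }
    want <- if (n_str == 0) NA_real_ else n_epi / n_str
    expect_equal(area_ratio(m), want)
  }
})

test_that("mean stromal SHG is the masked mean on the 8-bit scale", {
  m <- matrix(c(1L, 1L, 0L, 2L), 2)
  img <- mpm_image(matrix(c(0, 255, 7, 9), 2), matrix(0, 2, 2), bit_depth = 8L)
  expect_equal(mean_shg_in_stroma(img, m), 127.5)
  img10 <- mpm_image(matrix(10, 2, 2), matrix(0, 2, 2), bit_depth = 8L)
  expect_equal(mean_shg_in_stroma(img10, m), 10)
  expect_true(is.na(mean_shg_in_stroma(img, matrix(2L, 2, 2))))
  # 12-bit input is converted before averaging
  img12 <- mpm_image(matrix(c(160, 161, 0, 0), 2), matrix(0, 2, 2))
  expect_equal(mean_shg_in_stroma(img12, m), 10)
  for (s in 1:20) {
    set.seed(s)
    m <- random_mask(6); img <- random_image(6)
    vals <- c()
    for (i in seq_along(m)) if (m[i] == 1L) vals <- c(vals, img$shg[i])
    want <- if (is.null(vals)) NA_real_ else mean(vals)
    expect_equal(mean_shg_in_stroma(img, m), want)
  }
})

test_that("scores ignore the Outer region entirely", {
  set.seed(3)
  m <- random_mask(8)
  img <- random_image(8)
  r0 <- area_ratio(m); s0 <- mean_shg_in_stroma(img, m)
  img2 <- img
  img2$shg[m == 0L] <- 255 - img2$shg[m == 0L]  # perturb Outer intensities
  expect_equal(mean_shg_in_stroma(img2, m), s0)
  expect_equal(area_ratio(m), r0)
})

test_that("KS statistic and trivial cases behave canonically", {
  x <- c(1, 2, 2, 3.5)
  r <- ks_two_sample(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  r <- ks_two_sample(1:5, 6:10)
  expect_equal(r$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  # symmetry in the arguments
  set.seed(1)
  a <- rnorm(7); b <- rnorm(9, 0.5)
  expect_equal(ks_two_sample(a, b)$D, ks_two_sample(b, a)$D)
  expect_equal(ks_two_sample(a, b)$p, ks_two_sample(b, a)$p)
})

test_that("KS D and exact permutation p match the reference implementation", {
  # stats::ks.test is the independent oracle (exact p for tie-free samples)
  for (s in 1:30) {
    set.seed(s)
    x <- round(rnorm(5), 6); y <- round(rnorm(5, 0.8), 6)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$method, "exact permutation")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # asymptotic branch agrees with the reference asymptotic p
  for (s in 1:10) {
    set.seed(100 + s)
    x <- rnorm(40); y <- rnorm(35, 0.3)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$method, "asymptotic")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-4)
  }
})

test_that("KS type-I error under the null is near the nominal level", {
  set.seed(99)
  rejections <- 0L
  n_sim <- 2000L
  for (i in seq_len(n_sim)) {
    x <- rnorm(30); y <- rnorm(30)
    if (ks_two_sample(x, y)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("dataset scoring produces one record per image with group stats", {
  man <- tiny_cohort()
  rep <- score_dataset(man, "ground_truth")
  expect_equal(nrow(rep$records), nrow(man))
  expect_true(all(rep$records$area_ratio >= 0))
  expect_true(all(rep$records$shg_stroma_mean >= 0 &
                  rep$records$shg_stroma_mean <= 255))
  expect_true(all(c("area_ratio", "shg_stroma_mean") %in% names(rep$stats)))
  expect_error(score_dataset(man, "predicted"), "pred_mask_path")
})

test_that("identical image sets give zero score dispersion", {
  d <- withr::local_tempdir()
  mask <- generate_tissue_mask(fa_morphology(), frame_size = 32, seed = 4)
  img <- render_mpm_image(mask, optics_params(frame_size = 32), seed = 5)
  rows <- list()
  for (i in 1:3) {
    write_mpm_image(img, file.path(d, paste0("i", i, ".tif")))
    write_mask(mask, file.path(d, paste0("m", i, ".png")))
    rows[[i]] <- data.frame(image_id = paste0("img", i), patient_id = "p1",
                            lesion = if (i < 3) "FA" else "PT",
                            image_path = paste0("i", i, ".tif"),
                            mask_path = paste0("m", i, ".png"),
                            seed = 1, bit_depth = 12L)
  }
  man <- do.call(rbind, rows)
  attr(man, "root") <- d
  rep <- score_dataset(man, "ground_truth")
  expect_equal(rep$stats$area_ratio$sd[["FA"]], 0)
  expect_equal(rep$stats$shg_stroma_mean$sd[["FA"]], 0)
})
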