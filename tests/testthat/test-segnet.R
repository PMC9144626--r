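test_that("augmentation with zero translation and no flips is the identity", {
  img <- random_image(16)
  m <- random_mask(16)
  cfg <- training_config(max_translation_px = 0L, flip_augment = FALSE)
  out <- augment_pair(img, m, cfg, seed = 1)
  expect_identical(out$image$shg, img$shg)
  expect_identical(out$mask, m, ignore_attr = TRUE)
})

test_that("augmentation applies one common bounded translation with fill", {
  # ramp image with unique pixel values lets the shift be recovered exactly
  n <- 24L
  base <- matrix(seq_len(n * n), n)  # unique, strictly positive values
  img <- mpm_image(base, base, bit_depth = 12L)
  m <- matrix(1L, n, n)
  cfg <- training_config(max_translation_px = 2L, flip_augment = FALSE)
  seen_dr <- integer(0); seen_dc <- integer(0)
  for (s in 1:300) {
    out <- augment_pair(img, m, cfg, seed = s)
    # locate the shift from the (unique) value of an interior pixel
    p <- which(out$image$shg == img$shg[12, 12])
    expect_length(p, 1)
    dr <- ((p - 1) %% n + 1) - 12
    dc <- ((p - 1) %/% n + 1) - 12
    expect_lte(abs(dr), 2); expect_lte(abs(dc), 2)
    # the whole frame moved rigidly; vacated pixels are zero / Outer
    exp_img <- matrix(0, n, n)
    rs <- (1:n)[(1:n) - dr >= 1 & (1:n) - dr <= n]
    cs <- (1:n)[(1:n) - dc >= 1 & (1:n) - dc <= n]
    exp_img[rs, cs] <- img$shg[rs - dr, cs - dc]
    expect_equal(out$image$shg, exp_img, ignore_attr = TRUE)
    expect_true(all(out$mask[exp_img == 0] == 0L))
    seen_dr <- c(seen_dr, dr); seen_dc <- c(seen_dc, dc)
  }
  expect_true(all(c(-2L, 2L) %in% seen_dr))  # extremes attained
  expect_true(all(c(-2L, 2L) %in% seen_dc))
})

test_that("the network memorizes a degenerate single-class task", {
  d <- withr::local_tempdir()
  mask <- matrix(1L, 32, 32)
  opt <- optics_params(frame_size = 32)
  img <- render_mpm_image(mask, opt, seed = 1)
  write_mpm_image(img, file.path(d, "i.tif"))
  write_mask(mask, file.path(d, "m.png"))
  man <- data.frame(image_id = "i", patient_id = "p", lesion = "FA",
                    image_path = "i.tif", mask_path = "m.png", seed = 1,
                    bit_depth = 12L, split = "train")
  attr(man, "root") <- d
  net <- network_config(encoder_depth = 2L, base_filters = 4L)
  cfg <- training_config(epochs = 30L, mini_batch = 1L,
                         max_translation_px = 0L, flip_augment = FALSE,
                         seed = 2L)
  mod <- segnet(man, net, cfg)
  pred <- predict(mod, img)
  expect_gte(mean(pred == mask), 0.99)
})

test_that("a trained model beats the majority-class baseline on held-out images", {
  tm <- tiny_model()
  ev <- evaluate_split(tm$model, tm$manifest, "test")
  # majority baseline from the pooled test-mask class distribution
  rows <- which(tm$manifest$split == "test")
  counts <- Reduce(`+`, lapply(rows, function(i) tabulate(as.vector(
    read_mask(file.path(attr(tm$manifest, "root"),
                        tm$manifest$mask_path[i]))) + 1L, 3)))
  baseline <- max(counts) / sum(counts)
  expect_gt(ev$pooled$total_accuracy, baseline)
})

test_that("prediction is deterministic, idempotent and well-formed", {
  tm <- tiny_model()
  man <- tm$manifest
  img <- read_mpm_image(file.path(attr(man, "root"), man$image_path[1]))
  p1 <- predict(tm$model, img)
  p2 <- predict(tm$model, img)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% 0:2))
  expect_equal(dim(p1), dim(img$shg))
  pr <- predict(tm$model, img, type = "prob")
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, nrow(p1), ncol(p1)),
               tolerance = 1e-8)
  # argmax of the probability array reproduces the mask
  expect_equal(apply(pr, c(1, 2), which.max) - 1L, p1, ignore_attr = TRUE)
})

test_that("training with a fixed seed is reproducible", {
  d <- withr::local_tempdir()
  mask <- generate_tissue_mask(fa_morphology(), frame_size = 16, seed = 1)
  img <- render_mpm_image(mask, optics_params(frame_size = 16), seed = 2)
  write_mpm_image(img, file.path(d, "i.tif"))
  write_mask(mask, file.path(d, "m.png"))
  man <- data.frame(image_id = "i", patient_id = "p", lesion = "FA",
                    image_path = "i.tif", mask_path = "m.png", seed = 1,
                    bit_depth = 12L, split = "train")
  attr(man, "root") <- d
  net <- network_config(encoder_depth = 2L, base_filters = 4L)
  cfg <- training_config(epochs = 3L, mini_batch = 1L, seed = 11L)
  m1 <- segnet(man, net, cfg)
  m2 <- segnet(man, net, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$par$W, m2$par$W)
})

test_that("checkpoints restore an identical model", {
  tm <- tiny_model()
  d <- withr::local_tempdir()
  save_segnet(tm$model, file.path(d, "ck.json"))
  back <- load_segnet(file.path(d, "ck.json"))
  img <- read_mpm_image(file.path(attr(tm$manifest, "root"),
                                  tm$manifest$image_path[2]))
  expect_identical(predict(back, img), predict(tm$model, img))
})

test_that("invalid training inputs are rejected", {
  man <- tiny_cohort()
  expect_error(segnet(man), "split")
  man$split <- "test"
  expect_error(segnet(man), "empty training split")
})
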