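test_that("degenerate morphology fractions give the expected trivial masks", {
  m <- generate_tissue_mask(fa_morphology(epithelial_fraction_mean = 0,
                                          tissue_coverage = 1),
                            frame_size = 32, seed = 1)
  expect_equal(sum(m == 2), 0)
  expect_equal(sum(m == 0), 0)
  expect_equal(sum(m == 1), 32 * 32)

  m <- generate_tissue_mask(fa_morphology(tissue_coverage = 0),
                            frame_size = 32, seed = 1)
  expect_true(all(m == 0))
})

test_that("masks partition the frame over the three classes", {
  for (s in 1:5) {
    for (morph in list(fa_morphology(), pt_morphology())) {
      m <- generate_tissue_mask(morph, frame_size = 48, seed = s)
      expect_setequal(unique(as.vector(m)), intersect(0:2, unique(as.vector(m))))
      counts <- tabulate(as.vector(m) + 1L, nbins = 3)
      expect_equal(sum(counts), 48 * 48)
    }
  }
})

test_that("achieved epithelial fraction tracks the configured mean", {
  fracs <- vapply(1:400, function(s) {
    m <- generate_tissue_mask(fa_morphology(epithelial_fraction_mean = 0.3),
                              frame_size = 64, seed = s)
    sum(m == 2) / sum(m > 0)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.03)
})

test_that("too-small frames are rejected", {
  expect_error(generate_tissue_mask(fa_morphology(), frame_size = 4),
               "too small")
})

test_that("rendering is exact without noise and deterministic with it", {
  mask <- matrix(1L, 16, 16)  # uniform stroma
  opt <- optics_params(frame_size = 16, read_noise_sd = 0, shot_noise = FALSE)
  img <- render_mpm_image(mask, opt, seed = 1)
  expect_true(all(img$shg == opt$shg_stroma_mean))
  expect_true(all(img$af == opt$af_stroma_mean))

  opt2 <- optics_params(frame_size = 16)
  a <- render_mpm_image(mask, opt2, seed = 9)
  b <- render_mpm_image(mask, opt2, seed = 9)
  expect_identical(a$shg, b$shg)
  expect_identical(a$af, b$af)
  expect_false(identical(a$shg, render_mpm_image(mask, opt2, seed = 10)$shg))

  expect_error(render_mpm_image(matrix(1L, 8, 8), opt2), "frame_size")
})

test_that("noise model preserves configured class means", {
  mask <- matrix(rep(c(1L, 2L), each = 512), 32, 32)
  opt <- optics_params(frame_size = 32)
  sums <- c(stroma_shg = 0, epi_shg = 0, stroma_af = 0, epi_af = 0)
  for (s in 1:100) {
    img <- render_mpm_image(mask, opt, seed = s)
    sums <- sums + c(mean(img$shg[mask == 1]), mean(img$shg[mask == 2]),
                     mean(img$af[mask == 1]), mean(img$af[mask == 2]))
  }
  est <- sums / 100
  truth <- c(opt$shg_stroma_mean, opt$shg_epithelial_mean,
             opt$af_stroma_mean, opt$af_epithelial_mean)
  expect_true(all(abs(est - truth) / truth < 0.01))
})

test_that("cohort generation matches the requested design and is reproducible", {
  man <- tiny_cohort()
  expect_equal(nrow(man), 8)
  expect_equal(as.vector(table(man$lesion)), c(4, 4))
  expect_equal(length(unique(man$patient_id)), 4)
  expect_true(all(file.exists(file.path(attr(man, "root"), man$image_path))))
  expect_true(all(file.exists(file.path(attr(man, "root"), man$mask_path))))

  # incompatible totals rejected
  expect_error(cohort_spec(n_patients_per_class = 2,
                           regions_per_patient_range = c(2, 2),
                           target_totals = c(FA = 5, PT = 4)),
               "incompatible")

  # same seed -> bit-identical files
  spec <- cohort_spec(n_patients_per_class = 1L,
                      regions_per_patient_range = c(2L, 2L),
                      target_totals = c(FA = 2L, PT = 2L), seed = 5L)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  for (d in c(d1, d2))
    generate_cohort(spec, optics_fa = optics_params(frame_size = 32),
                    optics_pt = pt_optics(frame_size = 32), dir = d)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("per-patient random effects induce intra-patient score correlation", {
  # one-way ANOVA on per-image area ratios, patient as the grouping factor;
  # strong patient effect for power, several cohorts pooled
  icc <- numeric(0)
  for (k in 1:6) {
    d <- file.path(tempdir(), paste0("icc", k))
    man <- generate_cohort(
      cohort_spec(seed = 300 + k),
      morph_fa = fa_morphology(patient_effect_sd = 0.6),
      morph_pt = pt_morphology(patient_effect_sd = 0.6),
      optics_fa = optics_params(frame_size = 48),
      optics_pt = pt_optics(frame_size = 48), dir = d)
    ratios <- vapply(seq_len(nrow(man)), function(i)
      area_ratio(read_mask(file.path(d, man$mask_path[i]))), numeric(1))
    for (cls in c("FA", "PT")) {
      sel <- man$lesion == cls
      fit <- stats::aov(ratios[sel] ~ factor(man$patient_id[sel]))
      ms <- summary(fit)[[1]][["Mean Sq"]]
      k_eff <- mean(table(man$patient_id[sel]))
      icc <- c(icc, (ms[1] - ms[2]) / (ms[1] + (k_eff - 1) * ms[2]))
    }
  }
  expect_gt(mean(icc), 0)
})

test_that("FA/PT defaults produce the two directional contrasts", {
  man <- tiny_cohort()  # direction check at small n; acceptance covers full n
  rep <- score_dataset(man, "ground_truth")
  expect_gt(rep$stats$area_ratio$mean[["PT"]],
            rep$stats$area_ratio$mean[["FA"]])
  expect_gt(rep$stats$shg_stroma_mean$mean[["FA"]],
            rep$stats$shg_stroma_mean$mean[["PT"]])
})
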