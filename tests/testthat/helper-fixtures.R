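# shared fixtures, built once per test session and cached

.fixtures <- new.env()

# 8-image cohort (2+2 patients, 2 regions each) at 64 px
tiny_cohort <- function() {
  if (!is.null(.fixtures$tiny)) return(.fixtures$tiny)
  d <- file.path(tempdir(), "tiny_cohort")
  spec <- cohort_spec(n_patients_per_class = 2L,
                      regions_per_patient_range = c(2L, 2L),
                      target_totals = c(FA = 4L, PT = 4L), seed = 42L)
  man <- generate_cohort(spec,
                         optics_fa = optics_params(frame_size = 64L),
                         optics_pt = pt_optics(frame_size = 64L),
                         dir = d)
  .fixtures$tiny <- man
  man
}

# small model trained on the tiny cohort (half split)
tiny_model <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  man <- split_dataset(tiny_cohort(), 0.5, seed = 7L)
  net <- network_config(encoder_depth = 2L, base_filters = 6L)
  cfg <- training_config(epochs = 200L, mini_batch = 2L, seed = 3L)
  .fixtures$model <- list(model = segnet(man, net, cfg), manifest = man)
  .fixtures$model
}

random_mask <- function(n = 8L) matrix(sample(0:2, n * n, replace = TRUE), n)

random_image <- function(n = 8L, bit_depth = 8L) {
  vmax <- 2^bit_depth - 1
  mpm_image(matrix(sample(0:vmax, n * n, TRUE), n),
            matrix(sample(0:vmax, n * n, TRUE), n), bit_depth = bit_depth)
}
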