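#' Cohort specification
#'
#' Describes the acquisition design the generator emulates: a number of
#' patients per lesion class, a per-patient range of imaged regions, and
#' fixed per-class image totals. Defaults reproduce the study design of
#' 5 FA and 5 PT patients with 6--12 regions each, totalling 33 FA and
#' 43 PT frames.
#'
#' @param n_patients_per_class Patients per lesion class.
#' @param regions_per_patient_range Inclusive integer interval `c(lo, hi)` of
#'   imaged regions per patient.
#' @param target_totals Named vector `c(FA = , PT = )` of images per class,
#'   or `NULL` to let region counts fall where they may.
#' @param seed Integer seed controlling every random choice in the cohort.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec()
cohort_spec <- function(n_patients_per_class = 5L,
                        regions_per_patient_range = c(6L, 12L),
                        target_totals = c(FA = 33L, PT = 43L),
                        seed = 1L) {
  n <- as.integer(n_patients_per_class)
  rng <- as.integer(regions_per_patient_range)
  stopifnot(length(rng) == 2L, rng[1] >= 1L, rng[2] >= rng[1], n >= 1L)
  if (!is.null(target_totals)) {
    tt <- as.integer(target_totals)
    names(tt) <- names(target_totals)
    stopifnot(all(c("FA", "PT") %in% names(tt)))
    for (cls in c("FA", "PT")) {
      if (tt[[cls]] < n * rng[1] || tt[[cls]] > n * rng[2]) {
        stop("target total for ", cls, " (", tt[[cls]],
             ") is incompatible with ", n, " patients imaging ",
             rng[1], "-", rng[2], " regions each")
      }
    }
    target_totals <- tt
  }
  structure(list(n_patients_per_class = n,
                 regions_per_patient_range = rng,
                 target_totals = target_totals,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Morphology parameters for one lesion class
#'
#' Controls the tissue-mask generator. `duct_shape` selects the epithelial
#' structure family: `"ellipse"` gives rounded ducts (FA-like, balanced
#' epithelial/stromal proliferation), `"cleft"` gives elongated curved
#' ribbons emulating the leaf-like epithelial clefts of phyllodes tumors.
#'
#' @param duct_count_mean Expected number of epithelial structures per image.
#' @param duct_eccentricity Shape eccentricity in `[0, 1)`; low for round
#'   FA ducts, high for elongated PT clefts.
#' @param epithelial_fraction_mean Target mean of epithelial / (epithelial +
#'   stromal) pixel fraction.
#' @param epithelial_fraction_sd Between-image standard deviation of that
#'   fraction.
#' @param tissue_coverage Fraction of the frame occupied by tissue; the
#'   remainder is the Outer class.
#' @param patient_effect_sd Between-patient random-effect scale, applied on
#'   the logit of the epithelial fraction and the log of SHG means.
#' @param duct_shape `"ellipse"` or `"cleft"`.
#' @return An object of class `morphology_params`.
#' @seealso [fa_morphology()], [pt_morphology()]
#' @export
morphology_params <- function(duct_count_mean = 6,
                              duct_eccentricity = 0.3,
                              epithelial_fraction_mean = 0.3,
                              epithelial_fraction_sd = 0.05,
                              tissue_coverage = 0.9,
                              patient_effect_sd = 0.15,
                              duct_shape = c("ellipse", "cleft")) {
  duct_shape <- match.arg(duct_shape)
  stopifnot(duct_count_mean > 0,
            duct_eccentricity >= 0, duct_eccentricity < 1,
            epithelial_fraction_mean >= 0, epithelial_fraction_mean <= 1,
            epithelial_fraction_sd >= 0,
            tissue_coverage >= 0, tissue_coverage <= 1,
            patient_effect_sd >= 0)
  structure(list(duct_count_mean = duct_count_mean,
                 duct_eccentricity = duct_eccentricity,
                 epithelial_fraction_mean = epithelial_fraction_mean,
                 epithelial_fraction_sd = epithelial_fraction_sd,
                 tissue_coverage = tissue_coverage,
                 patient_effect_sd = patient_effect_sd,
                 duct_shape = duct_shape),
            class = "morphology_params")
}

#' Default FA-like morphology
#'
#' Round epithelial ducts, moderate epithelial fraction: the balanced
#' epithelial and stromal proliferation typical of fibroadenoma.
#' @param ... Overrides passed to [morphology_params()].
#' @return A `morphology_params` object.
#' @export
fa_morphology <- function(...) {
  args <- list(duct_count_mean = 8, duct_eccentricity = 0.4,
               epithelial_fraction_mean = 0.30, epithelial_fraction_sd = 0.10,
               tissue_coverage = 0.9, patient_effect_sd = 0.15,
               duct_shape = "ellipse")
  do.call(morphology_params, utils::modifyList(args, list(...)))
}

#' Default PT-like morphology
#'
#' Elongated curved epithelial clefts and a larger epithelial fraction,
#' emulating the exaggerated leaf-like architecture of phyllodes tumor.
#' @param ... Overrides passed to [morphology_params()].
#' @return A `morphology_params` object.
#' @export
pt_morphology <- function(...) {
  args <- list(duct_count_mean = 5, duct_eccentricity = 0.92,
               epithelial_fraction_mean = 0.55, epithelial_fraction_sd = 0.15,
               tissue_coverage = 0.9, patient_effect_sd = 0.15,
               duct_shape = "cleft")
  do.call(morphology_params, utils::modifyList(args, list(...)))
}

#' Optics and noise parameters
#'
#' Class-conditional channel intensities on the raw 12-bit scale plus a
#' photon-counting noise model (Poisson shot noise and Gaussian read noise).
#' SHG arises from fibrillar collagen, so it is bright in stroma and dim in
#' epithelium; autofluorescence (NADH/flavins) is the reverse. FA stroma is
#' configured brighter in SHG than PT stroma.
#'
#' @param frame_size Pixels per side (square frames).
#' @param pixel_size Pixel pitch in micrometres.
#' @param bit_depth_raw Raw acquisition bit depth.
#' @param shg_stroma_mean Mean SHG intensity on stroma (12-bit scale).
#' @param shg_epithelial_mean Mean SHG intensity on epithelium.
#' @param af_epithelial_mean,af_stroma_mean Mean autofluorescence intensities.
#' @param read_noise_sd Gaussian read-noise standard deviation.
#' @param shot_noise Logical, apply Poisson shot noise.
#' @return An object of class `optics_params`.
#' @export
#' @examples
#' optics_params(frame_size = 128)
optics_params <- function(frame_size = 512L,
                          pixel_size = 1,
                          bit_depth_raw = 12L,
                          shg_stroma_mean = 1800,
                          shg_epithelial_mean = 300,
                          af_epithelial_mean = 2000,
                          af_stroma_mean = 800,
                          read_noise_sd = 40,
                          shot_noise = TRUE) {
  frame_size <- as.integer(frame_size)
  vmax <- 2^bit_depth_raw - 1
  means <- c(shg_stroma_mean, shg_epithelial_mean,
             af_epithelial_mean, af_stroma_mean)
  stopifnot(frame_size >= 1L, all(means >= 0), all(means <= vmax),
            read_noise_sd >= 0)
  structure(list(frame_size = frame_size, pixel_size = pixel_size,
                 bit_depth_raw = as.integer(bit_depth_raw),
                 shg_stroma_mean = shg_stroma_mean,
                 shg_epithelial_mean = shg_epithelial_mean,
                 af_epithelial_mean = af_epithelial_mean,
                 af_stroma_mean = af_stroma_mean,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "optics_params")
}

#' Default PT-like optics
#'
#' Same geometry and noise as [optics_params()] but with the weaker stromal
#' SHG configured for phyllodes tumor (collagen organisation difference).
#' @param ... Overrides passed to [optics_params()].
#' @return An `optics_params` object.
#' @export
pt_optics <- function(...) {
  do.call(optics_params, utils::modifyList(list(shg_stroma_mean = 1200), list(...)))
}
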