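# ---- synthetic cohort generator -------------------------------------------
# Emulates the acquisition design and the qualitative FA/PT contrasts: round
# ducts and stronger stromal SHG for fibroadenoma; elongated leaf-like
# epithelial clefts, larger epithelial fraction and weaker stromal SHG for
# phyllodes tumor. None of the defaults are measured values; they realise the
# verbal contrasts with controllable effect sizes.

# bilinear upsample of a coarse control grid to n x n
upsample_bilinear <- function(g, n) {
  gs <- nrow(g)
  xs <- seq(1, gs, length.out = n)
  # interpolate rows then columns
  tmp <- apply(g, 2, function(col) stats::approx(seq_len(gs), col, xout = xs)$y)
  t(apply(tmp, 1, function(row) stats::approx(seq_len(gs), row, xout = xs)$y))
}

# smooth random tissue blob occupying `coverage` of the frame (by quantile
# threshold of a low-frequency Gaussian field)
tissue_blob <- function(n, coverage, grid = 7L) {
  if (coverage >= 1) return(matrix(TRUE, n, n))
  if (coverage <= 0) return(matrix(FALSE, n, n))
  g <- matrix(rnorm(grid * grid), grid, grid)
  field <- upsample_bilinear(g, n)
  field >= stats::quantile(field, 1 - coverage, names = FALSE)
}

# pixel linear indices of an ellipse of area A, eccentricity e, centred at
# (r0, c0) with random orientation
ellipse_pixels <- function(r0, c0, A, e, theta, n) {
  aspect <- 1 / sqrt(1 - e^2)
  a <- sqrt(A * aspect / pi)
  b <- A / (pi * a)
  ext <- ceiling(a) + 1L
  rr <- max(1L, r0 - ext):min(n, r0 + ext)
  cc <- max(1L, c0 - ext):min(n, c0 + ext)
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rr[row(inside)[inside]], cc[col(inside)[inside]])
}

# pixel coordinates of a curved ribbon (random-walk path dilated to a width),
# the cleft model for PT-like epithelium
cleft_pixels <- function(r0, c0, A, e, n) {
  elong <- 1 / sqrt(1 - e^2)
  L <- max(4L, round(sqrt(A * elong)))
  wdt <- max(1, A / L)
  rad <- wdt / 2
  ir <- ceiling(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, , drop = FALSE]
  phi <- runif(1, 0, 2 * pi)
  r <- r0; c <- c0
  pts <- matrix(0L, nrow = L * nrow(off), ncol = 2)
  k <- 0L
  for (s in seq_len(L)) {
    phi <- phi + rnorm(1, 0, 0.2)
    r <- r + sin(phi); c <- c + cos(phi)
    if (r < 1 || r > n || c < 1 || c > n) {   # bounce back into the frame
      r <- min(max(r, 1), n); c <- min(max(c, 1), n)
      phi <- phi + pi / 2
    }
    m <- nrow(off)
    pts[(k + 1):(k + m), 1] <- as.integer(round(r) + off$dr)
    pts[(k + 1):(k + m), 2] <- as.integer(round(c) + off$dc)
    k <- k + m
  }
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= n, ,
             drop = FALSE]
  lin <- unique(pts[, 1] + (pts[, 2] - 1L) * n)
  cbind(((lin - 1L) %% n) + 1L, ((lin - 1L) %/% n) + 1L)
}

#' Generate a ground-truth tissue mask
#'
#' Draws a smooth tissue blob covering `tissue_coverage` of the frame
#' (complement = Outer), samples a target epithelial fraction from a
#' logit-normal law around `epithelial_fraction_mean`, and embeds epithelial
#' structures (round ellipses or elongated curved clefts, per `duct_shape`)
#' strictly inside the tissue until the target pixel count is met exactly
#' (the last structure is trimmed from its rim).
#'
#' @param morph A [morphology_params()] object.
#' @param frame_size Frame side in pixels.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return Integer label matrix over \{0 Outer, 1 Stroma, 2 Epithelial\}.
#' @export
#' @examples
#' m <- generate_tissue_mask(fa_morphology(), frame_size = 64, seed = 1)
#' table(m)
generate_tissue_mask <- function(morph, frame_size = 512L, seed = NULL) {
  stopifnot(inherits(morph, "morphology_params"))
  n <- as.integer(frame_size)
  if (n < 8L) stop("frame too small to place any duct (need >= 8 px)")
  gen <- function() {
    tissue <- tissue_blob(n, morph$tissue_coverage)
    n_tissue <- sum(tissue)
    mask <- matrix(LBL_OUTER, n, n)
    mask[tissue] <- LBL_STROMA
    m <- morph$epithelial_fraction_mean
    f <- if (m <= 0) 0 else if (m >= 1) 1 else if (morph$epithelial_fraction_sd == 0) m
         else plogis(rnorm(1, qlogis(m), morph$epithelial_fraction_sd / (m * (1 - m))))
    n_target <- round(f * n_tissue)
    if (n_target == 0L || n_tissue == 0L) return(mask)
    n_ducts <- max(1L, rpois(1, morph$duct_count_mean))
    A0 <- max(4, n_target / n_ducts)
    epi <- matrix(FALSE, n, n)
    placed <- 0L
    attempts <- 0L
    while (placed < n_target) {
      attempts <- attempts + 1L
      if (attempts > 100L * n_ducts + 200L)
        stop("frame too small to place any duct at the requested fraction")
      free <- which(tissue & !epi)
      if (!length(free)) break
      ctr <- free[sample.int(length(free), 1L)]
      r0 <- ((ctr - 1L) %% n) + 1L
      c0 <- ((ctr - 1L) %/% n) + 1L
      A <- A0 * runif(1, 0.7, 1.3)
      pix <- if (morph$duct_shape == "ellipse")
        ellipse_pixels(r0, c0, A, morph$duct_eccentricity, runif(1, 0, pi), n)
      else
        cleft_pixels(r0, c0, A, morph$duct_eccentricity, n)
      if (!nrow(pix)) next
      lin <- pix[, 1] + (pix[, 2] - 1L) * n
      lin <- lin[tissue[lin] & !epi[lin]]
      if (!length(lin)) next
      need <- n_target - placed
      if (length(lin) > need) {
        # trim from the rim: keep the pixels nearest the structure centre
        pr <- ((lin - 1L) %% n) + 1L
        pc <- ((lin - 1L) %/% n) + 1L
        lin <- lin[order((pr - r0)^2 + (pc - c0)^2)][seq_len(need)]
      }
      epi[lin] <- TRUE
      placed <- placed + length(lin)
    }
    mask[epi] <- LBL_EPITHELIAL
    mask
  }
  if (is.null(seed)) gen() else with_seed(seed, gen)
}

#' Render a two-channel MPM image from a label mask
#'
#' Applies class-conditional mean intensities (SHG bright on stroma, dim on
#' epithelium, zero outside tissue; AF the reverse), Poisson shot noise on
#' the signal and Gaussian read noise, then clips to the 12-bit range and
#' quantizes. Bit-identical for a fixed seed.
#'
#' @param mask Label mask from [generate_tissue_mask()].
#' @param optics An [optics_params()] object.
#' @param seed Integer seed (`NULL` uses current RNG state).
#' @return An [mpm_image()] at `bit_depth_raw`.
#' @export
render_mpm_image <- function(mask, optics, seed = NULL) {
  mask <- check_mask(mask)
  stopifnot(inherits(optics, "optics_params"))
  if (nrow(mask) != optics$frame_size || ncol(mask) != optics$frame_size)
    stop("mask shape (", nrow(mask), "x", ncol(mask),
         ") does not match optics frame_size ", optics$frame_size)
  vmax <- 2^optics$bit_depth_raw - 1
  channel <- function(means) {
    base <- matrix(means[1], nrow(mask), ncol(mask))   # Outer
    base[mask == LBL_STROMA] <- means[2]
    base[mask == LBL_EPITHELIAL] <- means[3]
    v <- if (optics$shot_noise) rpois(length(base), base) else base
    if (optics$read_noise_sd > 0)
      v <- v + rnorm(length(base), 0, optics$read_noise_sd)
    matrix(pmin(pmax(round(v), 0), vmax), nrow(mask), ncol(mask))
  }
  gen <- function() {
    shg <- channel(c(0, optics$shg_stroma_mean, optics$shg_epithelial_mean))
    af <- channel(c(0, optics$af_stroma_mean, optics$af_epithelial_mean))
    mpm_image(shg, af, bit_depth = optics$bit_depth_raw,
              pixel_size = optics$pixel_size)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen)
}

# split `total` into n parts, each within [lo, hi] (sequential constrained
# sampling; deterministic under the caller's RNG state)
sample_composition <- function(total, n, lo, hi) {
  if (total < n * lo || total > n * hi)
    stop("total ", total, " incompatible with ", n, " parts in [", lo, ",", hi, "]")
  parts <- integer(n)
  rem <- total
  for (i in seq_len(n)) {
    r <- n - i
    kmin <- max(lo, rem - r * hi)
    kmax <- min(hi, rem - r * lo)
    parts[i] <- if (kmin == kmax) kmin else sample(kmin:kmax, 1L)
    rem <- rem - parts[i]
  }
  parts
}

#' Generate a full synthetic cohort to disk
#'
#' Emulates the study design: `n_patients_per_class` patients per lesion,
#' 6--12 imaged regions each, per-class image totals fixed (default 33 FA +
#' 43 PT). Per-patient Gaussian random effects shift the logit of the
#' epithelial fraction and the log of the SHG intensity means, so frames
#' from one patient are correlated. Every image gets its own seed derived
#' from the cohort seed, making the cohort bit-reproducible.
#'
#' @param spec A [cohort_spec()].
#' @param morph_fa,morph_pt [morphology_params()] for each lesion class.
#' @param optics_fa,optics_pt [optics_params()] for each lesion class.
#' @param shg_patient_effect_sd Between-patient random-effect scale on the
#'   log SHG intensity means (collagen brightness varies less across
#'   patients than duct morphology does).
#' @param dir Output directory (created if needed); images under `images/`,
#'   masks under `masks/`, manifest at `manifest.csv`.
#' @return The manifest data frame (invisibly also written to
#'   `dir/manifest.csv`), with `attr(, "root") = dir`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            morph_fa = fa_morphology(),
                            morph_pt = pt_morphology(),
                            optics_fa = optics_params(),
                            optics_pt = pt_optics(),
                            shg_patient_effect_sd = 0.08,
                            dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  lo <- spec$regions_per_patient_range[1]
  hi <- spec$regions_per_patient_range[2]
  rows <- list()
  gidx <- 0L
  for (lesion in c("FA", "PT")) {
    morph <- if (lesion == "FA") morph_fa else morph_pt
    optics <- if (lesion == "FA") optics_fa else optics_pt
    total <- if (is.null(spec$target_totals)) NA_integer_
             else spec$target_totals[[lesion]]
    counts <- with_seed(derive_seed(spec$seed, "regions", match(lesion, c("FA", "PT"))),
      function() {
        if (is.na(total)) sample(lo:hi, spec$n_patients_per_class, replace = TRUE)
        else sample_composition(total, spec$n_patients_per_class, lo, hi)
      })
    for (p in seq_len(spec$n_patients_per_class)) {
      pid <- sprintf("%s%02d", lesion, p)
      eff <- with_seed(derive_seed(spec$seed, "patient", gidx * 1000L + p),
                       function() c(rnorm(1, 0, morph$patient_effect_sd),
                                    rnorm(1, 0, shg_patient_effect_sd)))
      m <- morph
      if (m$epithelial_fraction_mean > 0 && m$epithelial_fraction_mean < 1)
        m$epithelial_fraction_mean <- plogis(qlogis(m$epithelial_fraction_mean) + eff[1])
      o <- optics
      fac <- exp(eff[2])
      vmax <- 2^o$bit_depth_raw - 1
      o$shg_stroma_mean <- min(o$shg_stroma_mean * fac, vmax)
      o$shg_epithelial_mean <- min(o$shg_epithelial_mean * fac, vmax)
      for (r in seq_len(counts[p])) {
        iid <- sprintf("%s_r%02d", pid, r)
        img_seed <- derive_seed(spec$seed, "image", length(rows) + 1L)
        mask <- generate_tissue_mask(m, frame_size = o$frame_size,
                                     seed = derive_seed(img_seed, "mask"))
        img <- render_mpm_image(mask, o, seed = derive_seed(img_seed, "render"))
        ipath <- file.path("images", paste0(iid, ".tif"))
        mpath <- file.path("masks", paste0(iid, ".png"))
        write_mpm_image(img, file.path(dir, ipath))
        write_mask(mask, file.path(dir, mpath))
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = iid, patient_id = pid, lesion = lesion,
          image_path = ipath, mask_path = mpath, seed = img_seed,
          bit_depth = o$bit_depth_raw, stringsAsFactors = FALSE)
      }
    }
    gidx <- gidx + 1L
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  attr(manifest, "root") <- normalizePath(dir)
  invisible(manifest)
}
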