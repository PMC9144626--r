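# ---- end-to-end pipeline driver -------------------------------------------
# simulate -> split -> train -> predict -> evaluate -> score -> classify,
# driven by one config and one global seed. Completed stages are detected by
# their artifacts and skipped on re-run, so a run can resume.

#' Default pipeline run configuration
#'
#' One nested list drives the whole pipeline. The `"paper"` preset keeps the
#' reference settings (512 px frames, 5000 epochs); the `"desk"` preset is
#' the scaled-down configuration used throughout the package's own analyses
#' (128 px frames, 60 epochs, 2 pooling stages) which a single CPU handles
#' in minutes. The configuration round-trips losslessly through YAML.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Global seed; every stochastic stage derives its own seed from
#'   it via [derive_seed()].
#' @param ... Named overrides merged into the preset (e.g.
#'   `training = list(epochs = 10)`).
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(preset = c("desk", "paper"), seed = 1L, ...) {
  preset <- match.arg(preset)
  frame <- if (preset == "desk") 128L else 512L
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(n_patients_per_class = 5L,
                  regions_per_patient_range = c(6L, 12L),
                  target_totals = c(FA = 33L, PT = 43L)),
    morphology = list(
      FA = list(duct_count_mean = 8, duct_eccentricity = 0.4,
                epithelial_fraction_mean = 0.30, epithelial_fraction_sd = 0.10,
                tissue_coverage = 0.9, patient_effect_sd = 0.15,
                duct_shape = "ellipse"),
      PT = list(duct_count_mean = 5, duct_eccentricity = 0.92,
                epithelial_fraction_mean = 0.55, epithelial_fraction_sd = 0.15,
                tissue_coverage = 0.9, patient_effect_sd = 0.15,
                duct_shape = "cleft")),
    optics = list(frame_size = frame, shg_stroma_mean_fa = 1800,
                  shg_stroma_mean_pt = 1200, shg_epithelial_mean = 300,
                  af_epithelial_mean = 2000, af_stroma_mean = 800,
                  read_noise_sd = 40, shot_noise = TRUE,
                  shg_patient_effect_sd = 0.08),
    network = list(input_channels = 2L, n_classes = 3L,
                   encoder_depth = if (preset == "desk") 2L else 3L,
                   base_filters = 8L, use_pooling_indices = TRUE),
    training = list(momentum = 0.9, learning_rate = 0.01,
                    l2_regularization = 0.0005,
                    epochs = if (preset == "desk") 60L else 5000L,
                    mini_batch = 4L, max_translation_px = 20L,
                    flip_augment = TRUE),
    split = list(train_fraction = 0.5),
    classification = list(block_px = if (preset == "desk") 32L else 128L,
                          n_per_class = 500L))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns the configuration.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$cohort$target_totals <- as.list(cfg$cohort$target_totals)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cohort$target_totals <- unlist(cfg$cohort$target_totals)
  cfg$cohort$regions_per_patient_range <-
    unlist(cfg$cohort$regions_per_patient_range)
  class(cfg) <- "run_config"
  cfg
}

cfg_objects <- function(cfg) {
  o <- cfg$optics
  base <- list(frame_size = o$frame_size,
               pixel_size = if (is.null(o$pixel_size)) 1 else o$pixel_size,
               shg_epithelial_mean = o$shg_epithelial_mean,
               af_epithelial_mean = o$af_epithelial_mean,
               af_stroma_mean = o$af_stroma_mean,
               read_noise_sd = o$read_noise_sd, shot_noise = o$shot_noise)
  shg_pe <- if (is.null(o$shg_patient_effect_sd)) 0.08 else o$shg_patient_effect_sd
  list(
    spec = cohort_spec(cfg$cohort$n_patients_per_class,
                       cfg$cohort$regions_per_patient_range,
                       cfg$cohort$target_totals,
                       seed = derive_seed(cfg$seed, "cohort")),
    morph_fa = do.call(morphology_params, cfg$morphology$FA),
    morph_pt = do.call(morphology_params, cfg$morphology$PT),
    optics_fa = do.call(optics_params,
                        c(base, list(shg_stroma_mean = o$shg_stroma_mean_fa))),
    optics_pt = do.call(optics_params,
                        c(base, list(shg_stroma_mean = o$shg_stroma_mean_pt))),
    shg_patient_effect_sd = shg_pe,
    net = do.call(network_config, cfg$network),
    train_cfg = do.call(training_config,
                        c(cfg$training,
                          list(seed = derive_seed(cfg$seed, "train")))))
}

#' Predict masks for every manifest image
#'
#' Writes one PNG mask per image under `masks_pred/` and adds a
#' `pred_mask_path` column. Existing predictions are reused unless
#' `overwrite`.
#'
#' @param model A fitted [segnet()] model.
#' @param manifest Manifest data frame with `attr(, "root")`.
#' @param overwrite Recompute masks that already exist on disk.
#' @return The manifest with `pred_mask_path` filled in.
#' @export
predict_manifest <- function(model, manifest, overwrite = FALSE) {
  root <- attr(manifest, "root")
  dir.create(file.path(root, "masks_pred"), showWarnings = FALSE)
  manifest$pred_mask_path <- file.path("masks_pred",
                                       paste0(manifest$image_id, ".png"))
  for (i in seq_len(nrow(manifest))) {
    out <- file.path(root, manifest$pred_mask_path[i])
    if (file.exists(out) && !overwrite) next
    img <- read_mpm_image(manifest_path(manifest, "image_path", i),
                          bit_depth = if ("bit_depth" %in% names(manifest))
                            manifest$bit_depth[i] else 12L)
    write_mask(predict(model, img), out)
  }
  manifest
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, splits it, trains the segmentation
#' network, predicts masks for every image, evaluates both splits, scores
#' both mask sources, fits the block-level and image-level LDA, and writes
#' every artifact (with MD5 checksums in `artifacts.csv`) under `out_dir`.
#' Re-running with the same config resumes from existing artifacts.
#'
#' @param cfg A [default_run_config()] configuration.
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return Invisible list with the manifest, model, reports and LDA fits.
#' @export
run_full <- function(cfg = default_run_config(), out_dir, verbose = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  obj <- cfg_objects(cfg)
  write_run_config(cfg, file.path(out_dir, "run_config.yaml"))

  # -- simulate
  man_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(man_path)) {
    say("[simulate] reusing existing cohort")
    manifest <- read_manifest(man_path)
  } else {
    say("[simulate] generating cohort")
    manifest <- generate_cohort(obj$spec, obj$morph_fa, obj$morph_pt,
                                obj$optics_fa, obj$optics_pt,
                                shg_patient_effect_sd = obj$shg_patient_effect_sd,
                                dir = out_dir)
  }

  # -- split
  if (!"split" %in% names(manifest)) {
    manifest <- split_dataset(manifest, cfg$split$train_fraction,
                              seed = derive_seed(cfg$seed, "split"))
    write_manifest(manifest, man_path)
    attr(manifest, "root") <- normalizePath(out_dir)
  }
  say("[split] %d train / %d test", sum(manifest$split == "train"),
      sum(manifest$split == "test"))

  # -- train
  model_path <- file.path(out_dir, "model.json")
  if (file.exists(model_path)) {
    say("[train] reusing checkpoint")
    model <- load_segnet(model_path)
  } else {
    say("[train] %d epochs", obj$train_cfg$epochs)
    model <- segnet(manifest, obj$net, obj$train_cfg, verbose = verbose)
    save_segnet(model, model_path)
  }

  # -- predict
  say("[predict] writing predicted masks")
  manifest <- predict_manifest(model, manifest)
  write_manifest(manifest, man_path)
  attr(manifest, "root") <- normalizePath(out_dir)

  # -- evaluate
  say("[evaluate] per-image metrics")
  evals <- lapply(c(train = "train", test = "test"), function(s) {
    rep <- evaluate_split(model, manifest, s)
    write_eval_report(rep, file.path(out_dir, paste0("eval_", s, ".csv")),
                      file.path(out_dir, paste0("eval_", s, ".json")))
    rep
  })

  # -- score
  say("[score] both mask sources")
  scores <- lapply(c(ground_truth = "ground_truth", predicted = "predicted"),
                   function(src) {
    rep <- score_dataset(manifest, src)
    utils::write.csv(rep$records,
                     file.path(out_dir, paste0("scores_", src, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(score_stats_list(rep$stats),
                         file.path(out_dir, paste0("scores_", src, ".json")),
                         digits = NA, auto_unbox = TRUE)
    plot_score_bars(rep, file.path(out_dir, paste0("scores_", src, ".png")))
    rep
  })

  # -- classify
  say("[classify] image- and block-level LDA")
  cls <- list()
  for (src in c("ground_truth", "predicted")) {
    img_pts <- image_features(scores[[src]])
    blk_pts <- build_block_features(manifest, src,
                                    block_px = cfg$classification$block_px,
                                    n_per_class = cfg$classification$n_per_class,
                                    seed = derive_seed(cfg$seed, "blocks"))
    for (gran in c("full_image", "block")) {
      pts <- if (gran == "full_image") img_pts else blk_pts
      fit <- fit_lda(pts)
      pred <- predict(fit, pts)
      tag <- paste0(src, "_", gran)
      cls[[tag]] <- list(fit = fit, accuracy = attr(pred, "accuracy"),
                         angle = if (fit$degenerate) NA_real_
                                 else boundary_angle_to_shg_axis(fit))
      jsonlite::write_json(list(
        w = fit$w, b = fit$b, class_means = fit$class_means,
        pooled_cov = fit$pooled_cov, standardized = fit$standardize,
        accuracy = attr(pred, "accuracy"),
        boundary_angle_deg = cls[[tag]]$angle),
        file.path(out_dir, paste0("lda_", tag, ".json")),
        digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
      plot_feature_space(pts, fit,
                         file.path(out_dir, paste0("scatter_", tag, ".png")))
    }
  }

  # -- artifact checksums
  files <- setdiff(list.files(out_dir, recursive = TRUE), "artifacts.csv")
  sums <- tools::md5sum(file.path(out_dir, files))
  utils::write.csv(data.frame(path = files, md5 = unname(sums)),
                   file.path(out_dir, "artifacts.csv"), row.names = FALSE)
  say("[done] %.1f s elapsed", as.numeric(difftime(Sys.time(), t0, "secs")))
  invisible(list(manifest = manifest, model = model, evals = evals,
                 scores = scores, classification = cls, out_dir = out_dir))
}

score_stats_list <- function(stats) {
  lapply(unclass(stats), function(s)
    list(mean = as.list(s$mean), sd = as.list(s$sd),
         ks_D = s$ks_D, ks_p = s$ks_p, ks_method = s$ks_method))
}

#' Render a plain-text summary report for a completed run
#'
#' Collates the serialized artifacts (no recomputation) into one readable
#' report mirroring the result structure of the analysis: segmentation
#' metric table, group score statistics with KS significance, and the LDA
#' summary.
#'
#' @param out_dir A completed [run_full()] directory.
#' @param path Output file (default `report.txt` inside the run directory).
#' @return The report text, invisibly.
#' @export
run_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  lines <- c("mpmtumor pipeline report", strrep("=", 40), "")
  grab <- function(f) jsonlite::read_json(file.path(out_dir, f),
                                          simplifyVector = TRUE)
  for (s in c("train", "test")) {
    f <- paste0("eval_", s, ".json")
    if (file.exists(file.path(out_dir, f))) {
      e <- grab(f)
      lines <- c(lines, sprintf("Segmentation (%s split):", s),
                 sprintf("  %-15s mean %.4f  sd %.4f", e$summary$metric,
                         e$summary$mean, e$summary$sd), "")
    } else lines <- c(lines, sprintf("Segmentation (%s split): MISSING", s), "")
  }
  for (src in c("ground_truth", "predicted")) {
    f <- paste0("scores_", src, ".json")
    if (file.exists(file.path(out_dir, f))) {
      sc <- grab(f)
      lines <- c(lines, sprintf("Scores (%s masks):", src))
      for (nm in names(sc)) {
        s <- sc[[nm]]
        lines <- c(lines, sprintf(
          "  %-16s FA %.3f+/-%.3f  PT %.3f+/-%.3f  KS D=%.3f p=%.3g%s",
          nm, s$mean$FA, s$sd$FA, s$mean$PT, s$sd$PT, s$ks_D, s$ks_p,
          if (s$ks_p < 0.05) " *" else ""))
      }
      lines <- c(lines, "")
    } else lines <- c(lines, sprintf("Scores (%s masks): MISSING", src), "")
  }
  for (tag in c("ground_truth_full_image", "ground_truth_block",
                "predicted_full_image", "predicted_block")) {
    f <- paste0("lda_", tag, ".json")
    if (file.exists(file.path(out_dir, f))) {
      l <- grab(f)
      lines <- c(lines, sprintf(
        "LDA (%s): accuracy %.3f, boundary angle to SHG axis %.1f deg",
        tag, l$accuracy, l$boundary_angle_deg))
    } else lines <- c(lines, sprintf("LDA (%s): MISSING", tag))
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, path)
  invisible(txt)
}
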