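# Run configuration and end-to-end pipeline.
#
# A run configuration is a nested list with one section per pipeline
# stage (scene, patches, model, train, tiling, metrics) plus a global
# seed and output root. YAML files are merged over the defaults;
# unknown keys are rejected with the offending key path, and every run
# writes its fully resolved configuration back to disk.

#' Default run configuration
#'
#' @return nested list of all pipeline settings (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_root = "runs",
    scene = list(n_patients = 10L, images_per_patient = 3L,
                 height = 512L, width = 512L, px_per_mm = 5,
                 n_lesions = c(1L, 3L), lesion_diameter_mm = c(4, 16),
                 contrast = c(0.15, 0.30), boundary_softness_px = c(1.5, 3),
                 n_hairs = c(2L, 5L), n_spots = c(1L, 4L), noise_sd = 0.03),
    patches = list(side = 512L, final_side = 256L, n_offsets = 8L,
                   max_shift = NULL,
                   fractions = c(train = 0.8, val = 0.1, test = 0.1)),
    model = list(input_side = 256L, base_filters = 64L,
                 convlstm_grid = c(4L, 4L), convlstm_kernel = 3L,
                 skip_fusion = "convlstm", bn_decoder = TRUE,
                 threshold = 0.5),
    train = list(learning_rate = 0.001, weight_decay = 1e-6,
                 batch_size = 32L, epochs = 100L),
    tiling = list(overlap = 0L, min_area_px = 0L),
    metrics = list(connectivity = 8L)
  ), class = "run_config")
}

#' Small smoke-test run configuration
#'
#' A tiny-everything configuration exercising every pipeline stage in
#' minutes on one CPU: small scenes, a narrow network (input 64, base
#' filters 8, 2x2 fusion grid) and a short training budget. Intended
#' for pipeline verification, not for accuracy.
#'
#' @return a `run_config`.
#' @export
smoke_run_config <- function() {
  cfg <- default_run_config()
  cfg$scene$n_patients <- 5L
  cfg$scene$images_per_patient <- 2L
  cfg$scene$height <- 256L
  cfg$scene$width <- 256L
  cfg$scene$n_lesions <- c(1L, 2L)
  cfg$scene$lesion_diameter_mm <- c(6, 14)
  cfg$patches$side <- 128L
  cfg$patches$final_side <- 64L
  cfg$patches$n_offsets <- 2L
  cfg$patches$fractions <- c(train = 0.6, val = 0.2, test = 0.2)
  cfg$model$input_side <- 64L
  cfg$model$base_filters <- 8L
  cfg$model$convlstm_grid <- c(2L, 2L)
  cfg$train$batch_size <- 8L
  cfg$train$epochs <- 2L
  cfg
}

# Recursive merge of `user` over `defaults`, erroring on unknown keys.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", key))
    }
    if (is.null(user[[nm]])) next  # explicit null keeps the default
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Values in the file override the defaults; unknown keys raise an
#' error naming the key path. An empty file yields all defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  user <- yaml::yaml.load_file(path)
  cfg <- .merge_config(default_run_config(), user)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as YAML
#'
#' `load_config(save_config(cfg, path))` restores the configuration.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  # yaml serializes named atomic vectors as plain sequences; convert
  # them to maps so names survive the round trip
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else x
  }
  x <- config
  class(x) <- NULL
  yaml::write_yaml(prep(x), path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline: synthesize, crop, train, predict, score
#'
#' Generates a synthetic multi-patient dataset, splits it at the
#' patient level, extracts translation-augmented training crops and
#' lesion-centered test crops, trains the configured network, runs
#' tiled wide-field inference on the held-out patients' full scenes,
#' and scores predictions with Dice/IoU and the region-tolerant
#' metrics. All artifacts (resolved config, split manifest, training
#' history, report) are written to `out_dir`.
#'
#' @param config a `run_config`, e.g. [smoke_run_config()].
#' @param out_dir run directory (created; default under
#'   `config$out_root`).
#' @param verbose print stage progress.
#' @return the report: list with `aggregate` metrics data.frame,
#'   `per_image` data.frame, `split_counts`, `test_patients`,
#'   `train_patients` and `history`.
#' @export
run_end_to_end <- function(config = smoke_run_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) {
    out_dir <- file.path(config$out_root,
                         format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage synth")
  data <- .stage("synth", {
    sc <- config$scene
    generate_dataset(sc$n_patients, sc$images_per_patient,
                     scene_config(height = sc$height, width = sc$width,
                                  px_per_mm = sc$px_per_mm,
                                  n_lesions = sc$n_lesions,
                                  lesion_diameter_mm = sc$lesion_diameter_mm,
                                  contrast = sc$contrast,
                                  boundary_softness_px = sc$boundary_softness_px,
                                  n_hairs = sc$n_hairs, n_spots = sc$n_spots,
                                  noise_sd = sc$noise_sd, seed = config$seed))
  })

  say("stage split")
  manifest <- .stage("split", split_by_patient(data$images,
                                               config$patches$fractions,
                                               seed = config$seed))
  save_manifest(manifest, file.path(out_dir, "split_manifest.json"))
  pid_of <- vapply(data$images, `[[`, character(1), "patient_id")
  split_of <- manifest$split[match(pid_of, manifest$patient_id)]
  # leakage guard
  for (a in unique(manifest$split)) for (b in unique(manifest$split)) {
    if (a < b) stopifnot(length(intersect(
      manifest$patient_id[manifest$split == a],
      manifest$patient_id[manifest$split == b])) == 0)
  }

  say("stage crops")
  crop_sets <- .stage("crops", build_crop_sets(
    data$images, manifest, side = config$patches$side,
    final_side = config$patches$final_side,
    n_offsets = config$patches$n_offsets,
    max_shift = config$patches$max_shift, seed = config$seed))

  say("stage train (%d train / %d val crops)",
      length(crop_sets$train), length(crop_sets$val %||% list()))
  model <- .stage("train", {
    mc <- config$model
    m <- build_model(aku_model_config(
      input_side = mc$input_side, base_filters = mc$base_filters,
      convlstm_grid = mc$convlstm_grid, convlstm_kernel = mc$convlstm_kernel,
      skip_fusion = mc$skip_fusion, bn_decoder = mc$bn_decoder,
      threshold = mc$threshold, seed = config$seed))
    tc <- config$train
    fit_akunet(m, crop_sets$train, crop_sets$val,
               train_config(learning_rate = tc$learning_rate,
                            weight_decay = tc$weight_decay,
                            batch_size = tc$batch_size, epochs = tc$epochs,
                            seed = config$seed))
  })
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  save_model(model, file.path(out_dir, "checkpoint"))

  say("stage predict+score")
  test_idx <- which(split_of == "test")
  if (!length(test_idx)) stop("pipeline stage 'predict' failed: no test images")
  reports <- list()
  per_image <- NULL
  .stage("predict_score", {
    for (ii in test_idx) {
      img <- data$images[[ii]]
      half <- rescale_half(img)  # inference at the training scale
      prob <- predict_wide(half$image, model,
                           plan_tiling(dim(half$mask)[1], dim(half$mask)[2],
                                       model$config$input_side,
                                       config$tiling$overlap))
      det <- detect_regions(prob, model$config$threshold,
                            config$tiling$min_area_px,
                            config$metrics$connectivity)
      rep <- adapted_scores(extract_regions(half$mask,
                                            config$metrics$connectivity),
                            det$mask, half$mask)
      reports[[length(reports) + 1L]] <- rep
      per_image <- rbind(per_image, data.frame(
        stem = data$index$stem[ii], patient_id = img$patient_id,
        dice = rep$dice, iou = rep$iou, aprec = rep$aprec, arec = rep$arec,
        af1 = rep$af1, tpc = rep$tpc, n_regions = rep$n_regions))
    }
  })

  report <- list(
    aggregate = aggregate_metrics(reports),
    per_image = per_image,
    split_counts = as.list(table(manifest$split)),
    test_patients = manifest$patient_id[manifest$split == "test"],
    train_patients = manifest$patient_id[manifest$split == "train"],
    history = model$history)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report
}
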