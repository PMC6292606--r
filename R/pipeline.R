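#' Pipeline run configuration
#'
#' Central bundle of every tunable parameter of the train/detect/evaluate
#' pipeline, with documented defaults. Unknown keys are rejected.
#'
#' @param illumination list: `wsize` (window side, px; default 64).
#' @param pattern list: `diameter_px` (default 40) or `offsets` (explicit
#'   integer offset matrix overriding the two-ring default).
#' @param boosting list: `rounds` (default 200), `seed` (default 1),
#'   `neg_pos_ratio` (default 3), `max_pos_per_image` (default 2000),
#'   `score_threshold` (default 0).
#' @param postprocess list: `opening_radius` (default 2), `min_area`
#'   (default 100).
#' @param evaluation list: `avg_cells_per_image` (default 1270),
#'   `overlap_threshold` (default 0.25).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(illumination = list(), pattern = list(),
                       boosting = list(), postprocess = list(),
                       evaluation = list()) {
  fill <- function(given, defaults, section) {
    extra <- setdiff(names(given), names(defaults))
    if (length(extra)) {
      stop("unknown ", section, " config keys: ",
           paste(extra, collapse = ", "))
    }
    utils::modifyList(defaults, given)
  }
  structure(list(
    illumination = fill(illumination, list(wsize = 64), "illumination"),
    pattern = fill(pattern, list(diameter_px = 40, offsets = NULL),
                   "pattern"),
    boosting = fill(boosting, list(rounds = 200, seed = 1,
                                   neg_pos_ratio = 3,
                                   max_pos_per_image = 2000,
                                   score_threshold = 0), "boosting"),
    postprocess = fill(postprocess, list(opening_radius = 2,
                                         min_area = 100), "postprocess"),
    evaluation = fill(evaluation, list(avg_cells_per_image = 1270,
                                       overlap_threshold = 0.25),
                      "evaluation")
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose top-level keys are
#'   the sections of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON")
  )
  extra <- setdiff(names(raw), c("illumination", "pattern", "boosting",
                                 "postprocess", "evaluation"))
  if (length(extra)) {
    stop("unknown config sections: ", paste(extra, collapse = ", "))
  }
  do.call(run_config, raw)
}

config_pattern <- function(config) {
  if (!is.null(config$pattern$offsets)) {
    ctc_pattern(matrix(as.integer(unlist(config$pattern$offsets)), ncol = 2),
                diameter_px = config$pattern$diameter_px)
  } else {
    default_pattern(config$pattern$diameter_px)
  }
}

#' Train a CTC detector from a manifest
#'
#' Illumination-corrects every training image, builds channel stacks,
#' samples labeled pixels, extracts feature vectors and trains the
#' AdaBoost ensemble.
#'
#' @param manifest manifest tibble (`image`, `mask`, `split`).
#' @param config a [run_config()].
#' @param split train on entries with this tag (`NULL` = all).
#' @return A `ctc_boost` model (its `feature_config` records the pattern
#'   and illumination window used).
#' @export
train_detector <- function(manifest, config = run_config(),
                           split = "train") {
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  if (nrow(manifest) == 0L) stop("no manifest entries to train on")
  if (any(is.na(manifest$mask) | manifest$mask == "")) {
    stop("all training entries need masks")
  }
  illum <- illum_config(config$illumination$wsize)
  pattern <- config_pattern(config)
  images <- purrr::map(manifest$image, read_image)
  masks <- purrr::map(seq_along(images), function(i) {
    read_mask(manifest$mask[i], images[[i]]$height, images[[i]]$width)
  })
  samples <- sample_training_pixels(
    images, masks,
    neg_pos_ratio = config$boosting$neg_pos_ratio,
    max_pos_per_image = config$boosting$max_pos_per_image,
    seed = config$boosting$seed
  )
  feats <- matrix(0, nrow(samples), 15L * pattern$n_samples)
  for (i in seq_along(images)) {
    sel <- samples$image == i
    if (!any(sel)) next
    stack <- compute_channel_stack(correct_illumination(images[[i]], illum))
    feats[sel, ] <- extract_feature_matrix(
      stack, cbind(samples$row[sel], samples$col[sel]), pattern)
  }
  train_adaboost(
    feats, samples$label,
    n_rounds = config$boosting$rounds,
    seed = config$boosting$seed,
    feature_config = list(pattern = pattern,
                          wsize = config$illumination$wsize),
    score_threshold = config$boosting$score_threshold
  )
}

#' Run the full pipeline: train, then evaluate
#'
#' Trains on the manifest's `train` split and evaluates on its `test`
#' split; optionally writes the model, per-image counts, detections and
#' metrics report under `out_dir`.
#'
#' @param manifest manifest tibble.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return A list of class `ctc_run`: `model` (`ctc_boost`), `evaluation`
#'   (`ctc_eval`), `config`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL) {
  model <- train_detector(manifest, config, split = "train")
  ev <- evaluate_dataset(
    manifest, model, split = "test",
    opening_radius = config$postprocess$opening_radius,
    min_area = config$postprocess$min_area,
    score_threshold = config$boosting$score_threshold,
    overlap_threshold = config$evaluation$overlap_threshold,
    avg_cells_per_image = config$evaluation$avg_cells_per_image,
    out_dir = out_dir
  )
  if (!is.null(out_dir)) {
    save_model(model, file.path(out_dir, "model.json"))
  }
  structure(list(model = model, evaluation = ev, config = config),
            class = "ctc_run")
}

#' @export
print.ctc_run <- function(x, ...) {
  print(x$model)
  print(x$evaluation)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `ctc_run` object.
#' @param ... unused.
#' @export
glance.ctc_run <- function(x, ...) {
  dplyr::bind_cols(glance(x$model), x$evaluation$metrics)
}

#' Synthetic end-to-end recovery benchmark
#'
#' The package's standard self-contained experiment: generate a synthetic
#' darkfield dataset (default 30 scenes of 512 x 512 px with 3--5 tumor
#' cells each at default appearance parameters), train the detector on the
#' 70% train split (default 200 boosting rounds) and evaluate object-level
#' recovery on the 30% test split at default thresholds.
#'
#' @param seed base RNG seed controlling scene generation and pixel
#'   sampling.
#' @param n_images number of scenes (default 30; 21 train / 9 test).
#' @param params a [scene_params()] for the generator.
#' @param config a [run_config()] for the pipeline.
#' @param out_dir scratch directory for the generated images (a temporary
#'   directory by default, removed afterwards unless supplied).
#' @return A `ctc_run`; its evaluation metrics additionally carry
#'   `fp_per_image = FP / n_images`.
#' @export
run_synthetic_benchmark <- function(seed = 1, n_images = 30,
                                    params = scene_params(),
                                    config = run_config(),
                                    out_dir = NULL) {
  cleanup <- is.null(out_dir)
  if (cleanup) out_dir <- tempfile("ctcdf_bench_")
  config$boosting$seed <- seed
  manifest <- generate_dataset(n_images, params, out_dir = out_dir,
                               seed = seed)
  res <- run_pipeline(manifest, config)
  if (cleanup) unlink(out_dir, recursive = TRUE)
  res$evaluation$metrics$fp_per_image <-
    res$evaluation$metrics$FP / res$evaluation$metrics$n_images
  res
}
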