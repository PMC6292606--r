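#' Match detections against ground-truth objects (one image)
#'
#' Greedy one-to-one matching in decreasing pixel-overlap order. A
#' detection/ground-truth pair is matchable when their pixel overlap is at
#' least `overlap_threshold` of the smaller object. TP = matched ground
#' truth, FN = unmatched ground truth, FP = unmatched detections.
#'
#' @param detections a `ctc_objects` tibble (with its `"labels"` attribute)
#'   of validated detections.
#' @param gt_objects a `ctc_objects` tibble of ground-truth objects, from
#'   [label_components()] on the ground-truth mask.
#' @param overlap_threshold minimum `|det ∩ gt| / min(|det|, |gt|)`
#'   (default 0.25).
#' @param avg_cells_per_image assumed total cells per image, used later for
#'   the estimated negative count (default 1270).
#' @return A one-row confusion-counts tibble: `TP`, `FN`, `FP`, `n_gt`,
#'   `n_images` (= 1), `avg_cells_per_image`.
#' @export
match_objects <- function(detections, gt_objects, overlap_threshold = 0.25,
                          avg_cells_per_image = 1270) {
  det_lab <- attr(detections, "labels")
  gt_lab <- attr(gt_objects, "labels")
  if (is.null(det_lab) || is.null(gt_lab)) {
    stop("both object tables must carry their label-matrix attribute")
  }
  if (!all(dim(det_lab) == dim(gt_lab))) {
    stop("detection and ground-truth label matrices differ in size")
  }
  n_gt <- nrow(gt_objects)
  n_det <- nrow(detections)
  TP <- 0L
  if (n_det > 0L && n_gt > 0L) {
    keep_det <- det_lab
    keep_det[!(det_lab %in% detections$object_id)] <- 0L
    both <- keep_det > 0L & gt_lab > 0L
    if (any(both)) {
      pairs <- tibble::tibble(det = keep_det[both], gt = gt_lab[both])
      ov <- dplyr::count(pairs, .data$det, .data$gt, name = "overlap")
      det_area <- detections$area_px[match(ov$det, detections$object_id)]
      gt_area <- gt_objects$area_px[match(ov$gt, gt_objects$object_id)]
      ov$frac <- ov$overlap / pmin(det_area, gt_area)
      ov <- ov[ov$frac >= overlap_threshold, ]
      ov <- ov[order(-ov$overlap, ov$det, ov$gt), ]
      used_det <- integer(0); used_gt <- integer(0)
      for (k in seq_len(nrow(ov))) {
        if (ov$det[k] %in% used_det || ov$gt[k] %in% used_gt) next
        used_det <- c(used_det, ov$det[k])
        used_gt <- c(used_gt, ov$gt[k])
        TP <- TP + 1L
      }
    }
  }
  confusion_counts(TP = TP, FN = n_gt - TP, FP = n_det - TP, n_gt = n_gt,
                   n_images = 1L, avg_cells_per_image = avg_cells_per_image)
}

#' Construct a confusion-counts row
#'
#' @param TP,FN,FP object-level true positives, false negatives, false
#'   positives.
#' @param n_gt number of ground-truth CTCs (`TP + FN`).
#' @param n_images number of images the counts cover.
#' @param avg_cells_per_image assumed average total cells per image, used
#'   to estimate the negative count (default 1270).
#' @return A one-row tibble.
#' @export
confusion_counts <- function(TP, FN, FP, n_gt = TP + FN, n_images = 1L,
                             avg_cells_per_image = 1270) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TP + FN == n_gt)
  tibble::tibble(TP = as.integer(TP), FN = as.integer(FN),
                 FP = as.integer(FP), n_gt = as.integer(n_gt),
                 n_images = as.integer(n_images),
                 avg_cells_per_image = avg_cells_per_image)
}

#' Aggregate per-image confusion counts
#'
#' Field-wise sums; `n_images` becomes the number of aggregated entries
#' (their `n_images` summed).
#'
#' @param counts a confusion-counts tibble (any number of rows).
#' @return A one-row confusion-counts tibble.
#' @export
aggregate_counts <- function(counts) {
  if (nrow(counts) == 0L) {
    return(confusion_counts(0L, 0L, 0L, n_images = 0L))
  }
  avg <- unique(counts$avg_cells_per_image)
  if (length(avg) > 1L) {
    stop("cannot aggregate counts with differing avg_cells_per_image")
  }
  confusion_counts(
    TP = sum(counts$TP), FN = sum(counts$FN), FP = sum(counts$FP),
    n_gt = sum(counts$n_gt), n_images = sum(counts$n_images),
    avg_cells_per_image = avg
  )
}

#' Detection metrics from object-level confusion counts
#'
#' Sensitivity and FN rate are exact: `100*TP/(TP+FN)` and
#' `100*FN/(TP+FN)`. Because the non-CTC cells in an image are not
#' individually enumerated, specificity and accuracy are estimated against
#' an assumed total object count `N = n_images * avg_cells_per_image`:
#' `TN_est = N - n_gt - FP`, estimated FP rate `100*FP/N`, estimated
#' specificity `100*TN_est/(TN_est + FP)`, estimated accuracy
#' `100*(TP + TN_est)/N`. Percentages are reported truncated to 2 decimals
#' (4 for the estimated FP rate), the convention of the published benchmark
#' figures this package reproduces.
#'
#' @param counts a one-row confusion-counts tibble (aggregate first if
#'   needed) with `n_gt > 0` and `n_images > 0`.
#' @param digits decimal places for percentage rounding (default 2).
#' @return A one-row tibble: `sensitivity_pct`, `fn_rate_pct`,
#'   `est_fp_rate`, `est_specificity_pct`, `est_accuracy_pct`, followed by
#'   the input counts.
#' @export
compute_metrics <- function(counts, digits = 2) {
  stopifnot(nrow(counts) == 1L)
  if (counts$n_gt <= 0L) {
    stop("sensitivity is undefined without ground-truth objects (n_gt = 0)")
  }
  if (counts$n_images <= 0L) stop("n_images must be positive")
  TP <- counts$TP; FN <- counts$FN; FP <- counts$FP
  N <- counts$n_images * counts$avg_cells_per_image
  TN <- N - counts$n_gt - FP
  dplyr::bind_cols(
    tibble::tibble(
      sensitivity_pct = trunc_decimals(100 * TP / (TP + FN), digits),
      fn_rate_pct = trunc_decimals(100 * FN / (TP + FN), digits),
      est_fp_rate = trunc_decimals(100 * FP / N, digits + 2),
      est_specificity_pct = trunc_decimals(100 * TN / (TN + FP), digits),
      est_accuracy_pct = trunc_decimals(100 * (TP + TN) / N, digits)
    ),
    counts
  )
}

#' Evaluate a trained model over a manifest
#'
#' Runs detection on every manifest entry (optionally restricted to one
#' split), matches detections against the ground-truth masks, aggregates
#' the counts, and computes the metrics report.
#'
#' @param manifest a manifest tibble (`image`, `mask`, `split`), as from
#'   [read_manifest()].
#' @param model a `ctc_boost`.
#' @param split evaluate only entries with this split tag (`NULL` = all).
#' @param opening_radius,min_area,score_threshold passed to [detect_ctc()].
#' @param overlap_threshold,avg_cells_per_image passed to [match_objects()].
#' @param out_dir if non-`NULL`, writes `per_image_counts.csv`,
#'   `detections.csv` and `metrics.json` there.
#' @return A list of class `ctc_eval`: `metrics` (one-row tibble),
#'   `per_image` (tibble of per-image counts), `detections` (tibble).
#' @export
evaluate_dataset <- function(manifest, model, split = "test",
                             opening_radius = 2, min_area = 100,
                             score_threshold = NULL,
                             overlap_threshold = 0.25,
                             avg_cells_per_image = 1270,
                             out_dir = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  if (nrow(manifest) == 0L) stop("no manifest entries to evaluate")
  missing_mask <- is.na(manifest$mask) | manifest$mask == ""
  if (any(missing_mask)) {
    stop("manifest entries without masks cannot be evaluated: ",
         paste(basename(manifest$image[missing_mask]), collapse = ", "))
  }
  res <- purrr::map(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$image[i])
    gt <- read_mask(manifest$mask[i], img$height, img$width)
    det <- detect_ctc(img, model, opening_radius = opening_radius,
                      min_area = min_area,
                      score_threshold = score_threshold)
    gt_obj <- label_components(gt, image_id = img$id)
    cc <- match_objects(det, gt_obj, overlap_threshold = overlap_threshold,
                        avg_cells_per_image = avg_cells_per_image)
    list(counts = dplyr::bind_cols(tibble::tibble(image = img$id), cc),
         detections = tibble::as_tibble(det))
  })
  per_image <- dplyr::bind_rows(purrr::map(res, "counts"))
  detections <- dplyr::bind_rows(purrr::map(res, "detections"))
  agg <- aggregate_counts(per_image[-1])
  metrics <- compute_metrics(agg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_image, file.path(out_dir, "per_image_counts.csv"))
    if (nrow(detections)) {
      write_detections(detections, file.path(out_dir, "detections.csv"))
    }
    jsonlite::write_json(as.list(metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(metrics = metrics, per_image = per_image,
                 detections = detections),
            class = "ctc_eval")
}

#' @export
print.ctc_eval <- function(x, ...) {
  cat(sprintf(
    "<ctc_eval> %d images: sensitivity %.2f%%, est. specificity %.2f%%, FP %d\n",
    x$metrics$n_images, x$metrics$sensitivity_pct,
    x$metrics$est_specificity_pct, x$metrics$FP))
  invisible(x)
}

#' @rdname evaluate_dataset
#' @param x a `ctc_eval` object.
#' @param ... unused.
#' @export
tidy.ctc_eval <- function(x, ...) x$per_image

#' @rdname evaluate_dataset
#' @export
glance.ctc_eval <- function(x, ...) x$metrics
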