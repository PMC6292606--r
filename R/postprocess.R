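# Euclidean disk structuring element: offsets with d_row^2 + d_col^2 <= r^2
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- seq(-r, r)
  k <- outer(d, d, function(a, b) as.numeric(a^2 + b^2 <= r^2))
  k
}

# EBImage replicates the border, i.e. treats out-of-image pixels as
# whatever the edge holds; blob cleaning wants out-of-image = background,
# so pad with background before the call and crop after.
morph_padded <- function(mask, radius, op) {
  H <- nrow(mask); W <- ncol(mask); r <- as.integer(radius)
  padded <- matrix(0, H + 2L * r, W + 2L * r)
  padded[(r + 1L):(r + H), (r + 1L):(r + W)] <- as.numeric(mask)
  res <- as.numeric(op(padded, disk_kernel(radius))) > 0
  matrix(res, H + 2L * r, W + 2L * r)[(r + 1L):(r + H), (r + 1L):(r + W)]
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  morph_padded(mask, radius, EBImage::dilate)
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  morph_padded(mask, radius, EBImage::erode)
}

#' Morphological opening of a detection mask
#'
#' Binary opening (erosion then dilation) with a discrete Euclidean disk of
#' the given radius; removes pixel groups smaller than the disk while
#' leaving cell-scale regions intact. Radius 0 is the identity.
#'
#' @param mask logical matrix of CTC-classified pixels.
#' @param radius structuring-element radius in pixels (default 2).
#' @return Logical matrix.
#' @export
morphological_clean <- function(mask, radius = 2) {
  stopifnot(radius >= 0)
  if (radius == 0) return(mask)
  dilate_mask(erode_mask(mask, radius), radius)
}

#' Label connected pixel groups as candidate objects
#'
#' 8-connectivity connected components, numbered 1..K in raster-scan order
#' of each component's first pixel. Centroids and bounding boxes use the
#' on-disk convention: (row, col) 0-based, boxes half-open `[min, max)`.
#'
#' @param mask logical matrix.
#' @param image_id identifier recorded with each object.
#' @return A tibble of class `ctc_objects` with columns `image_id`,
#'   `object_id`, `centroid_row`, `centroid_col`, `area_px`,
#'   `bbox_min_row`, `bbox_min_col`, `bbox_max_row`, `bbox_max_col`.
#'   The integer label matrix is attached as attribute `"labels"`.
#' @export
label_components <- function(mask, image_id = "image") {
  lab <- label_components_cpp(mask)
  K <- max(lab)
  if (K == 0L) {
    out <- tibble::tibble(
      image_id = character(), object_id = integer(),
      centroid_row = numeric(), centroid_col = numeric(),
      area_px = integer(), bbox_min_row = integer(), bbox_min_col = integer(),
      bbox_max_row = integer(), bbox_max_col = integer()
    )
  } else {
    idx <- which(lab > 0)
    lb <- lab[idx]
    r0 <- ((idx - 1L) %% nrow(lab))        # 0-based row
    c0 <- ((idx - 1L) %/% nrow(lab))       # 0-based col
    area <- tabulate(lb, K)
    out <- tibble::tibble(
      image_id = as.character(image_id),
      object_id = seq_len(K),
      centroid_row = as.vector(tapply(r0, lb, mean)),
      centroid_col = as.vector(tapply(c0, lb, mean)),
      area_px = as.integer(area),
      bbox_min_row = as.integer(tapply(r0, lb, min)),
      bbox_min_col = as.integer(tapply(c0, lb, min)),
      bbox_max_row = as.integer(tapply(r0, lb, max)) + 1L,
      bbox_max_col = as.integer(tapply(c0, lb, max)) + 1L
    )
  }
  attr(out, "labels") <- lab
  class(out) <- c("ctc_objects", class(out))
  out
}

#' Validate candidate objects by area
#'
#' An object counts as a CTC only if its pixel area strictly exceeds
#' `min_area` (default 100 px), discarding blood-cell-sized blobs.
#'
#' @param objects a `ctc_objects` tibble from [label_components()].
#' @param min_area area threshold in pixels (strict greater-than).
#' @return The validated subset, label matrix attribute preserved.
#' @export
validate_objects <- function(objects, min_area = 100) {
  stopifnot(min_area >= 0)
  keep <- objects$area_px > min_area
  out <- objects[keep, ]
  attr(out, "labels") <- attr(objects, "labels")
  class(out) <- unique(c("ctc_objects", class(out)))
  out
}

#' Detect CTC objects in a darkfield image
#'
#' Full prediction path: per-pixel ensemble scores, score thresholding,
#' morphological opening, component labeling, and area validation.
#'
#' @param image a [ctc_image].
#' @param model a `ctc_boost`.
#' @param opening_radius disk radius for [morphological_clean()].
#' @param min_area area-validation threshold (strict).
#' @param score_threshold decision threshold on the ensemble score;
#'   defaults to the model's.
#' @return A validated `ctc_objects` tibble; the post-opening pixel mask is
#'   attached as attribute `"mask"`.
#' @export
detect_ctc <- function(image, model, opening_radius = 2, min_area = 100,
                       score_threshold = NULL) {
  thr <- score_threshold %||% model$score_threshold
  scores <- predict_scores(image, model)
  mask <- threshold_scores(scores, thr)
  mask <- morphological_clean(mask, opening_radius)
  obj <- label_components(mask, image_id = image$id)
  out <- validate_objects(obj, min_area)
  attr(out, "mask") <- mask
  out
}
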