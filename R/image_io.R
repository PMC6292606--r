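#' Darkfield image container
#'
#' A `ctc_image` wraps an H x W x 3 array of 8-bit intensities (stored as
#' numerics in 0--255) together with an identifier, usually the source
#' filename stem. It is the raw input of the detection pipeline.
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 255\], or an
#'   H x W matrix (replicated to three identical channels).
#' @param id character identifier.
#' @return An object of class `ctc_image` with elements `pixels`, `height`,
#'   `width` and `id`.
#' @export
ctc_image <- function(pixels, id = "image") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 4L || dim(pixels)[2] < 4L) {
    stop("image must be at least 4x4 (quarter-resolution level would be empty)")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         id = as.character(id)),
    class = "ctc_image"
  )
}

#' @export
print.ctc_image <- function(x, ...) {
  cat(sprintf("<ctc_image> %s: %d x %d, intensities [%g, %g]\n",
              x$id, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ctc_image <- function(x) dim(x$pixels)

# decode a PNG/TIFF file into a numeric array in [0, 1]
read_raster_01 <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  px
}

#' Read a darkfield image
#'
#' Decodes a PNG or TIFF file into a [ctc_image]. Grayscale files are
#' replicated to three channels, an alpha channel is dropped with a warning,
#' and images with more than 8 bits per channel are linearly rescaled to
#' 0--255 by their min/max (with a warning), since all histogram logic in
#' the pipeline assumes 256 intensity levels.
#'
#' @param path path to a PNG or TIFF file.
#' @return A [ctc_image]; the `id` is the filename without extension.
#' @export
read_image <- function(path) {
  px <- read_raster_01(path)
  id <- tools::file_path_sans_ext(basename(path))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) {
    warning("alpha channel dropped: ", path)
    px <- px[, , 1:3, drop = FALSE]
  }
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), c(dim(px), 3L))
  }
  v <- px * 255
  if (max(v) > 255 + 1e-9) stop("unexpected intensity range in ", path)
  # detect >8-bit data: values that are not multiples of 1/255
  if (any(abs(v - round(v)) > 1e-6)) {
    warning("rescaling >8-bit intensities to 0-255: ", path)
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) * 255 else v * 0
  }
  ctc_image(round(v), id = id)
}

#' Write a darkfield image
#'
#' @param image a [ctc_image].
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

#' Read a binary ground-truth mask
#'
#' A mask marks tumor-cell pixels: any value greater than zero is foreground.
#' Dimensions must match the paired darkfield image.
#'
#' @param path path to a PNG or TIFF mask file.
#' @param height,width expected dimensions; checked when given.
#' @return A logical height x width matrix with attribute `id`.
#' @export
read_mask <- function(path, height = NULL, width = NULL) {
  px <- read_raster_01(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (!is.null(height) && !is.null(width) &&
      (nrow(px) != height || ncol(px) != width)) {
    stop(sprintf("mask %s is %dx%d, expected %dx%d",
                 path, nrow(px), ncol(px), height, width))
  }
  m <- px > 0
  attr(m, "id") <- tools::file_path_sans_ext(basename(path))
  m
}

#' Write a binary mask
#'
#' @param mask logical matrix.
#' @param path output path (.png or .tif/.tiff); foreground is written as 255.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  px <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest pairs darkfield images with their ground-truth masks and a
#' train/test split tag. Columns: `image`, `mask` (may be empty), `split`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path path to a manifest CSV.
#' @return A tibble with columns `image`, `mask`, `split`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("image", "mask", "split")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns image, mask, split")
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p,
           file.path(base, p))
  }
  m <- dplyr::mutate(m, image = resolve(.data$image),
                     mask = resolve(.data$mask))
  if (anyDuplicated(m$image)) stop("duplicate image paths in manifest")
  m[need]
}

#' Write detected objects to CSV
#'
#' Coordinates follow the on-disk convention used throughout: (row, col),
#' 0-based, row 0 at the top, bounding boxes half-open `[min, max)`.
#'
#' @param objects a detections tibble as returned by [label_components()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(objects, path) {
  cols <- c("image_id", "object_id", "centroid_row", "centroid_col",
            "area_px", "bbox_min_row", "bbox_min_col",
            "bbox_max_row", "bbox_max_col")
  out <- tibble::as_tibble(objects)[, cols]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a detections CSV written by [write_detections()]
#'
#' @param path CSV path.
#' @return A tibble of detected objects.
#' @export
read_detections <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    image_id = "c", object_id = "i", centroid_row = "d", centroid_col = "d",
    area_px = "i", bbox_min_row = "i", bbox_min_col = "i",
    bbox_max_row = "i", bbox_max_col = "i"
  ))
}
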