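#' Convert an 8-bit RGB image to CIE L*u*v*
#'
#' Uses sRGB primaries and the D65 white point. L* is in \[0, 100\]; u* and
#' v* are 0 on the achromatic axis. L*u*v* is approximately perceptually
#' uniform and separates luminance from chromaticity, which keeps the color
#' channels meaningful under the colored glare of darkfield lighting.
#'
#' @param image a [ctc_image].
#' @return A list of three numeric matrices `L`, `u`, `v`.
#' @export
rgb_to_luv <- function(image) {
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  flat <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                as.vector(px[, , 3])) / 255
  luv <- grDevices::convertColor(flat, from = "sRGB", to = "Luv")
  list(L = matrix(luv[, 1], H, W),
       u = matrix(luv[, 2], H, W),
       v = matrix(luv[, 3], H, W))
}

# shift a matrix by (dr, dc) with border replication
shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

#' Sobel gradient magnitude and quantized orientation
#'
#' Applies the 3x3 Sobel operator with replicated borders. The orientation
#' is quantized to 8 codes, code k for the angle nearest 45k degrees
#' (ties toward the smaller code), with the angle measured counterclockwise
#' from the +column axis with up as positive (`atan2(-g_row, g_col)`).
#' Zero-gradient pixels get code 0.
#'
#' @param gray numeric matrix, at least 3x3.
#' @return A list `mag` (numeric matrix, >= 0) and `orient` (integer matrix,
#'   codes 0--7).
#' @export
gradient <- function(gray) {
  if (nrow(gray) < 3L || ncol(gray) < 3L) stop("grid must be at least 3x3")
  s <- function(dr, dc) shift_replicate(gray, dr, dc)
  # g_col: response to the x-derivative kernel [-1 0 1; -2 0 2; -1 0 1]
  g_col <- (s(-1L, 1L) + 2 * s(0L, 1L) + s(1L, 1L)) -
           (s(-1L, -1L) + 2 * s(0L, -1L) + s(1L, -1L))
  g_row <- (s(1L, -1L) + 2 * s(1L, 0L) + s(1L, 1L)) -
           (s(-1L, -1L) + 2 * s(-1L, 0L) + s(-1L, 1L))
  mag <- sqrt(g_col^2 + g_row^2)
  ang <- atan2(-g_row, g_col) * 180 / pi
  ang <- ang %% 360
  code <- ceiling(ang / 45 - 0.5) %% 8   # nearest center, ties to smaller
  code[mag == 0] <- 0L
  list(mag = mag, orient = matrix(as.integer(code), nrow(gray), ncol(gray)))
}

#' Downsample a grid by 2x2 mean pooling
#'
#' Non-overlapping 2x2 block means (the average-pooling step of the
#' multi-resolution pyramid); a trailing odd row/column is dropped.
#'
#' @param grid numeric matrix with both dimensions >= 2.
#' @return Numeric matrix of dimensions `(floor(H/2), floor(W/2))`.
#' @export
downsample <- function(grid) {
  H <- nrow(grid); W <- ncol(grid)
  if (H < 2L || W < 2L) stop("grid must be at least 2x2 to downsample")
  h <- H %/% 2L; w <- W %/% 2L
  g <- grid[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  (g[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE] +
   g[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE] +
   g[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE] +
   g[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE]) / 4
}

#' Compute the 15-channel multi-resolution feature stack
#'
#' Five channels (L*, u*, v*, gradient magnitude of L*, quantized gradient
#' orientation of L*) at three resolutions: full, half, and quarter. The
#' L*u*v* grids are average-pooled to build the coarse levels, and the
#' gradient is recomputed at each level from the pooled L* grid rather than
#' pooled from the fine level.
#'
#' @param image a [ctc_image] (illumination-corrected upstream).
#' @return An object of class `ctc_channels`: a list of 3 levels, each with
#'   elements `L`, `u`, `v`, `mag`, `orient`, plus the scale factors.
#' @export
compute_channel_stack <- function(image) {
  luv <- rgb_to_luv(image)
  levels <- vector("list", 3L)
  cur <- luv
  for (lev in 1:3) {
    if (lev > 1L) {
      cur <- list(L = downsample(cur$L), u = downsample(cur$u),
                  v = downsample(cur$v))
    }
    g <- gradient(cur$L)
    levels[[lev]] <- list(L = cur$L, u = cur$u, v = cur$v,
                          mag = g$mag, orient = g$orient)
  }
  structure(list(levels = levels, scales = c(1L, 2L, 4L),
                 height = image$height, width = image$width,
                 id = image$id),
            class = "ctc_channels")
}

#' @export
print.ctc_channels <- function(x, ...) {
  cat(sprintf("<ctc_channels> %s: 15 channels, levels %s\n", x$id,
              paste(vapply(x$levels, function(l)
                paste(dim(l$L), collapse = "x"), ""), collapse = ", ")))
  invisible(x)
}

#' Default two-ring neighborhood pattern
#'
#' Sixteen sampling offsets covering the expected tumor-cell footprint:
#' eight at radius `round(diameter/4)` and eight at radius
#' `round(diameter/2)`, spaced 45 degrees, rounded to integer
#' displacements (duplicates removed). The implicit first sample is always
#' the anchor pixel itself.
#'
#' @param cell_diameter_px expected tumor-cell diameter in pixels (>= 4).
#' @return An object of class `ctc_pattern` with an `offsets` matrix
#'   (columns `d_row`, `d_col`) and the generating diameter.
#' @export
default_pattern <- function(cell_diameter_px = 40) {
  stopifnot(cell_diameter_px >= 4)
  radii <- c(round(cell_diameter_px / 4), round(cell_diameter_px / 2))
  ang <- (0:7) * pi / 4
  off <- do.call(rbind, lapply(radii, function(r) {
    cbind(d_row = round(r * sin(ang)), d_col = round(r * cos(ang)))
  }))
  off <- unique(off)
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  ctc_pattern(off, diameter_px = cell_diameter_px)
}

#' Construct a neighborhood pattern from explicit offsets
#'
#' @param offsets integer matrix with columns `d_row`, `d_col`; must not
#'   contain `(0, 0)` (the anchor is always sampled first) or duplicates.
#' @param diameter_px the nominal cell diameter the pattern was built for.
#' @return An object of class `ctc_pattern`.
#' @export
ctc_pattern <- function(offsets, diameter_px = NA_real_) {
  offsets <- matrix(as.integer(offsets), ncol = 2,
                    dimnames = list(NULL, c("d_row", "d_col")))
  if (anyDuplicated(offsets)) stop("duplicate offsets in pattern")
  if (any(offsets[, 1] == 0 & offsets[, 2] == 0)) {
    stop("(0,0) is implicit and must not appear in offsets")
  }
  structure(list(offsets = offsets, diameter_px = diameter_px,
                 n_samples = nrow(offsets) + 1L),
            class = "ctc_pattern")
}

# sample coordinates of one pattern sample at one pyramid level:
# 0-based full-res anchor + offset, divided by the scale with floor,
# clamped into the level grid; returns 1-based (row, col) index vectors
level_sample_coords <- function(anchor_r, anchor_c, d_row, d_col, scale,
                                level_h, level_w) {
  r <- ((anchor_r - 1L) + d_row) %/% scale
  c <- ((anchor_c - 1L) + d_col) %/% scale
  list(r = pmin(pmax(r, 0L), level_h - 1L) + 1L,
       c = pmin(pmax(c, 0L), level_w - 1L) + 1L)
}

channel_names <- c("L", "u", "v", "mag", "orient")

#' Map feature-vector positions to channel stack coordinates
#'
#' The feature layout is deterministic: level-major, channel-minor
#' (L, u, v, gradient magnitude, orientation), and within each channel the
#' anchor first followed by the pattern offsets in order.
#'
#' @param pattern a [ctc_pattern].
#' @return A tibble with one row per feature: `feature_index`, `level`
#'   (1--3), `channel` (name), `sample` (1 = anchor), `d_row`, `d_col`.
#' @export
feature_index_map <- function(pattern) {
  ns <- pattern$n_samples
  off <- rbind(c(0L, 0L), pattern$offsets)
  tibble::tibble(
    feature_index = seq_len(15L * ns),
    level = rep(1:3, each = 5L * ns),
    channel = rep(rep(channel_names, each = ns), times = 3L),
    sample = rep(seq_len(ns), times = 15L),
    d_row = rep(off[, 1], times = 15L),
    d_col = rep(off[, 2], times = 15L)
  )
}

#' Extract per-pixel feature vectors
#'
#' For each anchor, samples every channel of the stack at the anchor and at
#' each pattern offset, mapping full-resolution coordinates into each level
#' by integer division (floor) and clamping out-of-bounds samples to the
#' nearest valid coordinate.
#'
#' @param stack a `ctc_channels` object from [compute_channel_stack()].
#' @param anchors integer matrix with columns (row, col), 1-based,
#'   at full resolution.
#' @param pattern a [ctc_pattern].
#' @return A numeric matrix, one row per anchor, `15 * (1 + n_offsets)`
#'   columns in the layout of [feature_index_map()].
#' @export
extract_feature_matrix <- function(stack, anchors, pattern) {
  anchors <- matrix(as.integer(anchors), ncol = 2)
  stopifnot(all(anchors[, 1] >= 1L), all(anchors[, 1] <= stack$height),
            all(anchors[, 2] >= 1L), all(anchors[, 2] <= stack$width))
  ns <- pattern$n_samples
  off <- rbind(c(0L, 0L), pattern$offsets)
  out <- matrix(0, nrow(anchors), 15L * ns)
  col0 <- 0L
  for (lev in 1:3) {
    s <- stack$scales[lev]
    lv <- stack$levels[[lev]]
    lh <- nrow(lv$L); lw <- ncol(lv$L)
    # linear indices per sample point, shared across the 5 channels
    idx <- vector("list", ns)
    for (k in seq_len(ns)) {
      co <- level_sample_coords(anchors[, 1], anchors[, 2],
                                off[k, 1], off[k, 2], s, lh, lw)
      idx[[k]] <- (co$c - 1L) * lh + co$r
    }
    for (ch in channel_names) {
      g <- lv[[ch]]
      for (k in seq_len(ns)) {
        out[, col0 + k] <- g[idx[[k]]]
      }
      col0 <- col0 + ns
    }
  }
  out
}

#' Extract the feature vector of a single pixel
#'
#' @inheritParams extract_feature_matrix
#' @param anchor `(row, col)`, 1-based, at full resolution.
#' @return A numeric vector of length `15 * (1 + n_offsets)`.
#' @export
extract_feature_vector <- function(stack, anchor, pattern) {
  as.vector(extract_feature_matrix(stack, matrix(anchor, 1), pattern))
}
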