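#' Illumination-correction configuration
#'
#' Darkfield images have a near-black background, so the dominant histogram
#' bin of any window should sit at intensity 0. Reflective artifacts above
#' the focal plane add smooth bright halos that shift the local background
#' upward. The correction estimates the background level per window as the
#' histogram mode, interpolates the per-window modes into a full-resolution
#' illumination mask, and subtracts it.
#'
#' @param wsize window side length in pixels. The default 64 px is small
#'   relative to artifact halos but large relative to single blood cells, so
#'   the window mode stays at the background level.
#' @param n_bins histogram bin count; fixed at 256 for 8-bit data.
#' @return A list of class `illum_config`.
#' @export
illum_config <- function(wsize = 64, n_bins = 256) {
  stopifnot(wsize >= 8, n_bins == 256)
  structure(list(wsize = as.integer(wsize), n_bins = 256L),
            class = "illum_config")
}

#' Histogram mode of an image window
#'
#' Returns the intensity level of the highest 256-bin histogram bin of the
#' `wsize` x `wsize` window whose top-left corner is at `origin`. Windows
#' are clipped to the image boundary; ties break toward the lowest
#' intensity (biasing toward true black background).
#'
#' @param channel numeric matrix with values in \[0, 255\].
#' @param origin `(row, col)` of the window's top-left corner, 1-based.
#' @param wsize window side length.
#' @return The modal intensity level (0--255).
#' @export
window_mode <- function(channel, origin, wsize) {
  r0 <- origin[1]; c0 <- origin[2]
  if (r0 < 1L || c0 < 1L || r0 > nrow(channel) || c0 > ncol(channel)) {
    stop("window is empty or outside the image")
  }
  rows <- r0:min(r0 + wsize - 1L, nrow(channel))
  cols <- c0:min(c0 + wsize - 1L, ncol(channel))
  v <- floor(channel[rows, cols])
  h <- tabulate(v + 1L, nbins = 256L)
  which.max(h) - 1L  # which.max takes the first maximum = lowest intensity
}

# window origins along one axis: stride wsize, last window clipped to border
window_starts <- function(n, wsize) {
  s <- seq.int(1L, n, by = wsize)
  s[s > n - wsize + 1L] <- n - wsize + 1L
  unique(s)
}

#' Estimate the illumination mask of one channel
#'
#' Computes the window histogram mode on a regular grid (stride = `wsize`,
#' last window clipped to the border), anchors each mode at its window
#' center, and bilinearly interpolates between anchors; outside the anchor
#' hull values clamp to the nearest anchor.
#'
#' @param channel numeric matrix with values in \[0, 255\].
#' @param config an [illum_config()].
#' @return Numeric matrix of the same size: the estimated per-pixel
#'   background level.
#' @export
build_illumination_mask <- function(channel, config = illum_config()) {
  H <- nrow(channel); W <- ncol(channel); ws <- config$wsize
  if (ws > min(H, W)) stop("wsize exceeds image dimensions")
  rs <- window_starts(H, ws)
  cs <- window_starts(W, ws)
  g <- matrix(0, length(rs), length(cs))
  for (i in seq_along(rs)) {
    for (j in seq_along(cs)) {
      g[i, j] <- window_mode(channel, c(rs[i], cs[j]), ws)
    }
  }
  # anchor coordinates: window centers
  ar <- rs + (ws - 1) / 2
  ac <- cs + (ws - 1) / 2
  interp_axis <- function(anchors, values_mat, xout) {
    # interpolate each column of values_mat (rows indexed by `anchors`)
    if (length(anchors) == 1L) {
      return(matrix(rep(values_mat, each = length(xout)),
                    length(xout), ncol(values_mat)))
    }
    apply(values_mat, 2L, function(v) {
      stats::approx(anchors, v, xout = xout, rule = 2)$y
    })
  }
  tmp <- interp_axis(ar, g, seq_len(H))                 # H x length(cs)
  t(interp_axis(ac, t(tmp), seq_len(W)))                # H x W
}

#' Correct illumination of a darkfield image
#'
#' Subtracts the per-channel illumination mask from each color channel and
#' clamps at 0, shifting the local background histogram mode back to black.
#'
#' @param image a [ctc_image].
#' @param config an [illum_config()].
#' @param return_mask if `TRUE`, also return the three illumination masks.
#' @return The corrected [ctc_image]; with `return_mask = TRUE`, a list
#'   `list(image, mask)` where `mask` is an H x W x 3 array.
#' @export
correct_illumination <- function(image, config = illum_config(),
                                 return_mask = FALSE) {
  px <- image$pixels
  out <- px
  msk <- array(0, dim(px))
  for (ch in 1:3) {
    m <- build_illumination_mask(px[, , ch], config)
    msk[, , ch] <- m
    out[, , ch] <- pmin(pmax(px[, , ch] - m, 0), 255)
  }
  corrected <- ctc_image(out, id = image$id)
  if (return_mask) list(image = corrected, mask = msk) else corrected
}
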