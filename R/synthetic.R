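#' Parameters of a synthetic darkfield scene
#'
#' The generator emulates the statistical structure of darkfield images of
#' unstained blood spiked with tumor cells: a near-black noisy background,
#' many small bright blood cells (ring-like profiles, cool tint, density
#' scaled from about 1270 cells per full 2048x1088 camera frame), a few
#' much larger tumor cells with bright irregular rims, speckled interiors
#' and a warm tint, and optional smooth bright halos from out-of-focus
#' reflective artifacts. The ground-truth mask is true exactly on
#' tumor-cell pixels.
#'
#' @param height,width canvas size in pixels (default 512).
#' @param n_tumor tumor cells per scene; a length-2 vector is a uniform
#'   integer range sampled per scene (default `c(3, 5)`).
#' @param tumor_diameter_px mean and sd of tumor-cell diameter (default
#'   `c(40, 3)`, i.e. 18--23 um cells at ~0.55 um/px).
#' @param tumor_texture_contrast sd of the interior speckle texture in
#'   intensity levels (default 35); this variance excess over blood cells
#'   is what makes pixel classification learnable.
#' @param n_blood blood cells per scene; default `NULL` scales 1270 cells
#'   per 2048x1088 frame by canvas area.
#' @param blood_diameter_px mean and sd of blood-cell diameter (default
#'   `c(13, 1.5)`, ~7 um erythrocytes).
#' @param artifact_halos number of bright artifact halos (default 1).
#' @param background_level mean background intensity, < 20 (default 8).
#' @param noise_sd sd of the additive background noise (default 3).
#' @param seed RNG seed for full reproducibility.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(height = 512, width = 512, n_tumor = c(3, 5),
                         tumor_diameter_px = c(40, 3),
                         tumor_texture_contrast = 35,
                         n_blood = NULL, blood_diameter_px = c(13, 1.5),
                         artifact_halos = 1, background_level = 8,
                         noise_sd = 3, seed = 1) {
  stopifnot(background_level < 20, background_level >= 0,
            tumor_diameter_px[1] > blood_diameter_px[1])
  if (is.null(n_blood)) {
    n_blood <- round(1270 * height * width / (2048 * 1088))
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_tumor = as.integer(n_tumor),
    tumor_diameter_px = tumor_diameter_px,
    tumor_texture_contrast = tumor_texture_contrast,
    n_blood = as.integer(n_blood), blood_diameter_px = blood_diameter_px,
    artifact_halos = as.integer(artifact_halos),
    background_level = background_level, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "scene_params")
}

#' Cell-line presets for the scene generator
#'
#' Tumor diameters of the three benchmark cell lines (Hs 578T 23.15 um,
#' MCF7 21.75 um, DLD-1 18.13 um) converted to pixels at a configurable
#' pixel pitch.
#'
#' @param line `"hs578t"`, `"mcf7"` or `"dld1"`.
#' @param um_per_px microscope pixel pitch (default 0.55 um/px).
#' @param ... further arguments to [scene_params()].
#' @return A `scene_params` object.
#' @export
scene_preset <- function(line = c("hs578t", "mcf7", "dld1"),
                         um_per_px = 0.55, ...) {
  line <- match.arg(line)
  um <- c(hs578t = 23.15, mcf7 = 21.75, dld1 = 18.13)[[line]]
  scene_params(tumor_diameter_px = c(um / um_per_px, 0.05 * um / um_per_px),
               ...)
}

# add a radially-profiled cell into the scene (modifies in the caller);
# returns the logical support mask of the cell within the canvas
render_cell <- function(canvas, cr, cc, radius_fun, intensity_fun, tint,
                        r_max) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  rr <- max(1L, floor(cr - r_max)):min(H, ceiling(cr + r_max))
  cc_ <- max(1L, floor(cc - r_max)):min(W, ceiling(cc + r_max))
  dr <- outer(rr - cr, rep(1, length(cc_)))
  dc <- outer(rep(1, length(rr)), cc_ - cc)
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  rb <- radius_fun(theta)
  inside <- rho <= rb
  val <- intensity_fun(rho, rb)
  val[!inside] <- 0
  for (ch in 1:3) {
    canvas[rr, cc_, ch] <- canvas[rr, cc_, ch] + val * tint[ch]
  }
  support <- matrix(FALSE, H, W)
  support[rr, cc_] <- inside
  list(canvas = canvas, support = support)
}

#' Generate one synthetic darkfield scene
#'
#' @param params a [scene_params()].
#' @return A list: `image` ([ctc_image]), `mask` (logical matrix, true on
#'   tumor pixels), `objects` (tibble of placed tumor cells with centers
#'   and radii, 1-based coordinates).
#' @export
generate_scene <- function(params) {
  p <- params
  withr::with_seed(p$seed, {
    H <- p$height; W <- p$width
    canvas <- array(rnorm(H * W * 3, p$background_level, p$noise_sd),
                    c(H, W, 3))
    # artifact halos: broad 2-D Gaussians of scattered glare
    if (p$artifact_halos > 0) {
      for (k in seq_len(p$artifact_halos)) {
        hc <- c(runif(1, 1, H), runif(1, 1, W))
        sig <- runif(1, 60, 100)
        amp <- runif(1, 25, 50)
        d2 <- outer((seq_len(H) - hc[1])^2, rep(1, W)) +
              outer(rep(1, H), (seq_len(W) - hc[2])^2)
        halo <- amp * exp(-d2 / (2 * sig^2))
        tintk <- c(1, 1, 0.95)
        for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] + halo * tintk[ch]
      }
    }
    n_tumor <- if (length(p$n_tumor) == 2L) {
      sample(p$n_tumor[1]:p$n_tumor[2], 1L)
    } else p$n_tumor[1]
    # place tumor cells, pairwise non-overlapping
    tumors <- list()
    mask <- matrix(FALSE, H, W)
    for (k in seq_len(n_tumor)) {
      R <- max(4, rnorm(1, p$tumor_diameter_px[1], p$tumor_diameter_px[2]) / 2)
      placed <- FALSE
      for (try in 1:200) {
        cr <- runif(1, 1.3 * R, H - 1.3 * R)
        cc <- runif(1, 1.3 * R, W - 1.3 * R)
        ok <- TRUE
        for (t in tumors) {
          if (sqrt((cr - t$row)^2 + (cc - t$col)^2) < 1.2 * (R + t$radius) + 4) {
            ok <- FALSE; break
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place ", n_tumor, " tumor cells without overlap; ",
             "lower the density or enlarge the canvas")
      }
      # irregular contour: low-order radial harmonics
      a <- runif(3, 0, 0.06); phi <- runif(3, 0, 2 * pi)
      radius_fun <- function(theta) {
        R * (1 + a[1] * cos(2 * theta + phi[1]) +
                 a[2] * cos(3 * theta + phi[2]) +
                 a[3] * cos(4 * theta + phi[3]))
      }
      intensity_fun <- function(rho, rb) {
        n <- length(rho)
        base <- 60 + 90 * exp(-((rho - 0.85 * rb) / (0.18 * rb))^2)
        speckle <- rnorm(n, 0, p$tumor_texture_contrast)
        pmax(base + speckle, 0)
      }
      res <- render_cell(canvas, cr, cc, radius_fun, intensity_fun,
                         tint = c(1, 0.85, 0.65), r_max = 1.25 * R)
      canvas <- res$canvas
      mask <- mask | res$support
      tumors[[k]] <- list(row = cr, col = cc, radius = R)
    }
    # blood cells: small bright rings, kept clear of tumor cells
    tumor_clear <- dilate_mask(mask, radius = 3)
    blood_placed <- 0L
    guard <- 0L
    while (blood_placed < p$n_blood && guard < 50L * p$n_blood) {
      guard <- guard + 1L
      Rb <- max(2.5, rnorm(1, p$blood_diameter_px[1], p$blood_diameter_px[2]) / 2)
      cr <- runif(1, Rb + 1, H - Rb - 1)
      cc <- runif(1, Rb + 1, W - Rb - 1)
      if (tumor_clear[round(cr), round(cc)]) next
      ok <- TRUE
      for (t in tumors) {
        if (sqrt((cr - t$row)^2 + (cc - t$col)^2) < 1.25 * t$radius + Rb + 2) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      intensity_fun <- function(rho, rb) {
        ring <- 125 * exp(-((rho - 0.75 * rb) / (0.35 * rb))^2) +
                35 * exp(-(rho / (0.5 * rb))^2)
        pmax(ring + rnorm(length(rho), 0, 5), 0)
      }
      res <- render_cell(canvas, cr, cc, function(theta) Rb + 0 * theta,
                         intensity_fun, tint = c(0.8, 0.9, 1), r_max = Rb + 1)
      canvas <- res$canvas
      blood_placed <- blood_placed + 1L
    }
    img <- ctc_image(round(pmin(pmax(canvas, 0), 255)), id = "synthetic")
    objects <- dplyr::bind_rows(purrr::map(tumors, tibble::as_tibble))
    list(image = img, mask = mask, objects = objects)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` image/mask PNG pairs (per-scene seeds derived as
#' `seed + i`) plus a `manifest.csv` with a deterministic train/test split
#' (first `train_frac` of the images are tagged `train`).
#'
#' @param n_images number of scenes.
#' @param params a [scene_params()]; its `seed` field is ignored in favor
#'   of `seed + i`.
#' @param out_dir output directory (created if needed).
#' @param seed base RNG seed.
#' @param train_frac fraction of images tagged `train` (default 0.7).
#' @return The manifest tibble (paths relative to `out_dir`), invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_images, params = scene_params(),
                             out_dir = tempfile("ctcdf_data_"), seed = 1,
                             train_frac = 0.7) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- round(train_frac * n_images)
  rows <- purrr::map(seq_len(n_images), function(i) {
    p <- params
    p$seed <- as.integer(seed + i)
    sc <- generate_scene(p)
    img_file <- sprintf("img_%03d.png", i)
    msk_file <- sprintf("mask_%03d.png", i)
    sc$image$id <- tools::file_path_sans_ext(img_file)
    write_image(sc$image, file.path(out_dir, img_file))
    write_mask(sc$mask, file.path(out_dir, msk_file))
    tibble::tibble(image = img_file, mask = msk_file,
                   split = if (i <= n_train) "train" else "test")
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  # return resolved paths so the result is usable directly
  manifest$image <- file.path(out_dir, manifest$image)
  manifest$mask <- file.path(out_dir, manifest$mask)
  attr(manifest, "dir") <- out_dir
  manifest
}
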