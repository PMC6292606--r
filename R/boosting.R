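#' Sample labeled training pixels from image/mask pairs
#'
#' Positives are drawn uniformly without replacement from mask-true pixels
#' (capped per image); negatives are drawn uniformly from pixels farther
#' than `margin` pixels from any mask-true pixel, excluding a blurred band
#' around cell borders where labels are unreliable. The negative count is
#' `neg_pos_ratio` times the positive count.
#'
#' @param images list of [ctc_image]s.
#' @param masks list of logical matrices paired with `images`.
#' @param neg_pos_ratio negatives drawn per positive (default 3).
#' @param max_pos_per_image cap on positives per image (default 2000).
#' @param margin exclusion distance (px) around mask-true pixels for
#'   negatives (default 5).
#' @param seed RNG seed; sampling is fully reproducible.
#' @return A tibble with columns `image` (index into `images`), `row`,
#'   `col` (1-based) and `label` (+1 CTC pixel, -1 non-CTC pixel).
#' @export
sample_training_pixels <- function(images, masks, neg_pos_ratio = 3,
                                   max_pos_per_image = 2000,
                                   margin = 5, seed = 1) {
  stopifnot(length(images) == length(masks))
  out <- withr::with_seed(seed, {
    rows <- purrr::map(seq_along(images), function(i) {
      msk <- masks[[i]]
      img <- images[[i]]
      if (nrow(msk) != img$height || ncol(msk) != img$width) {
        stop("mask/image dimension mismatch at entry ", i)
      }
      pos_idx <- which(msk)
      if (length(pos_idx) == 0L) {
        warning("mask has no true pixels; skipping image ", img$id)
        return(NULL)
      }
      n_pos <- min(length(pos_idx), max_pos_per_image)
      pos <- sample(pos_idx, n_pos)
      excl <- dilate_mask(msk, radius = margin)
      neg_idx <- which(!excl)
      n_neg <- min(length(neg_idx), round(neg_pos_ratio * n_pos))
      neg <- sample(neg_idx, n_neg)
      H <- nrow(msk)
      tibble::tibble(
        image = i,
        row = ((c(pos, neg) - 1L) %% H) + 1L,
        col = ((c(pos, neg) - 1L) %/% H) + 1L,
        label = rep(c(1, -1), c(n_pos, n_neg))
      )
    })
    dplyr::bind_rows(rows)
  })
  if (nrow(out) == 0L || !any(out$label == 1)) {
    stop("no positive pixels found in any mask")
  }
  out
}

#' Train a discrete AdaBoost ensemble of decision stumps
#'
#' Classical discrete AdaBoost: sample weights start uniform; each round
#' picks the (feature, threshold, polarity) stump minimizing the weighted
#' error over all features, with candidate thresholds at midpoints of
#' consecutive distinct sorted feature values; the stump weight is
#' `alpha = 0.5 * log((1 - eps) / eps)` with `eps` clamped to
#' `[1e-10, 1 - 1e-10]`; weights are multiplied by `exp(-alpha * y * h(x))`
#' and renormalized. Training stops early if no stump beats error 0.5.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels vector in `{-1, +1}`.
#' @param n_rounds maximum number of boosting rounds (default 200).
#' @param seed recorded in the model for provenance (training itself is
#'   deterministic).
#' @param feature_config list describing how `features` were built (pattern,
#'   illumination window size); stored so prediction can reproduce the
#'   feature space.
#' @param score_threshold decision threshold on the ensemble score
#'   (default 0; a pixel is CTC when the score strictly exceeds it).
#' @return An object of class `ctc_boost` with elements `stumps` (tibble:
#'   `round`, `feature_index`, `threshold`, `polarity`, `alpha`, `error`,
#'   `bound`), `n_rounds`, `seed`, `score_threshold`, `feature_config`.
#' @export
train_adaboost <- function(features, labels, n_rounds = 200, seed = 1,
                           feature_config = NULL, score_threshold = 0) {
  stopifnot(n_rounds >= 1)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  X <- as.matrix(features)
  n <- nrow(X)
  ord <- apply(X, 2L, order) - 1L
  storage.mode(ord) <- "integer"
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  bound <- 1
  for (t in seq_len(n_rounds)) {
    st <- best_stump_cpp(X, ord, y, w)
    if (st$feature_index < 1 || st$error >= 0.5) break
    eps <- min(max(st$error, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    pred <- ifelse(X[, st$feature_index] > st$threshold,
                   st$polarity, -st$polarity)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    bound <- bound * 2 * sqrt(eps * (1 - eps))
    stumps[[t]] <- tibble::tibble(
      round = t, feature_index = st$feature_index,
      threshold = st$threshold, polarity = st$polarity,
      alpha = alpha, error = eps, bound = bound
    )
  }
  stumps <- dplyr::bind_rows(stumps)
  structure(
    list(stumps = stumps, n_rounds = as.integer(n_rounds),
         seed = as.integer(seed), score_threshold = score_threshold,
         feature_config = feature_config),
    class = "ctc_boost"
  )
}

#' @export
print.ctc_boost <- function(x, ...) {
  cat(sprintf(
    "<ctc_boost> %d stumps (of %d rounds), score threshold %g\n",
    nrow(x$stumps), x$n_rounds, x$score_threshold))
  invisible(x)
}

#' @rdname train_adaboost
#' @param x a `ctc_boost` model.
#' @param ... unused.
#' @export
tidy.ctc_boost <- function(x, ...) x$stumps

#' @rdname train_adaboost
#' @export
glance.ctc_boost <- function(x, ...) {
  tibble::tibble(
    n_stumps = nrow(x$stumps),
    n_rounds = x$n_rounds,
    final_bound = if (nrow(x$stumps)) x$stumps$bound[nrow(x$stumps)] else 1,
    score_threshold = x$score_threshold
  )
}

#' Ensemble scores for a feature matrix
#'
#' @param model a `ctc_boost`.
#' @param features numeric matrix compatible with the model's feature space.
#' @return Numeric vector of ensemble scores `sum_t alpha_t h_t(x)`.
#' @export
boost_scores <- function(model, features) {
  X <- as.matrix(features)
  st <- model$stumps
  if (nrow(st) > 0 && max(st$feature_index) > ncol(X)) {
    stop("feature dimension smaller than the model's feature space")
  }
  sc <- numeric(nrow(X))
  for (t in seq_len(nrow(st))) {
    h <- ifelse(X[, st$feature_index[t]] > st$threshold[t],
                st$polarity[t], -st$polarity[t])
    sc <- sc + st$alpha[t] * h
  }
  sc
}

#' Per-pixel ensemble score grid of an image
#'
#' Runs the full per-pixel pipeline: illumination correction, channel
#' stack, feature lookup and ensemble scoring, for every pixel of the
#' image. Only the channel samples referenced by the model's stumps are
#' materialized, so scoring stays linear in stump count.
#'
#' @param image a [ctc_image] (raw; correction is applied here).
#' @param model a `ctc_boost` whose `feature_config` holds the pattern and
#'   illumination window size used at training.
#' @param illum an [illum_config()]; defaults to the model's.
#' @return A numeric H x W matrix of ensemble scores.
#' @export
predict_scores <- function(image, model, illum = NULL) {
  fc <- model$feature_config
  if (is.null(fc) || is.null(fc$pattern)) {
    stop("model carries no feature_config; cannot rebuild its feature space")
  }
  pattern <- fc$pattern
  if (!inherits(pattern, "ctc_pattern")) {
    pattern <- ctc_pattern(pattern$offsets, pattern$diameter_px %||% NA_real_)
  }
  if (is.null(illum)) illum <- illum_config(fc$wsize %||% 64)
  corrected <- correct_illumination(image, illum)
  stack <- compute_channel_stack(corrected)
  H <- image$height; W <- image$width
  npix <- H * W
  fmap <- feature_index_map(pattern)
  st <- model$stumps
  scores <- numeric(npix)
  if (nrow(st) == 0L) return(matrix(scores, H, W))
  if (max(st$feature_index) > nrow(fmap)) {
    stop("model feature indices exceed the pattern's feature space")
  }
  anchor_r <- rep(seq_len(H), times = W)
  anchor_c <- rep(seq_len(W), each = H)
  # cache linear index grids per (level, sample point)
  idx_cache <- new.env(parent = emptyenv())
  sample_idx <- function(lev, d_row, d_col) {
    key <- paste(lev, d_row, d_col)
    if (!is.null(idx_cache[[key]])) return(idx_cache[[key]])
    lv <- stack$levels[[lev]]
    co <- level_sample_coords(anchor_r, anchor_c, d_row, d_col,
                              stack$scales[lev], nrow(lv$L), ncol(lv$L))
    idx <- (co$c - 1L) * nrow(lv$L) + co$r
    idx_cache[[key]] <- idx
    idx
  }
  for (t in seq_len(nrow(st))) {
    f <- fmap[st$feature_index[t], ]
    g <- stack$levels[[f$level]][[f$channel]]
    v <- g[sample_idx(f$level, f$d_row, f$d_col)]
    scores <- scores + st$alpha[t] *
      ifelse(v > st$threshold[t], st$polarity[t], -st$polarity[t])
  }
  matrix(scores, H, W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a score grid into a CTC pixel mask
#'
#' @param scores numeric matrix of ensemble scores.
#' @param score_threshold decision threshold; a pixel is CTC only when its
#'   score strictly exceeds it (ties are non-CTC).
#' @return Logical matrix.
#' @export
threshold_scores <- function(scores, score_threshold = 0) {
  scores > score_threshold
}

#' Save / load a boost model as JSON
#'
#' All stump fields, the feature configuration, seed and round count are
#' serialized; a load/save round-trip reproduces predictions exactly.
#'
#' @param model a `ctc_boost`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  fc <- model$feature_config
  obj <- list(
    version = 1L,
    n_rounds = model$n_rounds,
    seed = model$seed,
    score_threshold = model$score_threshold,
    feature_config = if (is.null(fc)) NULL else list(
      wsize = fc$wsize,
      pattern = list(
        diameter_px = fc$pattern$diameter_px,
        offsets = unname(as.matrix(fc$pattern$offsets))
      )
    ),
    stumps = as.data.frame(model$stumps)
  )
  # 17 significant digits: lossless IEEE-754 double round trip, so a
  # reloaded model predicts bitwise-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version)) stop("model file has no version field: ", path)
  st <- obj$stumps
  need <- c("feature_index", "threshold", "polarity", "alpha")
  if (length(st) == 0L) {
    st <- tibble::tibble(round = integer(), feature_index = integer(),
                         threshold = numeric(), polarity = numeric(),
                         alpha = numeric(), error = numeric(),
                         bound = numeric())
  } else {
    if (!all(need %in% names(st))) {
      stop("model file is missing stump fields: ",
           paste(setdiff(need, names(st)), collapse = ", "))
    }
    st <- tibble::as_tibble(st)
  }
  fc <- obj$feature_config
  if (!is.null(fc) && !is.null(fc$pattern)) {
    off <- matrix(as.integer(fc$pattern$offsets), ncol = 2)
    fc$pattern <- ctc_pattern(off, fc$pattern$diameter_px %||% NA_real_)
  }
  structure(
    list(stumps = st, n_rounds = as.integer(obj$n_rounds),
         seed = as.integer(obj$seed),
         score_threshold = obj$score_threshold,
         feature_config = fc),
    class = "ctc_boost"
  )
}
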