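# Independent brute-force oracles used across the suite. These are written
# as plainly as possible (explicit loops, closed-form references) and stay
# independent of the package's vectorized/compiled code paths.

# deterministic random test image
random_image <- function(H, W, seed = 1) {
  withr::with_seed(seed, {
    ctc_image(array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3)),
              id = sprintf("rand_%d", seed))
  })
}

# --- color ------------------------------------------------------------
# CIE L*u*v* from 8-bit sRGB, straight from the defining formulas
luv_oracle <- function(rgb255) {
  cc <- rgb255 / 255
  lin <- ifelse(cc <= 0.04045, cc / 12.92, ((cc + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wn <- as.vector(M %*% c(1, 1, 1))   # D65 white = sRGB (1,1,1)
  yr <- xyz[2] / wn[2]
  L <- if (yr > (6 / 29)^3) 116 * yr^(1 / 3) - 16 else (29 / 3)^3 * yr
  dn <- wn[1] + 15 * wn[2] + 3 * wn[3]
  d <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  if (d == 0) return(c(L = L, u = 0, v = 0))
  c(L = L,
    u = 13 * L * (4 * xyz[1] / d - 4 * wn[1] / dn),
    v = 13 * L * (9 * xyz[2] / d - 9 * wn[2] / dn))
}

# --- gradient / pooling ----------------------------------------------
sobel_oracle <- function(g) {
  H <- nrow(g); W <- ncol(g)
  at <- function(r, c) g[min(max(r, 1), H), min(max(c, 1), W)]
  mag <- matrix(0, H, W); code <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    gx <- at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1) -
          at(r - 1, c - 1) - 2 * at(r, c - 1) - at(r + 1, c - 1)
    gy <- at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1) -
          at(r - 1, c - 1) - 2 * at(r - 1, c) - at(r - 1, c + 1)
    m <- sqrt(gx^2 + gy^2)
    mag[r, c] <- m
    if (m == 0) { code[r, c] <- 0L; next }
    ang <- (atan2(-gy, gx) * 180 / pi) %% 360
    k <- ang / 45
    code[r, c] <- as.integer(ceiling(k - 0.5) %% 8)
  }
  list(mag = mag, orient = code)
}

pool_oracle <- function(g) {
  h <- nrow(g) %/% 2; w <- ncol(g) %/% 2
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    out[r, c] <- mean(g[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
  }
  out
}

# per-sample feature lookup, nested loops, 0-based arithmetic spelled out
feature_oracle <- function(stack, anchor, pattern) {
  off <- rbind(c(0L, 0L), pattern$offsets)
  vals <- c()
  for (lev in 1:3) {
    s <- c(1L, 2L, 4L)[lev]
    lv <- stack$levels[[lev]]
    for (ch in c("L", "u", "v", "mag", "orient")) {
      g <- lv[[ch]]
      for (k in seq_len(nrow(off))) {
        r0 <- ((anchor[1] - 1) + off[k, 1]) %/% s
        c0 <- ((anchor[2] - 1) + off[k, 2]) %/% s
        r0 <- min(max(r0, 0), nrow(g) - 1)
        c0 <- min(max(c0, 0), ncol(g) - 1)
        vals <- c(vals, g[r0 + 1, c0 + 1])
      }
    }
  }
  vals
}

# --- boosting ---------------------------------------------------------
make_separable_1d <- function() {
  list(X = matrix(c(0, 1, 10, 11), ncol = 1), y = c(-1, -1, 1, 1))
}

# plain-R discrete AdaBoost with exact stump search; independent of the
# package's compiled path but with the same deterministic conventions:
# candidate thresholds at midpoints of consecutive distinct sorted values,
# ties to the first feature / lowest threshold / polarity +1, and weighted
# errors accumulated as running sums in ascending sorted order (so that
# exact error ties resolve the same way in floating point)
adaboost_reference <- function(X, y, n_rounds) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  out <- list()
  for (t in seq_len(n_rounds)) {
    w_pos <- 0; w_neg <- 0
    for (i in seq_len(n)) {
      if (y[i] > 0) w_pos <- w_pos + w[i] else w_neg <- w_neg + w[i]
    }
    best <- list(err = Inf)
    for (j in seq_len(ncol(X))) {
      o <- order(X[, j])
      cum_pos <- 0; cum_neg <- 0
      for (k in seq_len(n - 1)) {
        i <- o[k]
        if (y[i] > 0) cum_pos <- cum_pos + w[i] else cum_neg <- cum_neg + w[i]
        if (X[o[k + 1], j] <= X[i, j]) next
        thr <- (X[i, j] + X[o[k + 1], j]) / 2
        err_pos <- cum_pos + (w_neg - cum_neg)   # predict +1 where x > thr
        err_neg <- (w_pos + w_neg) - err_pos
        if (err_pos < best$err) {
          best <- list(feature = j, thr = thr, pol = 1, err = err_pos)
        }
        if (err_neg < best$err) {
          best <- list(feature = j, thr = thr, pol = -1, err = err_neg)
        }
      }
    }
    if (!is.finite(best$err) || best$err >= 0.5) break
    eps <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    pred <- ifelse(X[, best$feature] > best$thr, best$pol, -best$pol)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    out[[t]] <- data.frame(feature_index = best$feature, threshold = best$thr,
                           polarity = best$pol, alpha = alpha, error = eps)
  }
  do.call(rbind, out)
}

# --- morphology / labeling -------------------------------------------
disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= radius^2, ]
}

erode_oracle <- function(mask, radius) {
  off <- disk_offsets(radius)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      # pixels outside the image count as background
      if (rr < 1 || rr > H || cc < 1 || cc > W || !mask[rr, cc]) {
        ok <- FALSE; break
      }
    }
    out[r, c] <- ok
  }
  out
}

dilate_oracle <- function(mask, radius) {
  off <- disk_offsets(radius)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    hit <- FALSE
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) {
        hit <- TRUE; break
      }
    }
    out[r, c] <- hit
  }
  out
}

opening_oracle <- function(mask, radius) {
  dilate_oracle(erode_oracle(mask, radius), radius)
}

# stack-based flood fill, 8-connectivity, raster-scan seed order
floodfill_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  k <- 0L
  for (r in 1:H) for (c in 1:W) {   # note: row-major seed order
    if (!mask[r, c] || lab[r, c] > 0L) next
    k <- k + 1L
    stack <- list(c(r, c))
    lab[r, c] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# random blob mask for fuzz tests
random_mask <- function(H, W, density = 0.3, seed = 1) {
  withr::with_seed(seed, matrix(runif(H * W) < density, H, W))
}
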