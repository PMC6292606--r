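test_that("rgb_to_luv matches the CIE formulas", {
  black <- ctc_image(array(0, c(4, 4, 3)))
  luv <- rgb_to_luv(black)
  expect_equal(luv$L[1, 1], 0)
  expect_equal(luv$u[1, 1], 0)
  expect_equal(luv$v[1, 1], 0)

  white <- ctc_image(array(255, c(4, 4, 3)))
  luv <- rgb_to_luv(white)
  expect_equal(luv$L[1, 1], 100, tolerance = 1e-6)
  expect_equal(luv$u[1, 1], 0, tolerance = 1e-6)
  expect_equal(luv$v[1, 1], 0, tolerance = 1e-6)

  # mid-gray: achromatic, L from the cube-root law
  gray <- ctc_image(array(128, c(4, 4, 3)))
  luv <- rgb_to_luv(gray)
  ref <- luv_oracle(c(128, 128, 128))
  expect_equal(luv$u[1, 1], 0, tolerance = 1e-6)
  expect_equal(luv$v[1, 1], 0, tolerance = 1e-6)
  expect_equal(luv$L[1, 1], ref[["L"]], tolerance = 0.05)

  # random colors against the closed-form oracle
  withr::with_seed(11, {
    for (i in 1:20) {
      rgb <- sample(0:255, 3, replace = TRUE)
      img <- ctc_image(array(rep(rgb, each = 16), c(4, 4, 3)))
      got <- rgb_to_luv(img)
      ref <- luv_oracle(rgb)
      expect_equal(got$L[1, 1], ref[["L"]], tolerance = 0.2)
      expect_equal(got$u[1, 1], ref[["u"]], tolerance = 0.6)
      expect_equal(got$v[1, 1], ref[["v"]], tolerance = 0.6)
    }
  })
})

test_that("gradient codes follow the 8-direction convention on ramps", {
  # horizontal ramp: gradient along +col -> angle 0 -> code 0
  h <- outer(rep(1, 8), 1:8) * 10
  g <- gradient(h)
  expect_true(all(g$orient[, 2:7] == 0L))
  expect_equal(stats::sd(g$mag[2:7, 2:7]), 0)

  # vertical ramp: gradient toward increasing row -> atan2(-g_row, 0) ->
  # 270 degrees -> code 6
  v <- outer(1:8, rep(1, 8)) * 10
  expect_true(all(gradient(v)$orient[2:7, ] == 6L))

  # diagonal ramp vs brute-force Sobel oracle on a 5x5 grid
  d <- outer(1:5, 1:5, `+`) * 7
  ref <- sobel_oracle(d)
  got <- gradient(d)
  expect_equal(got$mag, ref$mag)
  expect_equal(got$orient, ref$orient)
  expect_equal(unique(as.vector(got$orient[2:4, 2:4])),
               7L)  # down-right gradient: angle 315 with up-positive y

  expect_error(gradient(matrix(0, 2, 5)), "3x3")
})

test_that("gradient matches the Sobel oracle on random grids", {
  withr::with_seed(3, {
    for (i in 1:5) {
      g <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
      ref <- sobel_oracle(g)
      got <- gradient(g)
      expect_equal(got$mag, ref$mag)
      expect_equal(got$orient, ref$orient)
      expect_true(all(got$orient >= 0L & got$orient <= 7L))
      expect_true(all(got$mag >= 0))
    }
  })
})

test_that("downsample is 2x2 mean pooling with odd edges dropped", {
  expect_equal(downsample(matrix(5, 8, 8)), matrix(5, 4, 4))
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) * 255)
  expect_equal(downsample(cb), matrix(127.5, 2, 2))
  expect_equal(dim(downsample(matrix(1, 5, 5))), c(2L, 2L))
  expect_equal(downsample(matrix(1:25, 5, 5))[1, 1], mean(matrix(1:25, 5, 5)[1:2, 1:2]))
  expect_error(downsample(matrix(1, 1, 5)), "2x2")
})

test_that("the channel stack has 15 channels at the pyramid dimensions", {
  img <- random_image(64, 64, seed = 21)
  st <- compute_channel_stack(img)
  expect_length(st$levels, 3L)
  dims <- lapply(st$levels, function(l) dim(l$L))
  expect_equal(dims, list(c(64L, 64L), c(32L, 32L), c(16L, 16L)))
  for (l in st$levels) {
    expect_length(l, 5L)
    expect_true(all(l$orient %in% 0:7))
    expect_true(all(l$mag >= 0))
  }

  flat <- ctc_image(array(rep(c(30, 80, 120), each = 64 * 64), c(64, 64, 3)))
  st2 <- compute_channel_stack(flat)
  for (l in st2$levels) expect_equal(max(abs(l$mag)), 0)
})

test_that("the channel stack equals a straight-line recomputation", {
  img <- random_image(17, 14, seed = 5)   # odd dims exercise the floor rule
  st <- compute_channel_stack(img)
  # independent recomputation: oracle Luv per pixel, oracle pooling/Sobel
  H <- 17; W <- 14
  L <- u <- v <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    ref <- luv_oracle(img$pixels[r, c, ])
    L[r, c] <- ref[["L"]]; u[r, c] <- ref[["u"]]; v[r, c] <- ref[["v"]]
  }
  expect_equal(st$levels[[1]]$L, L, tolerance = 0.05)
  expect_equal(st$levels[[1]]$u, u, tolerance = 0.7)
  g1 <- sobel_oracle(st$levels[[1]]$L)
  expect_equal(st$levels[[1]]$mag, g1$mag)
  expect_equal(st$levels[[1]]$orient, g1$orient)
  # level 2: pooled Luv grids, gradient recomputed at the coarse scale
  L2 <- pool_oracle(st$levels[[1]]$L)
  expect_equal(st$levels[[2]]$L, L2)
  expect_equal(st$levels[[2]]$v, pool_oracle(st$levels[[1]]$v))
  g2 <- sobel_oracle(L2)
  expect_equal(st$levels[[2]]$mag, g2$mag)
  # level 3 dims follow floor(H/4)
  expect_equal(dim(st$levels[[3]]$L), c(4L, 3L))
  expect_equal(st$levels[[3]]$u, pool_oracle(pool_oracle(st$levels[[1]]$u)))
})

test_that("default_pattern builds two 8-point rings inside the diameter", {
  p8 <- default_pattern(8)
  expect_equal(nrow(p8$offsets), 16L)
  # per-coordinate displacement bounded by round(diameter/2)
  expect_true(all(abs(p8$offsets) <= 4))
  rad <- sqrt(rowSums(p8$offsets^2))
  # rings at nominal radii 2 and 4 (integer rounding shifts diagonals)
  expect_true(all(abs(rad - 2) < 0.8 | abs(rad - 4) < 0.8))

  p40 <- default_pattern(40)
  rad40 <- sqrt(rowSums(p40$offsets^2))
  expect_true(all(abs(rad40 - 10) < 1.5 | abs(rad40 - 20) < 1.5))
  expect_true(all(abs(p40$offsets) <= 20))
  expect_false(any(p40$offsets[, 1] == 0 & p40$offsets[, 2] == 0))
  expect_equal(anyDuplicated(p40$offsets), 0L)
})

test_that("feature vectors have the fixed layout and lengths", {
  img <- random_image(32, 32, seed = 31)
  st <- compute_channel_stack(img)
  empty <- ctc_pattern(matrix(integer(), ncol = 2))
  expect_length(extract_feature_vector(st, c(5, 5), empty), 15L)

  flat <- compute_channel_stack(ctc_image(array(77, c(16, 16, 3))))
  fv <- extract_feature_vector(flat, c(8, 8), default_pattern(8))
  fm <- feature_index_map(default_pattern(8))
  expect_length(fv, 15L * 17L)
  expect_true(all(fv[fm$channel == "mag"] == 0))
  for (ch in c("L", "u", "v")) {
    expect_equal(length(unique(fv[fm$channel == ch])), 1L)
  }
})

test_that("feature extraction matches the nested-loop oracle", {
  img <- random_image(32, 32, seed = 13)
  st <- compute_channel_stack(img)
  pat <- default_pattern(12)
  withr::with_seed(17, {
    anchors <- cbind(sample(32, 40, TRUE), sample(32, 40, TRUE))
  })
  got <- extract_feature_matrix(st, anchors, pat)
  for (i in seq_len(nrow(anchors))) {
    expect_equal(got[i, ], feature_oracle(st, anchors[i, ], pat))
  }
})

test_that("features are translation-consistent under a (2,2) shift", {
  base <- random_image(24, 24, seed = 41)
  shifted_px <- array(0, c(24, 24, 3))
  shifted_px[3:24, 3:24, ] <- base$pixels[1:22, 1:22, ]
  shifted <- ctc_image(shifted_px)
  pat <- ctc_pattern(cbind(c(-2L, 0L, 2L, 0L), c(0L, -2L, 0L, 2L)))
  st1 <- compute_channel_stack(base)
  st2 <- compute_channel_stack(shifted)
  # anchor far from borders; offsets even so coarse floor-quantization aligns
  f1 <- extract_feature_vector(st1, c(12, 12), pat)
  f2 <- extract_feature_vector(st2, c(14, 14), pat)
  fm <- feature_index_map(pat)
  sel <- fm$level == 1 & fm$channel %in% c("L", "u", "v")
  expect_equal(f1[sel], f2[sel], tolerance = 1e-8)
})
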