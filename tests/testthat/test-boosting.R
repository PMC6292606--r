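test_that("training-pixel sampling counts, caps, and reproduces", {
  img <- random_image(40, 40, seed = 2)
  mask <- matrix(FALSE, 40, 40)
  mask[5:18, 5:18] <- TRUE                     # 196 positives available
  s1 <- sample_training_pixels(list(img), list(mask), neg_pos_ratio = 3,
                               max_pos_per_image = 1000, seed = 5)
  expect_equal(sum(s1$label == 1), 196L)
  expect_equal(sum(s1$label == -1), 3L * 196L)
  # negatives respect the 5 px exclusion margin
  neg <- s1[s1$label == -1, ]
  near <- dilate_oracle(mask, 5)
  expect_false(any(near[cbind(neg$row, neg$col)]))

  s2 <- sample_training_pixels(list(img), list(mask), neg_pos_ratio = 3,
                               max_pos_per_image = 1000, seed = 5)
  expect_identical(s1, s2)

  s3 <- sample_training_pixels(list(img), list(mask),
                               max_pos_per_image = 50, seed = 5)
  expect_equal(sum(s3$label == 1), 50L)

  empty <- matrix(FALSE, 40, 40)
  expect_warning(
    expect_error(sample_training_pixels(list(img), list(empty), seed = 1),
                 "no positive"),
    "no true pixels")
})

test_that("adaboost separates separable data in one round", {
  d <- make_separable_1d()
  m <- train_adaboost(d$X, d$y, n_rounds = 1)
  st <- tidy(m)
  expect_equal(nrow(st), 1L)
  expect_gt(st$threshold, 1)
  expect_lt(st$threshold, 10)
  expect_equal(sign(boost_scores(m, d$X)), d$y)
})

test_that("alpha follows the closed form at error 0.25", {
  # four equally-weighted 1-D samples, best stump misclassifies exactly one
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(-1, -1, 1, -1)
  m <- train_adaboost(X, y, n_rounds = 1)
  st <- tidy(m)
  expect_equal(st$error, 0.25)
  expect_equal(st$alpha, 0.5 * log(3), tolerance = 1e-12)
})

test_that("adaboost agrees round-by-round with the naive reference", {
  withr::with_seed(23, {
    X <- cbind(runif(60), runif(60))
    y <- ifelse(xor(X[, 1] > 0.5, X[, 2] > 0.5), 1, -1)
    flip <- sample(60, 5)
    y[flip] <- -y[flip]
  })
  ref <- adaboost_reference(X, y, 15)
  got <- tidy(train_adaboost(X, y, n_rounds = 15))
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$feature_index, ref$feature_index)
  expect_equal(got$threshold, ref$threshold)
  expect_equal(got$polarity, ref$polarity)
  expect_equal(got$alpha, ref$alpha, tolerance = 1e-12)
  expect_equal(got$error, ref$error, tolerance = 1e-12)
})

test_that("the ensemble beats the best single stump on XOR data", {
  withr::with_seed(29, {
    X <- cbind(runif(80), runif(80))
    y <- ifelse(xor(X[, 1] > 0.5, X[, 2] > 0.5), 1, -1)
  })
  m <- train_adaboost(X, y, n_rounds = 20)
  st <- tidy(m)
  ens_err <- mean(sign(boost_scores(m, X)) != y)
  expect_lt(ens_err, min(st$error))
  # every accepted stump is better than chance
  expect_true(all(st$error < 0.5))
  # exponential-loss bound on the training error
  expect_lte(ens_err, st$bound[nrow(st)] + 1e-12)
})

test_that("the exponential-loss bound holds on random problems", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      X <- matrix(rnorm(50 * 4), 50, 4)
      y <- sample(c(-1, 1), 50, replace = TRUE)
      m <- train_adaboost(X, y, n_rounds = 25)
      st <- tidy(m)
      err <- mean(sign(boost_scores(m, X)) != y)
      expect_lte(err, st$bound[nrow(st)] + 1e-12)
      expect_true(all(st$error < 0.5))
    }
  })
})

test_that("training is deterministic and rejects single-class input", {
  withr::with_seed(37, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(c(-1, 1), 40, replace = TRUE)
  })
  m1 <- train_adaboost(X, y, n_rounds = 10)
  m2 <- train_adaboost(X, y, n_rounds = 10)
  expect_identical(tidy(m1), tidy(m2))
  expect_error(train_adaboost(X, rep(1, 40), n_rounds = 5), "single class")
})

test_that("score thresholding treats ties as non-CTC", {
  sc <- matrix(c(-1, 0, 0.5, 2), 2, 2)
  expect_equal(threshold_scores(sc, 0), matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_false(any(threshold_scores(sc, Inf)))
  expect_false(any(threshold_scores(matrix(0, 3, 3), 0)))
})

test_that("an empty ensemble scores zero everywhere", {
  img <- random_image(16, 16, seed = 43)
  pat <- default_pattern(8)
  model <- structure(
    list(stumps = tibble::tibble(round = integer(), feature_index = integer(),
                                 threshold = numeric(), polarity = numeric(),
                                 alpha = numeric(), error = numeric(),
                                 bound = numeric()),
         n_rounds = 0L, seed = 1L, score_threshold = 0,
         feature_config = list(pattern = pat, wsize = 16)),
    class = "ctc_boost")
  expect_equal(predict_scores(img, model), matrix(0, 16, 16))
})

test_that("models round-trip through JSON with identical predictions", {
  withr::with_seed(41, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- sample(c(-1, 1), 60, replace = TRUE)
  })
  m <- train_adaboost(X, y, n_rounds = 10,
                      feature_config = list(pattern = default_pattern(8),
                                            wsize = 32))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(boost_scores(m2, X), boost_scores(m, X))
  expect_equal(m2$feature_config$pattern$offsets,
               m$feature_config$pattern$offsets, ignore_attr = TRUE)

  # image-level predictions are bitwise identical, and deterministic
  img <- random_image(24, 24, seed = 47)
  mod_img <- train_adaboost(X, y, n_rounds = 5,
                            feature_config = list(
                              pattern = default_pattern(8), wsize = 24))
  p1 <- predict_scores(img, mod_img)
  save_model(mod_img, f)
  p2 <- predict_scores(img, load_model(f))
  expect_identical(p1, p2)
  expect_identical(p1, predict_scores(img, mod_img))

  # schema validation
  bad <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad$stumps$alpha <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f2), "alpha")
  bad2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  bad2$version <- NULL
  jsonlite::write_json(bad2, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f2), "version")
})

test_that("a model trained on a synthetic blob scores it above background", {
  sc <- generate_scene(scene_params(height = 128, width = 128,
                                    n_tumor = 1, artifact_halos = 0,
                                    seed = 51))
  img <- sc$image; mask <- sc$mask
  samples <- sample_training_pixels(list(img), list(mask),
                                    max_pos_per_image = 200, seed = 3)
  stack <- compute_channel_stack(correct_illumination(img, illum_config(64)))
  pat <- default_pattern(40)
  feats <- extract_feature_matrix(stack, cbind(samples$row, samples$col), pat)
  m <- train_adaboost(feats, samples$label, n_rounds = 20,
                      feature_config = list(pattern = pat, wsize = 64))
  scores <- predict_scores(img, m)
  expect_gt(mean(scores[mask]), mean(scores[!mask]))
})
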