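gt_blobs <- function() {
  m <- matrix(FALSE, 60, 60)
  m[5:16, 5:16] <- TRUE
  m[30:41, 8:19] <- TRUE
  m[20:31, 40:51] <- TRUE
  m
}

test_that("object matching handles identity, misses, and shared overlap", {
  gt <- label_components(gt_blobs())

  same <- match_objects(gt, gt)
  expect_equal(same$TP, 3L); expect_equal(same$FN, 0L)
  expect_equal(same$FP, 0L); expect_equal(same$n_gt, 3L)

  none <- match_objects(label_components(matrix(FALSE, 60, 60)), gt)
  expect_equal(none$TP, 0L); expect_equal(none$FN, 3L)
  expect_equal(none$FP, 0L)

  # one wide detection overlapping two GT blobs above threshold: greedy
  # one-to-one matching credits a single TP and leaves one FN, no FP
  det_mask <- matrix(FALSE, 30, 30)
  det_mask[5:10, 3:26] <- TRUE
  gt_mask <- matrix(FALSE, 30, 30)
  gt_mask[4:11, 4:9] <- TRUE
  gt_mask[4:11, 20:25] <- TRUE
  cc <- match_objects(label_components(det_mask), label_components(gt_mask))
  expect_equal(cc$TP, 1L)
  expect_equal(cc$FN, 1L)
  expect_equal(cc$FP, 0L)

  # below the 0.25-of-smaller overlap threshold nothing matches
  d2 <- matrix(FALSE, 30, 30); d2[1:10, 1:10] <- TRUE
  g2 <- matrix(FALSE, 30, 30); g2[10:19, 10:19] <- TRUE   # 1 px overlap
  cc2 <- match_objects(label_components(d2), label_components(g2))
  expect_equal(cc2$TP, 0L)
  expect_equal(cc2$FP, 1L)
  expect_equal(cc2$FN, 1L)
})

test_that("counts aggregate field-wise and order-invariantly", {
  a <- confusion_counts(2, 1, 0)
  b <- confusion_counts(3, 0, 2)
  expect_equal(aggregate_counts(a), a)
  ab <- aggregate_counts(dplyr::bind_rows(a, b))
  expect_equal(ab$TP, 5L); expect_equal(ab$FN, 1L)
  expect_equal(ab$FP, 2L); expect_equal(ab$n_images, 2L)
  expect_equal(aggregate_counts(dplyr::bind_rows(b, a)), ab)
  empty <- aggregate_counts(a[0, ])
  expect_equal(empty$TP, 0L); expect_equal(empty$n_images, 0L)
})

test_that("metrics arithmetic reproduces known confusion-count examples", {
  # 230/235 sensitivity
  m <- compute_metrics(confusion_counts(230, 5, 1, n_images = 83))
  expect_equal(m$sensitivity_pct, 97.87)

  # 36 FP over 120 images at 1270 cells/image
  m2 <- compute_metrics(confusion_counts(168, 29, 36, n_images = 120))
  expect_equal(m2$est_fp_rate, 0.0236)

  # perfect detector
  m3 <- compute_metrics(confusion_counts(10, 0, 0, n_images = 4))
  expect_equal(m3$sensitivity_pct, 100)
  expect_equal(m3$est_specificity_pct, 100)
  expect_equal(m3$fn_rate_pct, 0)

  expect_error(compute_metrics(confusion_counts(0, 0, 3, n_images = 1)),
               "n_gt")
})

test_that("metrics move monotonically with the counts", {
  base <- compute_metrics(confusion_counts(50, 10, 5, n_images = 10))
  more_fp <- compute_metrics(confusion_counts(50, 10, 25, n_images = 10))
  expect_lt(more_fp$est_specificity_pct, base$est_specificity_pct)
  more_tp <- compute_metrics(confusion_counts(55, 5, 5, n_images = 10))
  expect_gt(more_tp$sensitivity_pct, base$sensitivity_pct)
  # TP + FN = n_gt and the rate complement hold
  expect_equal(base$TP + base$FN, base$n_gt)
  expect_equal(base$sensitivity_pct + base$fn_rate_pct, 100,
               tolerance = 0.011)
})

test_that("dataset evaluation wires detection, matching and reporting", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(3, scene_params(height = 128, width = 128,
                                          n_tumor = 2, artifact_halos = 0),
                          out_dir = dir, seed = 77, train_frac = 2 / 3)
  cfg <- run_config(boosting = list(rounds = 15, max_pos_per_image = 150))
  model <- train_detector(man, cfg)
  out_dir <- withr::local_tempdir()
  ev <- evaluate_dataset(man, model, split = "test", out_dir = out_dir)
  expect_s3_class(glance(ev), "tbl_df")
  expect_gte(ev$metrics$sensitivity_pct, 0)
  expect_lte(ev$metrics$sensitivity_pct, 100)
  expect_equal(ev$metrics$TP + ev$metrics$FN, ev$metrics$n_gt)
  expect_true(file.exists(file.path(out_dir, "per_image_counts.csv")))
  expect_true(file.exists(file.path(out_dir, "metrics.json")))

  # entries without masks are rejected
  man2 <- man; man2$mask[man2$split == "test"] <- ""
  expect_error(evaluate_dataset(man2, model, split = "test"), "mask")
})
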