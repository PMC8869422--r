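test_that("subject splits are balanced, deterministic, and exhaustive", {
  s10 <- split_subjects(sprintf("P%02d", 1:10), k = 5, seed = 1)
  expect_equal(as.integer(sort(table(s10))), rep(2L, 5))
  expect_setequal(names(s10), sprintf("P%02d", 1:10))
  # 351 subjects over 5 folds -> sizes 70 or 71
  s351 <- split_subjects(sprintf("P%03d", 1:351), k = 5, seed = 2)
  expect_true(all(table(s351) %in% c(70L, 71L)))
  expect_identical(split_subjects(sprintf("P%03d", 1:351), 5, 2), s351)
  expect_false(identical(split_subjects(sprintf("P%03d", 1:351), 5, 3), s351))
  expect_error(split_subjects(c("A", "B"), k = 5), "at least k")
  # repeat days of one subject share a fold
  srep <- split_subjects(c("A", "B", "A", "C", "D", "E"), k = 5, seed = 1)
  expect_length(srep, 5L)
})

make_pipeline_dataset <- function() {
  params <- synth_params(day_length_h = 1.5, meals_per_day_mean = 2,
                         meals_max = 3, meal_dur_median_min = 5,
                         meal_dur_mean_min = 6.5)
  dataset <- generate_dataset(4, params, seed = 17)
  lapply(dataset, function(d) {
    d$recording <- preprocess_recording(d$recording)
    d
  })
}

test_that("a fold trains, detects, and reports coherent metrics", {
  dataset <- make_pipeline_dataset()
  split <- structure(c(1L, 1L, 2L, 2L), names = dataset_subjects <-
                       vapply(dataset, function(d) d$recording$subject_id,
                              character(1)))
  rep1 <- run_fold(dataset, split, 1, window_config(0.5),
                   train_cfg = train_config(learning_rate = 1e-3,
                                            epochs = 8, seed = 5),
                   infer_stride_data = 15)
  expect_true(rep1$window_accuracy >= 0 && rep1$window_accuracy <= 1)
  expect_equal(rep1$TP + rep1$Miss,
               sum(vapply(dataset[1:2], function(d) nrow(d$meals),
                          integer(1))))
  expect_equal(rep1$n_days, 2L)
  expect_true(all(c("TPR", "FP_per_TP", "datum") %in% names(rep1)))
  # impossible start threshold: nothing can be detected
  repx <- run_fold(dataset, split, 1, window_config(0.5),
                   train_cfg = train_config(learning_rate = 1e-3,
                                            epochs = 2, seed = 5),
                   detector_cfg = detector_config(TS = 1, TE = 0.4),
                   infer_stride_data = 15)
  expect_equal(repx$TPR, 0)
  expect_equal(repx$FP, 0L)
  # a fold with no training days is refused
  expect_error(run_fold(dataset, structure(rep(1L, 4),
                                           names = names(split)),
                        1, window_config(0.5)), "no training days")
})

test_that("cross-validation aggregates fold metrics and is seed-stable", {
  dataset <- make_pipeline_dataset()
  cv <- run_crossval(dataset, k = 2, window_cfg = window_config(0.5),
                     train_cfg = train_config(learning_rate = 1e-3,
                                              epochs = 5),
                     infer_stride_data = 15, seed = 3)
  expect_length(cv$folds, 2L)
  accs <- vapply(cv$folds, function(f) f$window_accuracy, numeric(1))
  agg_acc <- cv$aggregate$mean[cv$aggregate$metric == "window_accuracy"]
  expect_equal(agg_acc, mean(accs))
  # subject-disjoint folds
  expect_equal(as.integer(sort(table(cv$split))), c(2L, 2L))
  cv2 <- run_crossval(dataset, k = 2, window_cfg = window_config(0.5),
                      train_cfg = train_config(learning_rate = 1e-3,
                                               epochs = 5),
                      infer_stride_data = 15, seed = 3)
  expect_equal(cv$aggregate, cv2$aggregate)
})

test_that("threshold sweeps reuse traces and behave monotonically", {
  dataset <- make_pipeline_dataset()
  tc <- train_config(learning_rate = 1e-3, epochs = 8)
  sw <- sweep_hyperparam("TS", c(0.5, 0.7, 0.9), dataset, k = 2,
                         window_cfg = window_config(0.5), train_cfg = tc,
                         infer_stride_data = 15, seed = 3)
  expect_equal(nrow(sw), 3L)
  expect_equal(attr(sw, "axis"), "TS")
  # value order must not matter
  sw_rev <- sweep_hyperparam("TS", c(0.9, 0.7, 0.5), dataset, k = 2,
                             window_cfg = window_config(0.5), train_cfg = tc,
                             infer_stride_data = 15, seed = 3)
  expect_equal(sw[order(sw$value), ], sw_rev[order(sw_rev$value), ],
               ignore_attr = TRUE)
  # degenerate single-value sweep equals the cross-validation it wraps
  sw1 <- sweep_hyperparam("TS", 0.8, dataset, k = 2,
                          window_cfg = window_config(0.5), train_cfg = tc,
                          infer_stride_data = 15, seed = 3)
  cv <- run_crossval(dataset, k = 2, window_cfg = window_config(0.5),
                     train_cfg = tc, infer_stride_data = 15, seed = 3)
  pooled_tp <- sum(vapply(cv$folds, function(f) f$TP, integer(1)))
  pooled_miss <- sum(vapply(cv$folds, function(f) f$Miss, integer(1)))
  expect_equal(sw1$TPR, pooled_tp / (pooled_tp + pooled_miss))
})

test_that("lower TE lengthens individual detections on a smooth trace", {
  tr <- withr::with_seed(44, pmin(pmax(gaussian_smooth(runif(3000), 30) *
                                         2 - 0.4, 0), 1))
  mean_len <- function(te) {
    seg <- hysteresis_segment(tr, 0.7, te)
    if (!nrow(seg)) return(0)
    mean(seg$end_datum - seg$start_datum)
  }
  lens <- vapply(c(0.6, 0.4, 0.2), mean_len, numeric(1))
  expect_true(all(diff(lens) >= 0))
})
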