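test_that("episode matching covers all five overlap scenarios", {
  meal <- episode_list(100, 200)
  # (a) one meal, one overlapping detection
  c1 <- match_episodes(meal, episode_list(150, 250, "eating"))
  expect_equal(c(c1$TP, c1$FP, c1$Miss), c(1L, 0L, 0L))
  # (b) one meal covered by several detections -> still one TP
  c2 <- match_episodes(meal, episode_list(c(90, 160), c(130, 210), "eating"))
  expect_equal(c(c2$TP, c2$FP, c2$Miss), c(1L, 0L, 0L))
  # (c) two meals under one detection -> two TPs, no FP
  c3 <- match_episodes(episode_list(c(100, 300), c(200, 400)),
                       episode_list(150, 350, "eating"))
  expect_equal(c(c3$TP, c3$FP, c3$Miss), c(2L, 0L, 0L))
  # (d) meal with no overlapping detection -> miss
  # (e) detection with no overlapping meal -> FP
  c4 <- match_episodes(meal, episode_list(300, 400, "eating"))
  expect_equal(c(c4$TP, c4$FP, c4$Miss), c(0L, 1L, 1L))
  # touching endpoints do not overlap
  c5 <- match_episodes(meal, episode_list(200, 300, "eating"))
  expect_equal(c(c5$TP, c5$FP, c5$Miss), c(0L, 1L, 1L))
})

test_that("matching agrees with a pairwise-overlap oracle on random scenarios", {
  withr::with_seed(40, {
    for (i in 1:200) {
      meals <- random_episodes(sample(0:6, 1), 3600, 30, 600)
      dets <- random_episodes(sample(0:8, 1), 3600, 30, 600)
      if (nrow(meals) == 0) next
      got <- match_episodes(meals, dets)
      want <- oracle_match(meals, dets)
      expect_equal(got$TP, want$TP)
      expect_equal(got$FP, want$FP)
      expect_equal(got$Miss, want$Miss)
      expect_equal(got$TP + got$Miss, nrow(meals))
      # every detection is classified exactly once
      expect_equal(got$FP + sum(!seq_len(nrow(dets)) %in% got$fp_detections),
                   nrow(dets))
    }
  })
})

test_that("episode metrics and their time-shift invariance", {
  em <- episode_metrics(list(TP = 10, Miss = 0, FP = 0), n_days = 2)
  expect_equal(unlist(em), c(TPR = 1, FP_per_TP = 0, FP_per_day = 0))
  em0 <- episode_metrics(list(TP = 0, Miss = 5, FP = 3), n_days = 1)
  expect_equal(em0$TPR, 0)
  expect_true(is.na(em0$FP_per_TP))
  expect_true(attr(em0$FP_per_TP, "undefined"))
  expect_error(episode_metrics(list(TP = 1, Miss = 0, FP = 0), 0), "n_days")
  # shifting both lists by a constant changes nothing
  withr::with_seed(41, {
    meals <- random_episodes(4, 3600, 60, 300)
    dets <- random_episodes(5, 3600, 60, 300)
    m1 <- episode_metrics(match_episodes(meals, dets), 1)
    shift <- function(e) episode_list(e$start_s + 500, e$end_s + 500, e$label)
    m2 <- episode_metrics(match_episodes(shift(meals), shift(dets)), 1)
    expect_equal(m1, m2)
  })
})

test_that("boundary errors use the first/last overlapping detection", {
  meal <- episode_list(600, 1200)
  b1 <- boundary_errors(match_episodes(meal, episode_list(600, 1200, "eating")))
  expect_equal(c(b1$start_mean_min, b1$end_mean_min), c(0, 0))
  # detection [510, 1254): starts 1.5 min early, ends 0.9 min late
  b2 <- boundary_errors(match_episodes(meal, episode_list(510, 1254, "eating")))
  expect_equal(b2$start_mean_min, -1.5)
  expect_equal(b2$end_mean_min, 0.9)
  # two detections: first start and last end are used
  b3 <- boundary_errors(match_episodes(meal,
    episode_list(c(550, 900), c(700, 1300), "eating")))
  expect_equal(b3$start_mean_min, (550 - 600) / 60)
  expect_equal(b3$end_mean_min, (1300 - 1200) / 60)
  expect_error(boundary_errors(match_episodes(meal,
    episode_list(2000, 2100, "eating"))), "no true positives")
})

test_that("datum metrics reproduce hand-built confusion matrices", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  perf <- datum_metrics(truth, truth)
  expect_equal(unlist(perf), c(precision = 1, recall = 1, TNR = 1, F1 = 1,
                               ACC_W = 1))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 4))
  dm <- datum_metrics(truth, pred)
  expect_equal(dm$precision, 0.6)
  expect_equal(dm$recall, 0.75)
  expect_equal(dm$TNR, 2 / 3)
  expect_equal(dm$F1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  # weighted accuracy is balanced accuracy
  expect_equal((0.69 + 0.93) / 2, 0.81)
  expect_equal(dm$ACC_W, (dm$recall + dm$TNR) / 2)
  # degenerate denominators are flagged, not raised
  none <- datum_metrics(rep(FALSE, 5), rep(FALSE, 5))
  expect_true(is.na(none$precision) && is.na(none$recall))
  expect_error(datum_metrics(logical(), logical()), "empty")
})

test_that("percent reduction matches direct arithmetic", {
  expect_equal(percent_reduction(7.3, 0.9), 100 * (7.3 - 0.9) / 7.3)
  expect_equal(percent_reduction(10, 10), 0)
  expect_error(percent_reduction(0, 1), "nonzero")
})
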