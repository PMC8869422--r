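test_that("hysteresis opens above TS, stays open above TE, closes below TE", {
  expect_equal(nrow(hysteresis_segment(rep(0, 100), 0.8, 0.4)), 0L)
  # 0.5 >= TE keeps the segment open; it closes at the first p < TE
  tr <- c(0, 0, 0.9, 0.9, 0.5, 0.5, 0.3, 0)
  seg <- hysteresis_segment(tr, 0.8, 0.4)
  expect_equal(seg, data.frame(start_datum = 3L, end_datum = 7L))
  # exactly TS does not open; exactly TE does not close
  seg2 <- hysteresis_segment(c(0.8, 0.85, 0.4, 0.39), 0.8, 0.4)
  expect_equal(seg2, data.frame(start_datum = 2L, end_datum = 4L))
  # open at end of trace closes after the last datum
  seg3 <- hysteresis_segment(c(0, 0.9, 0.9), 0.8, 0.4)
  expect_equal(seg3, data.frame(start_datum = 2L, end_datum = 4L))
  expect_error(hysteresis_segment(0.5, 0.3, 0.6), "TE must be <= TS")
})

test_that("hysteresis equals a per-datum state-machine oracle on random traces", {
  withr::with_seed(30, {
    for (i in 1:300) {
      n <- sample(1:300, 1)
      tr <- runif(n)
      TE <- runif(1, 0, 0.9); TS <- runif(1, TE, 1)
      expect_identical(hysteresis_segment(tr, TS, TE),
                       oracle_hysteresis(tr, TS, TE))
    }
  })
})

test_that("merging is inclusive at the gap boundary and transitive", {
  rate <- 15
  seg <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_datum = m[, 1], end_datum = m[, 2])
  }
  # 30 s apart -> merged
  expect_equal(merge_close_segments(seg(1, 100, 550, 700), 60, rate),
               seg(1, 700))
  # exactly 60 s apart -> merged ("within 1 min" is inclusive)
  expect_equal(merge_close_segments(seg(1, 100, 1000, 1100), 60, rate),
               seg(1, 1100))
  expect_equal(merge_close_segments(seg(1, 100, 1001, 1100), 60, rate),
               seg(1, 100, 1001, 1100))
  # three segments with 30 s gaps collapse to one hull
  expect_equal(merge_close_segments(seg(1, 100, 550, 700, 1150, 1300),
                                    60, rate),
               seg(1, 1300))
  expect_error(merge_close_segments(seg(550, 700, 1, 100), 60, rate),
               "sorted")
})

test_that("short-segment removal is strict", {
  rate <- 15
  s59 <- data.frame(start_datum = 1L, end_datum = 1L + 59L * 15L)
  s60 <- data.frame(start_datum = 1L, end_datum = 1L + 60L * 15L)
  expect_equal(nrow(drop_short_segments(s59, 60, rate)), 0L)
  expect_equal(nrow(drop_short_segments(s60, 60, rate)), 1L)
  empty <- data.frame(start_datum = integer(), end_datum = integer())
  expect_equal(nrow(drop_short_segments(empty, 60, rate)), 0L)
})

test_that("detect_episodes composes hysteresis, merge, drop in order", {
  rate <- 15
  # two 90 s humps above TS separated by a 20 s dip below TE -> one episode
  hump <- function(len_s) rep(0.9, len_s * rate)
  tr <- c(rep(0, 150), hump(90), rep(0.1, 20 * rate), hump(90), rep(0, 150))
  eps <- detect_episodes(tr, detector_config(), rate)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$end_s - eps$start_s, 200, tolerance = 0.1)
  # a lone 45 s hump is dropped as shorter than 1 min
  tr2 <- c(rep(0, 150), hump(45), rep(0, 150))
  expect_equal(nrow(detect_episodes(tr2, detector_config(), rate)), 0L)
  # degenerate hysteresis TS == TE == 0.5 equals plain thresholding
  withr::with_seed(31, {
    tr3 <- pmin(pmax(gaussian_smooth(runif(2000), 5), 0), 1)
    got <- detect_episodes(tr3, detector_config(TS = 0.5, TE = 0.5), rate)
    plain <- tr3 > 0.5
    d <- diff(c(FALSE, plain, FALSE))
    seg <- data.frame(start_datum = which(d == 1), end_datum = which(d == -1))
    seg <- oracle_drop(oracle_merge(seg, 60, rate), 60, rate)
    expect_equal(got$start_s, (seg$start_datum - 1) / rate)
    expect_equal(got$end_s, (seg$end_datum - 1) / rate)
  })
})

test_that("lowering TS never shrinks pre-merge coverage; results respect the config", {
  withr::with_seed(32, {
    covered <- function(seg) sum(seg$end_datum - seg$start_datum)
    for (i in 1:50) {
      tr <- gaussian_smooth(runif(1500), 3)
      TEv <- 0.3
      cov <- vapply(c(0.9, 0.7, 0.5, 0.4),
                    function(ts) covered(hysteresis_segment(tr, ts, TEv)),
                    numeric(1))
      expect_true(all(diff(cov) >= 0))
    }
    # post-processed detections: min length and min separation guaranteed
    for (i in 1:20) {
      tr <- pmin(pmax(gaussian_smooth(runif(3000), 2), 0), 1)
      eps <- detect_episodes(tr, detector_config(), 15)
      if (nrow(eps)) {
        expect_true(all(eps$end_s - eps$start_s >= 60))
        if (nrow(eps) > 1)
          expect_true(all(eps$start_s[-1] - eps$end_s[-nrow(eps)] > 60))
      }
    }
  })
})
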