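#' Windowing configuration
#'
#' Training windows are cut with a coarse slide (default 15 s) and labeled
#' eating when more than half of the window overlaps a self-reported meal.
#'
#' @param W_minutes window length in minutes (the main hyperparameter;
#'   fractional values such as 0.125 = 7.5 s are accepted).
#' @param train_slide_s slide between consecutive training windows, seconds.
#' @param overlap_threshold fraction of the window that must be covered by
#'   meals for an eating label; strictly greater-than (default 0.5).
#' @return a `window_config` list.
#' @export
window_config <- function(W_minutes, train_slide_s = 15,
                          overlap_threshold = 0.5) {
  if (W_minutes <= 0) stop("W_minutes must be > 0")
  if (train_slide_s <= 0) stop("train_slide_s must be > 0")
  if (overlap_threshold <= 0 || overlap_threshold >= 1)
    stop("overlap_threshold must be in (0, 1)")
  structure(list(W_minutes = W_minutes, train_slide_s = train_slide_s,
                 overlap_threshold = overlap_threshold),
            class = "window_config")
}

#' Window length in samples
#' @param W_minutes window length in minutes.
#' @param sample_rate samples per second.
#' @return integer number of samples, `round(W_minutes * 60 * sample_rate)`.
#' @export
window_samples <- function(W_minutes, sample_rate = 15) {
  as.integer(round(W_minutes * 60 * sample_rate))
}

# total length of [t0, t1) covered by the union of episodes
interval_overlap <- function(t0, t1, episodes) {
  if (nrow(episodes) == 0L) return(0)
  lo <- pmax(episodes$start_s, t0)
  hi <- pmin(episodes$end_s, t1)
  keep <- hi > lo
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  # union of clipped intervals (inputs may overlap in principle)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0; cur_lo <- lo[1L]; cur_hi <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { total <- total + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  total + (cur_hi - cur_lo)
}

#' Label one window as eating or non-eating
#'
#' A window `[t0, t1)` is labeled eating (1) when the union of ground-truth
#' meals covers strictly more than `overlap_threshold` of its duration;
#' exactly the threshold is non-eating.
#'
#' @param t0,t1 window bounds in seconds, `t1 > t0`.
#' @param meals an [episode_list()] of ground-truth meals.
#' @param overlap_threshold overlap fraction required (strict; default 0.5).
#' @return integer 0 or 1.
#' @export
label_window <- function(t0, t1, meals, overlap_threshold = 0.5) {
  if (t1 <= t0) stop("window must have t1 > t0")
  as.integer(interval_overlap(t0, t1, meals) >
               overlap_threshold * (t1 - t0))
}

#' Cut labeled training windows from one day
#'
#' Windows of `W_minutes` start at data 1, 1 + S*rate, 1 + 2*S*rate, ...
#' (S = `train_slide_s`); windows running off the end of the recording are
#' dropped. Each window is labeled with [label_window()]. The returned table
#' carries indices only; use [extract_windows()] to materialize the data.
#'
#' @param recording a (preprocessed) [motion_recording()].
#' @param meals ground-truth meal [episode_list()].
#' @param config a [window_config()].
#' @return data frame with columns `source`, `start_datum` (1-based),
#'   `n_samples`, `label`.
#' @export
cut_training_windows <- function(recording, meals, config) {
  rate <- recording$sample_rate
  m <- window_samples(config$W_minutes, rate)
  n <- n_samples(recording)
  step <- as.integer(round(config$train_slide_s * rate))
  if (n < m) {
    warning("recording shorter than one window (", n, " < ", m,
            " samples); no windows cut")
    return(data.frame(source = character(), start_datum = integer(),
                      n_samples = integer(), label = integer()))
  }
  starts <- seq.int(1L, n - m + 1L, by = step)
  t0 <- (starts - 1) / rate
  t1 <- t0 + m / rate
  labels <- vapply(seq_along(starts), function(i)
    label_window(t0[i], t1[i], meals, config$overlap_threshold), integer(1))
  data.frame(source = rep(recording$subject_id, length(starts)),
             start_datum = starts, n_samples = m, label = labels,
             stringsAsFactors = FALSE)
}

#' Balance classes by undersampling non-eating windows
#'
#' Keeps every eating window and draws, uniformly without replacement, an
#' equal number of non-eating windows (all of them, with a warning, if fewer
#' exist). The result is shuffled. Deterministic given `seed`.
#'
#' @param windows window table as returned by [cut_training_windows()]
#'   (possibly row-bound over days).
#' @param seed integer seed for the draw and the shuffle.
#' @return balanced, shuffled window table.
#' @export
balance_undersample <- function(windows, seed) {
  eat <- which(windows$label == 1L)
  non <- which(windows$label == 0L)
  if (length(eat) == 0L)
    stop("cannot balance: no eating windows present")
  withr::with_seed(as.integer(seed), {
    if (length(non) < length(eat)) {
      warning("fewer non-eating (", length(non), ") than eating (",
              length(eat), ") windows; keeping all")
      keep_non <- non
    } else {
      keep_non <- sample(non, length(eat))
    }
    keep <- c(eat, keep_non)
    windows[sample(keep, length(keep)), , drop = FALSE]
  })
}

#' Materialize windows into an array
#'
#' Gathers the raw data behind a window table into a
#' `n_samples x 6 x n_windows` array, the input format of the classifier.
#'
#' @param windows window table (see [cut_training_windows()]).
#' @param recordings a single [motion_recording()] or a list of them; when a
#'   list, recordings are matched to windows by `subject_id` == `source`.
#' @return numeric array of dimension `c(n_samples, 6, nrow(windows))`.
#' @export
extract_windows <- function(windows, recordings) {
  if (inherits(recordings, "motion_recording"))
    recordings <- list(recordings)
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  lookup <- if (length(recordings) == 1L) {
    function(src) recordings[[1L]]
  } else {
    if (!all(windows$source %in% ids))
      stop("window source not found among recordings: ",
           setdiff(windows$source, ids)[1L])
    names(recordings) <- ids
    function(src) recordings[[src]]
  }
  m <- if (nrow(windows)) windows$n_samples[1L] else 0L
  x <- array(0, dim = c(m, 6L, nrow(windows)))
  for (i in seq_len(nrow(windows))) {
    r <- lookup(windows$source[i])
    s <- windows$start_datum[i]
    x[, , i] <- r$data[s:(s + m - 1L), ]
  }
  x
}
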