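#' Preprocessing configuration
#'
#' @param sigma_samples standard deviation of the Gaussian smoothing kernel,
#'   in samples (default 10, i.e. 2/3 s at 15 Hz).
#' @param normalize z-normalize each axis after smoothing (default TRUE).
#' @param stats_scope where normalization statistics come from:
#'   `"recording"` (per day, per axis; default) or `"dataset"` (pooled over
#'   all recordings, see [preprocess_dataset()]).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sigma_samples = 10, normalize = TRUE,
                              stats_scope = c("recording", "dataset")) {
  if (sigma_samples <= 0) stop("sigma_samples must be > 0")
  structure(list(sigma_samples = sigma_samples,
                 normalize = isTRUE(normalize),
                 stats_scope = match.arg(stats_scope)),
            class = "preprocess_config")
}

# Mirror-reflect index mapping (edge sample duplicated), period 2n:
# positions ... 3 2 1 | 1 2 .. n | n n-1 ... extend any integer offset.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Gaussian smoothing of one axis
#'
#' Convolution with a unit-area Gaussian kernel of standard deviation
#' `sigma_samples`, truncated at 4 sigma, with mirror-reflect padding at the
#' edges. Output length equals input length; constants are preserved exactly
#' (up to floating point) because the kernel has unit area.
#'
#' @param signal numeric vector, length >= 1.
#' @param sigma_samples kernel standard deviation in samples.
#' @return smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(signal, sigma_samples = 10) {
  if (sigma_samples <= 0) stop("sigma_samples must be > 0")
  n <- length(signal)
  if (n < 1L) stop("signal must have length >= 1")
  r <- as.integer(ceiling(4 * sigma_samples))
  k <- dnorm(-r:r, sd = sigma_samples)
  k <- k / sum(k)
  padded <- signal[reflect_index(seq.int(1L - r, n + r), n)]
  # symmetric kernel: FFT "filter" convolution == correlation
  as.numeric(convolve(padded, k, type = "filter"))
}

#' z-normalization of one axis
#'
#' Centers to mean 0 and scales to population (1/n) standard deviation 1.
#' A zero-variance axis signals a dead sensor and raises an error.
#'
#' @param signal numeric vector, length >= 2.
#' @return normalized numeric vector.
#' @export
znorm <- function(signal) {
  if (length(signal) < 2L) stop("signal must have length >= 2")
  m <- mean(signal)
  s <- sqrt(mean((signal - m)^2))
  if (!is.finite(s) || s < .Machine$double.eps^0.5 * max(1, abs(m)))
    stop("degenerate signal: zero variance (dead axis?)")
  (signal - m) / s
}

#' Preprocess a recording
#'
#' Smooths each of the 6 axes independently with a Gaussian filter, then
#' (optionally) z-normalizes each axis, in that order. This is the input
#' conditioning expected by the window classifier.
#'
#' @param recording a [motion_recording()].
#' @param config a [preprocess_config()].
#' @return a preprocessed [motion_recording()] of the same shape.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "motion_recording"))
  out <- recording$data
  for (ch in seq_len(6L)) {
    out[, ch] <- tryCatch({
      x <- gaussian_smooth(recording$data[, ch], config$sigma_samples)
      if (config$normalize) x <- znorm(x)
      x
    }, error = function(e) {
      stop("channel ", ch, " (", colnames(recording$data)[ch], "): ",
           conditionMessage(e), call. = FALSE)
    })
  }
  motion_recording(out, recording$sample_rate, recording$subject_id,
                   recording$start_clock)
}

#' Preprocess a set of recordings
#'
#' With `stats_scope = "recording"` each day is handled independently by
#' [preprocess_recording()]. With `"dataset"` each axis is smoothed per day
#' but normalized with mean/sd pooled over all recordings.
#'
#' @param recordings list of [motion_recording()].
#' @param config a [preprocess_config()].
#' @return list of preprocessed recordings.
#' @export
preprocess_dataset <- function(recordings, config = preprocess_config()) {
  if (config$stats_scope == "recording" || !config$normalize)
    return(lapply(recordings, preprocess_recording, config = config))
  smoothed <- lapply(recordings, function(r) {
    d <- r$data
    for (ch in seq_len(6L)) d[, ch] <- gaussian_smooth(d[, ch],
                                                       config$sigma_samples)
    motion_recording(d, r$sample_rate, r$subject_id, r$start_clock)
  })
  pooled <- do.call(rbind, lapply(smoothed, function(r) r$data))
  mu <- colMeans(pooled)
  sig <- sqrt(colMeans(sweep(pooled, 2L, mu)^2))
  if (any(sig < .Machine$double.eps^0.5))
    stop("degenerate axis: zero pooled variance on channel ",
         which(sig < .Machine$double.eps^0.5)[1L])
  lapply(smoothed, function(r) {
    d <- sweep(sweep(r$data, 2L, mu), 2L, sig, "/")
    motion_recording(d, r$sample_rate, r$subject_id, r$start_clock)
  })
}
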