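#' Probability trace
#'
#' A per-datum probability of eating for one recording. The value at datum
#' `t` is the classifier output for the window centered on `t`; within
#' `W/2` of the recording edges no full window fits and the trace is set to
#' 0 (the conservative, non-eating value).
#'
#' @param values numeric vector, one value per datum of the recording.
#' @param valid_range integer `c(first, last)` datum indices covered by a
#'   full window.
#' @param W_minutes window length used.
#' @param stride evaluation stride, in data.
#' @return an object of class `probability_trace`.
#' @export
probability_trace <- function(values, valid_range, W_minutes, stride = 1L) {
  if (any(!is.finite(values))) stop("trace values must be finite")
  inside <- values[seq.int(valid_range[1L], valid_range[2L])]
  if (any(inside < 0 | inside > 1))
    stop("trace values inside the valid range must be in [0, 1]")
  structure(list(values = as.numeric(values),
                 valid_range = as.integer(valid_range),
                 W_minutes = W_minutes, stride = as.integer(stride)),
            class = "probability_trace")
}

#' @export
print.probability_trace <- function(x, ...) {
  cat(sprintf("<probability_trace> %d data; valid [%d, %d]; W=%g min, stride %d\n",
              length(x$values), x$valid_range[1L], x$valid_range[2L],
              x$W_minutes, x$stride))
  invisible(x)
}

#' Slide the classifier across a full day
#'
#' Evaluates the window classifier at starts `1, 1+k, 1+2k, ...`
#' (k = `infer_stride_data`), assigns each probability to the window's
#' center datum (`start + floor(n_samples/2)`), and linearly interpolates
#' between evaluated centers when `k > 1`. Data outside the valid range are
#' assigned probability 0.
#'
#' Because the conv layers are shift-invariant, the stack is evaluated once
#' over the whole recording with dilated kernels (dilation 1, 2, 4 for the
#' three stride-2 layers); the window starting at datum `s` then pools the
#' layer-3 feature rows `s, s+8, s+16, ...`. This is algebraically identical
#' to running the classifier window by window, at a small fraction of the
#' cost.
#'
#' @param model a trained `window_classifier`.
#' @param recording a preprocessed [motion_recording()].
#' @param infer_stride_data evaluation stride in data (default 1, i.e. every
#'   datum; larger values trade trace resolution for speed).
#' @return a [probability_trace()].
#' @export
sliding_probability <- function(model, recording, infer_stride_data = 1L) {
  m <- model$n_samples
  n <- n_samples(recording)
  if (n < m)
    stop("recording (", n, " samples) shorter than one window (", m, ")")
  k <- as.integer(infer_stride_data)
  starts <- seq.int(1L, n - m + 1L, by = k)
  centers <- starts + m %/% 2L
  half <- m %/% 2L
  p <- model$params
  st <- model$config$conv_stride
  y1 <- relu(.conv1d_dilated_forward(recording$data, p$W1, p$b1, 1L))
  y2 <- relu(.conv1d_dilated_forward(y1, p$W2, p$b2, st))
  y3 <- relu(.conv1d_dilated_forward(y2, p$W3, p$b3, st * st))
  n3 <- model$feature_lengths[3L]
  d3 <- st^3                      # spacing of a window's layer-3 features
  G <- matrix(0, length(starts), ncol(y3))
  for (j in 0:(n3 - 1L)) G <- G + y3[starts + d3 * j, , drop = FALSE]
  G <- G / n3
  H <- relu(sweep(G %*% p$W4, 2L, p$b4, "+"))
  probs <- sigmoid(as.numeric(H %*% p$W5) + p$b5)
  values <- numeric(n)
  if (length(centers) == 1L) {
    values[centers] <- probs
  } else {
    fill <- seq.int(centers[1L], centers[length(centers)])
    values[fill] <- approx(centers, probs, xout = fill)$y
  }
  first_center <- 1L + half
  last_center <- (n - m + 1L) + half
  probability_trace(values, c(first_center, last_center),
                    W_minutes = m / recording$sample_rate / 60, stride = k)
}

#' Per-datum boolean mask from episodes or a trace
#'
#' For an [episode_list()], the mask is true exactly on data whose time lies
#' in an episode (`[start_s, end_s)`; datum `i` has time `(i-1)/rate`). For
#' a [probability_trace()] (or plain numeric trace), the mask is
#' `p >= threshold`.
#'
#' @param x an `episode_list`, `probability_trace`, or numeric vector.
#' @param n number of data in the recording.
#' @param rate samples per second.
#' @param threshold probability threshold for trace input (default 0.5).
#' @return logical vector of length `n`.
#' @export
trace_to_mask <- function(x, n, rate = 15, threshold = 0.5) {
  n <- as.integer(n)
  if (inherits(x, "probability_trace")) x <- x$values
  if (is.numeric(x) && !inherits(x, "episode_list")) {
    if (length(x) != n) stop("trace length != n")
    return(x >= threshold)
  }
  stopifnot(inherits(x, "episode_list"))
  mask <- logical(n)
  for (i in seq_len(nrow(x))) {
    if (x$start_s[i] < 0 || x$end_s[i] > n / rate + 1e-9)
      stop("episode ", i, " [", x$start_s[i], ", ", x$end_s[i],
           ") outside recording [0, ", n / rate, ")")
    lo0 <- ceiling(x$start_s[i] * rate - 1e-9)        # first 0-based datum
    hi0 <- ceiling(x$end_s[i] * rate - 1e-9) - 1      # last 0-based datum
    if (hi0 >= lo0) mask[(lo0 + 1L):min(hi0 + 1L, n)] <- TRUE
  }
  mask
}
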