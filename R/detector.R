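#' Detector configuration
#'
#' The hysteresis detector opens a segment when the probability of eating
#' rises strictly above `TS` and closes it when the probability drops
#' strictly below `TE` (TE <= TS). Two thresholds suppress chatter around a
#' single threshold, the same way a debounced button does: a detection needs
#' strong evidence (> TS) to start but only weak evidence (>= TE) to
#' continue, accommodating eating that fades towards the end of a meal.
#' Post-processing merges segments separated by at most `merge_gap_s` and
#' removes segments strictly shorter than `min_len_s`.
#'
#' @param TS start threshold in `[0, 1]` (default 0.8).
#' @param TE end threshold in `[0, 1]`, `TE <= TS` (default 0.4).
#' @param merge_gap_s merge segments within this many seconds (inclusive;
#'   default 60).
#' @param min_len_s drop segments strictly shorter than this (default 60;
#'   ground-truth meals are all at least 1 min long).
#' @return a `detector_config` list.
#' @export
detector_config <- function(TS = 0.8, TE = 0.4, merge_gap_s = 60,
                            min_len_s = 60) {
  if (!(0 <= TE && TE <= TS && TS <= 1))
    stop("thresholds must satisfy 0 <= TE <= TS <= 1 (got TS=", TS,
         ", TE=", TE, ")")
  if (merge_gap_s < 0 || min_len_s < 0)
    stop("merge_gap_s and min_len_s must be >= 0")
  structure(list(TS = TS, TE = TE, merge_gap_s = merge_gap_s,
                 min_len_s = min_len_s),
            class = "detector_config")
}

#' Hysteresis segmentation of a probability trace
#'
#' Two-state scan over the trace: while not eating, the first datum with
#' `p > TS` opens a segment at that datum; while eating, the first datum
#' with `p < TE` closes the segment there (exclusive). A segment still open
#' at the end of the trace is closed after the last datum.
#'
#' @param trace numeric vector (or [probability_trace()]).
#' @param TS,TE start and end thresholds, `TE <= TS`.
#' @return data frame with columns `start_datum`, `end_datum` (1-based,
#'   closed-open), ordered and disjoint.
#' @export
hysteresis_segment <- function(trace, TS = 0.8, TE = 0.4) {
  if (TE > TS) stop("TE must be <= TS")
  if (inherits(trace, "probability_trace")) trace <- trace$values
  if (any(!is.finite(trace))) stop("trace values must be finite")
  n <- length(trace)
  if (n == 0L)
    return(data.frame(start_datum = integer(), end_datum = integer()))
  # signal: +1 forces EATING, -1 forces NOT_EATING, 0 keeps the state;
  # state at i is the most recent nonzero signal (initially NOT_EATING)
  sig <- integer(n)
  sig[trace > TS] <- 1L
  sig[trace < TE] <- -1L
  last_nz <- cummax(ifelse(sig != 0L, seq_len(n), 0L))
  state <- ifelse(last_nz > 0L, sig[pmax(last_nz, 1L)], -1L)
  eating <- state == 1L
  d <- diff(c(FALSE, eating, FALSE))
  data.frame(start_datum = which(d == 1L), end_datum = which(d == -1L))
}

check_sorted_segments <- function(segments) {
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(segments$end_datum <= segments$start_datum))
    stop("segments must have start_datum < end_datum")
  if (nrow(segments) > 1L) {
    if (is.unsorted(segments$start_datum, strictly = FALSE) ||
        any(segments$start_datum[-1L] < segments$end_datum[-nrow(segments)]))
      stop("segments must be sorted and disjoint")
  }
  invisible(segments)
}

#' Merge segments separated by small gaps
#'
#' Left-to-right: while the gap between adjacent segments is at most
#' `merge_gap_s` ("within" is inclusive), the pair is replaced by its hull.
#'
#' @param segments sorted disjoint segment table from [hysteresis_segment()].
#' @param merge_gap_s maximum gap to merge across, seconds.
#' @param rate samples per second.
#' @return merged segment table.
#' @export
merge_close_segments <- function(segments, merge_gap_s = 60, rate = 15) {
  check_sorted_segments(segments)
  if (nrow(segments) <= 1L) return(segments)
  gap_data <- merge_gap_s * rate
  out_start <- segments$start_datum[1L]
  out_end <- segments$end_datum[1L]
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(segments))[-1L]) {
    if (segments$start_datum[i] - out_end[length(out_end)] <= gap_data) {
      out_end[length(out_end)] <- segments$end_datum[i]
    } else {
      out_start <- c(out_start, segments$start_datum[i])
      out_end <- c(out_end, segments$end_datum[i])
    }
  }
  data.frame(start_datum = out_start, end_datum = out_end)
}

#' Drop short segments
#'
#' Removes segments strictly shorter than `min_len_s`; a segment of exactly
#' `min_len_s` is kept.
#'
#' @param segments sorted segment table.
#' @param min_len_s minimum duration in seconds.
#' @param rate samples per second.
#' @return filtered segment table.
#' @export
drop_short_segments <- function(segments, min_len_s = 60, rate = 15) {
  check_sorted_segments(segments)
  keep <- (segments$end_datum - segments$start_datum) / rate >= min_len_s
  segments[keep, , drop = FALSE]
}

#' Detect eating episodes from a probability trace
#'
#' Composition of [hysteresis_segment()], [merge_close_segments()] and
#' [drop_short_segments()], in that order, returned in seconds.
#'
#' @param trace a [probability_trace()] or numeric vector.
#' @param config a [detector_config()].
#' @param rate samples per second.
#' @return an [episode_list()] of detections (label `"eating"`).
#' @export
detect_episodes <- function(trace, config = detector_config(), rate = 15) {
  seg <- hysteresis_segment(trace, config$TS, config$TE)
  seg <- merge_close_segments(seg, config$merge_gap_s, rate)
  seg <- drop_short_segments(seg, config$min_len_s, rate)
  episode_list(start_s = (seg$start_datum - 1) / rate,
               end_s = (seg$end_datum - 1) / rate,
               label = "eating")
}
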