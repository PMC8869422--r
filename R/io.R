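#' Construct a motion recording
#'
#' A motion recording is one continuous stretch (typically a full waking day)
#' of 6-axis wrist-motion samples at a fixed rate. Channel order is
#' `a_x, a_y, a_z, w_x, w_y, w_z` (linear acceleration then angular
#' velocity); units are passed through untouched. Datum `i` (1-based)
#' covers time `[(i-1)/sample_rate, i/sample_rate)` seconds from the start
#' of the recording.
#'
#' @param data numeric matrix with 6 columns (one row per sample).
#' @param sample_rate samples per second (default 15).
#' @param subject_id opaque subject identifier.
#' @param start_clock optional wall-clock offset in seconds, for reporting
#'   only; all internal computation is relative to the recording start.
#' @return an object of class `motion_recording`.
#' @export
motion_recording <- function(data, sample_rate = 15, subject_id = "",
                             start_clock = NULL) {
  data <- as.matrix(data)
  if (length(data) == 0L) data <- matrix(numeric(0), nrow = 0L, ncol = 6L)
  if (ncol(data) != 6L)
    stop("motion recording must have exactly 6 channels, got ", ncol(data))
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data))[1L]
    stop("non-finite value at datum ", ((bad - 1L) %% nrow(data)) + 1L,
         ", channel ", ((bad - 1L) %/% nrow(data)) + 1L)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  colnames(data) <- c("a_x", "a_y", "a_z", "w_x", "w_y", "w_z")
  structure(list(data = data, sample_rate = sample_rate,
                 subject_id = as.character(subject_id),
                 start_clock = start_clock),
            class = "motion_recording")
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf("<motion_recording> subject=%s  %d samples @ %g Hz (%.1f min)\n",
              if (nzchar(x$subject_id)) x$subject_id else "?",
              nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate / 60))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording a `motion_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$data)

#' Construct an episode list
#'
#' An ordered set of non-overlapping labeled time intervals, used both for
#' ground-truth meals and for detected eating episodes. Intervals are
#' closed-open `[start_s, end_s)` in seconds from recording start.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param label character vector of labels (recycled), e.g. `"meal"`.
#' @param reference identifier of the recording the episodes annotate.
#' @param check_overlap error if any two episodes overlap (default TRUE).
#' @return a data frame of class `episode_list`, sorted by `start_s`.
#' @export
episode_list <- function(start_s = numeric(), end_s = numeric(),
                         label = "meal", reference = "",
                         check_overlap = TRUE) {
  if (length(start_s) != length(end_s))
    stop("start_s and end_s must have equal length")
  bad <- which(!(start_s < end_s))
  if (length(bad))
    stop("episode ", bad[1L], " has end <= start (",
         start_s[bad[1L]], " >= ", end_s[bad[1L]], ")")
  o <- order(start_s, end_s)
  df <- data.frame(start_s = as.numeric(start_s)[o],
                   end_s = as.numeric(end_s)[o],
                   label = rep_len(as.character(label), length(start_s))[o],
                   stringsAsFactors = FALSE)
  if (check_overlap && nrow(df) > 1L) {
    ov <- which(df$start_s[-1L] < df$end_s[-nrow(df)])
    if (length(ov))
      stop("episodes ", ov[1L], " and ", ov[1L] + 1L, " overlap")
  }
  attr(df, "reference") <- as.character(reference)
  class(df) <- c("episode_list", "data.frame")
  df
}

#' Read a flat-binary 6-axis recording
#'
#' The on-disk format is a headerless flat sequence of little-endian floats,
#' six per sample in the order `a_x, a_y, a_z, w_x, w_y, w_z` -- the layout
#' used by day-long Shimmer3 wrist logs.
#'
#' @param path file to read.
#' @param sample_rate samples per second of the recording (default 15).
#' @param float_width bytes per float: 4 (default) or 8.
#' @param subject_id subject identifier to attach.
#' @return a [motion_recording()].
#' @export
read_cad_recording <- function(path, sample_rate = 15, float_width = 4,
                               subject_id = "") {
  if (!float_width %in% c(4, 8)) stop("float_width must be 4 or 8")
  size <- file.size(path)
  if (is.na(size)) stop("cannot read file: ", path)
  bytes_per_sample <- 6L * float_width
  if (size %% bytes_per_sample != 0L)
    stop("malformed file: ", size %% bytes_per_sample,
         " trailing bytes beyond a whole 6-channel sample (", path, ")")
  n <- size %/% bytes_per_sample
  vals <- readBin(path, what = "numeric", n = 6L * n, size = float_width,
                  endian = "little")
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals))[1L]
    stop("non-finite value at flat position ", bad,
         " (datum ", (bad - 1L) %/% 6L + 1L, ")")
  }
  motion_recording(matrix(vals, ncol = 6L, byrow = TRUE),
                   sample_rate = sample_rate, subject_id = subject_id)
}

#' Write a recording in the flat-binary format
#'
#' Inverse of [read_cad_recording()]: samples are written interleaved
#' (`a_x, a_y, a_z, w_x, w_y, w_z` per sample) as little-endian floats.
#' Note that with `float_width = 4` values are quantized to single
#' precision; use 8 for an exact round trip of double data.
#'
#' @param recording a [motion_recording()].
#' @param path output file.
#' @param float_width bytes per float: 4 (default) or 8.
#' @return `path`, invisibly.
#' @export
write_cad_recording <- function(recording, path, float_width = 4) {
  stopifnot(inherits(recording, "motion_recording"))
  if (!float_width %in% c(4, 8)) stop("float_width must be 4 or 8")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = float_width,
           endian = "little")
  invisible(path)
}

#' Read / write episode annotations
#'
#' Annotations are a CSV table with header `start_s,end_s,label`; times are
#' seconds from recording start. The reader validates and sorts; overlapping
#' episodes are rejected.
#'
#' @param path CSV file.
#' @param reference recording identifier to attach.
#' @return an [episode_list()].
#' @export
read_episode_list <- function(path, reference = "") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns start_s,end_s[,label]: ", path)
  if (is.null(df$label)) df$label <- "meal"
  bad <- which(!(df$start_s < df$end_s))
  if (length(bad))
    stop("row ", bad[1L], ": end_s <= start_s in ", path)
  episode_list(df$start_s, df$end_s, df$label, reference = reference)
}

#' @param episodes an [episode_list()].
#' @rdname read_episode_list
#' @export
write_episode_list <- function(episodes, path) {
  stopifnot(inherits(episodes, "episode_list"))
  write.csv(as.data.frame(episodes)[, c("start_s", "end_s", "label")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a probability trace
#'
#' Traces are stored as a single-column CSV (header `p`, one value per
#' datum). [write_probability_trace()] stores only the values; on reading,
#' the whole trace is treated as valid.
#'
#' @param path CSV file.
#' @return numeric vector of per-datum probabilities.
#' @export
read_probability_trace <- function(path) {
  df <- read.csv(path)
  as.numeric(df[[1L]])
}

#' @param values numeric vector, or a `probability_trace`.
#' @rdname read_probability_trace
#' @export
write_probability_trace <- function(values, path) {
  if (inherits(values, "probability_trace")) values <- values$values
  write.csv(data.frame(p = as.numeric(values)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
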