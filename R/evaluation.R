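#' Match detections against ground-truth meals
#'
#' Episode-level confusion: a meal with any positive overlap with a
#' detection is a true positive (TP); a meal with none is a miss; a
#' detection overlapping no meal is a false positive (FP). One detection
#' covering k meals yields k TPs (each meal is evaluated on its own); one
#' meal covered by k detections yields a single TP. Touching endpoints
#' (`[a,b)` vs `[b,c)`) do not overlap. True negatives are undefined at the
#' episode level.
#'
#' @param meals ground-truth [episode_list()] (non-overlapping).
#' @param detections detected [episode_list()] (non-overlapping).
#' @return an `episode_confusion` object with counts `TP`, `FP`, `Miss`, a
#'   per-meal table (matched flag, first/last overlapping detection bounds)
#'   and the FP detection indices.
#' @export
match_episodes <- function(meals, detections) {
  stopifnot(inherits(meals, "episode_list"),
            inherits(detections, "episode_list"))
  n_meal <- nrow(meals); n_det <- nrow(detections)
  meal_hit <- logical(n_meal)
  det_hit <- logical(n_det)
  first_start <- rep(NA_real_, n_meal)
  last_end <- rep(NA_real_, n_meal)
  for (i in seq_len(n_meal)) {
    ov <- which(pmin(meals$end_s[i], detections$end_s) >
                  pmax(meals$start_s[i], detections$start_s))
    if (length(ov)) {
      meal_hit[i] <- TRUE
      det_hit[ov] <- TRUE
      first_start[i] <- detections$start_s[min(ov)]
      last_end[i] <- detections$end_s[max(ov)]
    }
  }
  per_meal <- data.frame(start_s = meals$start_s, end_s = meals$end_s,
                         matched = meal_hit,
                         det_first_start_s = first_start,
                         det_last_end_s = last_end)
  structure(list(TP = sum(meal_hit), Miss = sum(!meal_hit),
                 FP = sum(!det_hit), n_meals = n_meal,
                 n_detections = n_det, per_meal = per_meal,
                 fp_detections = which(!det_hit)),
            class = "episode_confusion")
}

#' @export
print.episode_confusion <- function(x, ...) {
  cat(sprintf("<episode_confusion> TP=%d  Miss=%d  FP=%d (of %d meals, %d detections)\n",
              x$TP, x$Miss, x$FP, x$n_meals, x$n_detections))
  invisible(x)
}

#' Episode-level summary metrics
#'
#' `TPR = TP / (TP + Miss)`, `FP/TP = FP / TP` and `FP/day = FP / n_days`.
#' With zero TPs, `FP_per_TP` is returned as `NA` with attribute
#' `undefined = TRUE` rather than raising, so sweeps over extreme thresholds
#' keep running.
#'
#' @param confusion an `episode_confusion` from [match_episodes()], or a
#'   list with elements `TP`, `Miss`, `FP`.
#' @param n_days number of recording days the detections cover.
#' @return list with `TPR`, `FP_per_TP`, `FP_per_day`.
#' @export
episode_metrics <- function(confusion, n_days) {
  if (n_days <= 0) stop("n_days must be > 0")
  TP <- confusion$TP; Miss <- confusion$Miss; FP <- confusion$FP
  if (TP + Miss <= 0) stop("no ground-truth meals (TP + Miss == 0)")
  fp_tp <- if (TP > 0) FP / TP else structure(NA_real_, undefined = TRUE)
  list(TPR = TP / (TP + Miss), FP_per_TP = fp_tp, FP_per_day = FP / n_days)
}

#' Boundary errors of matched episodes
#'
#' For every TP meal, the start error is `(start of first overlapping
#' detection - meal start)` and the end error `(end of last overlapping
#' detection - meal end)`, both in minutes. Negative start error means the
#' detection began before the self-reported start.
#'
#' @param confusion an `episode_confusion` from [match_episodes()].
#' @return list with `start_mean_min`, `start_sd_min`, `end_mean_min`,
#'   `end_sd_min` and the per-meal error table.
#' @export
boundary_errors <- function(confusion) {
  pm <- confusion$per_meal[confusion$per_meal$matched, , drop = FALSE]
  if (nrow(pm) == 0L) stop("no true positives; boundary errors undefined")
  start_err <- (pm$det_first_start_s - pm$start_s) / 60
  end_err <- (pm$det_last_end_s - pm$end_s) / 60
  list(start_mean_min = mean(start_err),
       start_sd_min = if (length(start_err) > 1L) sd(start_err) else 0,
       end_mean_min = mean(end_err),
       end_sd_min = if (length(end_err) > 1L) sd(end_err) else 0,
       per_meal = data.frame(start_err_min = start_err,
                             end_err_min = end_err))
}

#' Datum-level classification metrics
#'
#' Standard confusion-matrix ratios over per-datum masks: precision,
#' recall (TPR), true-negative rate, F1, and weighted accuracy `ACC_W`
#' defined as balanced accuracy `(recall + TNR) / 2`. Degenerate
#' denominators yield `NA` with attribute `undefined = TRUE`.
#'
#' @param truth_mask,pred_mask equal-length logical vectors.
#' @return list with `precision`, `recall`, `TNR`, `F1`, `ACC_W`.
#' @export
datum_metrics <- function(truth_mask, pred_mask) {
  if (length(truth_mask) == 0L) stop("empty masks")
  if (length(truth_mask) != length(pred_mask))
    stop("masks must have equal length")
  truth_mask <- as.logical(truth_mask); pred_mask <- as.logical(pred_mask)
  tp <- sum(truth_mask & pred_mask)
  fp <- sum(!truth_mask & pred_mask)
  fn <- sum(truth_mask & !pred_mask)
  tn <- sum(!truth_mask & !pred_mask)
  ratio <- function(num, den)
    if (den > 0) num / den else structure(NA_real_, undefined = TRUE)
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  tnr <- ratio(tn, tn + fp)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else structure(NA_real_, undefined = TRUE)
  accw <- if (!is.na(recall) && !is.na(tnr)) (recall + tnr) / 2
          else structure(NA_real_, undefined = TRUE)
  list(precision = precision, recall = recall, TNR = tnr, F1 = f1,
       ACC_W = accw)
}

#' Percent reduction of an error
#'
#' `100 * (reference - new) / reference`: how much smaller `new` is than
#' `reference`, in percent.
#'
#' @param reference baseline value.
#' @param new improved value.
#' @return percent reduction.
#' @export
percent_reduction <- function(reference, new) {
  if (reference == 0) stop("reference must be nonzero")
  100 * (reference - new) / reference
}
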