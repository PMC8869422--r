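#' Subject-wise fold assignment
#'
#' Subjects are shuffled deterministically and dealt round-robin into `k`
#' folds, so fold sizes differ by at most one and every recording of a
#' subject lands in exactly one fold. Splitting by subject (rather than by
#' day) prevents a person's data from leaking between training and testing.
#'
#' @param subject_ids character vector of subject ids (repeats allowed; one
#'   id per recording is fine).
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return named integer vector mapping each unique subject id to a fold in
#'   `1..k`, with attributes `k` and `seed`.
#' @export
split_subjects <- function(subject_ids, k = 5L, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < k)
    stop("need at least k = ", k, " subjects, got ", length(ids))
  assignment <- withr::with_seed(as.integer(seed), {
    shuffled <- sample(ids)
    structure(rep_len(seq_len(k), length(ids)), names = shuffled)
  })
  assignment <- assignment[ids]   # restore input order of names
  attr(assignment, "k") <- as.integer(k)
  attr(assignment, "seed") <- as.integer(seed)
  assignment
}

dataset_subjects <- function(dataset)
  vapply(dataset, function(d) d$recording$subject_id, character(1))

#' Train and evaluate one cross-validation fold
#'
#' Trains the window classifier on every day whose subject is outside
#' `test_fold` (windows cut with the training slide, labeled, class-balanced
#' by undersampling), then scores the held-out days: a probability trace is
#' computed for each test day, episodes are detected and matched against the
#' ground truth, and window accuracy is measured on class-balanced held-out
#' windows. Raises if any test subject appears in the training windows
#' (leakage guard).
#'
#' @param dataset list of `list(recording, meals)` (preprocessed; see
#'   [preprocess_dataset()] or pass `preprocess = TRUE`).
#' @param split fold assignment from [split_subjects()].
#' @param test_fold fold index used for testing.
#' @param window_cfg a [window_config()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param detector_cfg a [detector_config()].
#' @param infer_stride_data inference stride in data (default 15, i.e. 1 s).
#' @param preprocess smooth/normalize each day first (default FALSE: data
#'   assumed already preprocessed).
#' @param keep_traces also return the per-test-day probability traces (used
#'   by threshold sweeps).
#' @return a metrics report: window accuracy, episode metrics, boundary
#'   errors, datum-level metrics, counts, and optionally traces.
#' @export
run_fold <- function(dataset, split, test_fold, window_cfg,
                     model_cfg = model_config(),
                     train_cfg = train_config(),
                     detector_cfg = detector_config(),
                     infer_stride_data = 15L, preprocess = FALSE,
                     keep_traces = FALSE) {
  subjects <- dataset_subjects(dataset)
  in_test <- split[subjects] == test_fold
  if (!any(in_test)) stop("fold ", test_fold, " has no test days")
  if (!any(!in_test)) stop("fold ", test_fold, " has no training days")
  if (preprocess)
    dataset <- lapply(dataset, function(d) {
      d$recording <- preprocess_recording(d$recording)
      d
    })
  rate <- dataset[[1L]]$recording$sample_rate

  cut_all <- function(days) {
    do.call(rbind, lapply(days, function(d)
      cut_training_windows(d$recording, d$meals, window_cfg)))
  }
  train_windows <- cut_all(dataset[!in_test])
  # leakage guard: no window may originate from a test subject
  test_subjects <- unique(subjects[in_test])
  if (any(train_windows$source %in% test_subjects))
    stop("subject leakage: test subject found among training windows")
  balanced <- balance_undersample(train_windows, seed = train_cfg$seed)
  recs <- lapply(dataset, function(d) d$recording)
  x_train <- extract_windows(balanced, recs)
  model <- build_model(model_cfg,
                       n_samples = window_samples(window_cfg$W_minutes, rate),
                       seed = train_cfg$seed)
  model <- train_model(model, x_train, balanced$label, train_cfg)

  # held-out window accuracy on a class-balanced set
  test_windows <- cut_all(dataset[in_test])
  test_balanced <- balance_undersample(test_windows,
                                       seed = train_cfg$seed + 1L)
  p_test <- predict_windows(model, extract_windows(test_balanced, recs))
  win_acc <- window_accuracy(p_test, test_balanced$label)

  # per-day detection and scoring
  TP <- 0L; FP <- 0L; Miss <- 0L
  start_errs <- numeric(); end_errs <- numeric()
  truth_all <- logical(); pred_all <- logical()
  traces <- list()
  for (d in dataset[in_test]) {
    trace <- sliding_probability(model, d$recording, infer_stride_data)
    detections <- detect_episodes(trace, detector_cfg, rate)
    conf <- match_episodes(d$meals, detections)
    TP <- TP + conf$TP; FP <- FP + conf$FP; Miss <- Miss + conf$Miss
    if (conf$TP > 0) {
      be <- boundary_errors(conf)
      start_errs <- c(start_errs, be$per_meal$start_err_min)
      end_errs <- c(end_errs, be$per_meal$end_err_min)
    }
    n <- n_samples(d$recording)
    truth_all <- c(truth_all, trace_to_mask(d$meals, n, rate))
    pred_all <- c(pred_all, trace_to_mask(detections, n, rate))
    if (keep_traces)
      traces[[d$recording$subject_id]] <- list(trace = trace,
                                               meals = d$meals, n = n)
  }
  n_days <- sum(in_test)
  confusion <- list(TP = TP, Miss = Miss, FP = FP)
  em <- episode_metrics(confusion, n_days)
  report <- list(
    fold = test_fold, n_days = n_days,
    window_accuracy = win_acc,
    TPR = em$TPR, FP_per_TP = em$FP_per_TP, FP_per_day = em$FP_per_day,
    TP = TP, FP = FP, Miss = Miss,
    start_err_mean_min = if (length(start_errs)) mean(start_errs) else NA_real_,
    start_err_sd_min = if (length(start_errs) > 1) sd(start_errs) else NA_real_,
    end_err_mean_min = if (length(end_errs)) mean(end_errs) else NA_real_,
    end_err_sd_min = if (length(end_errs) > 1) sd(end_errs) else NA_real_,
    boundary_abs_err_mean_min = if (length(start_errs))
      mean(abs(c(start_errs, end_errs))) else NA_real_,
    datum = datum_metrics(truth_all, pred_all),
    history = model$history)
  if (keep_traces) {
    report$traces <- traces
    report$model <- model
  }
  report
}

crossval_numeric_fields <- c("window_accuracy", "TPR", "FP_per_TP",
                             "FP_per_day", "start_err_mean_min",
                             "end_err_mean_min")

#' Subject-wise k-fold cross-testing
#'
#' Runs [run_fold()] with each fold held out once and aggregates the fold
#' reports (per-metric mean, min, max). Per-fold spread is worth inspecting:
#' fold-to-fold differences of several percent are normal for this kind of
#' data.
#'
#' @inheritParams run_fold
#' @param k number of folds.
#' @param seed seed for the subject split (fold training seeds are derived
#'   as `seed + fold`).
#' @return list with `folds` (list of fold reports) and `aggregate`
#'   (data frame of mean/min/max per metric).
#' @export
run_crossval <- function(dataset, k = 5L, window_cfg,
                         model_cfg = model_config(),
                         train_cfg = train_config(),
                         detector_cfg = detector_config(),
                         infer_stride_data = 15L, seed = 1L,
                         preprocess = FALSE, keep_traces = FALSE) {
  split <- split_subjects(dataset_subjects(dataset), k, seed)
  folds <- lapply(seq_len(k), function(f) {
    tc <- train_cfg
    tc$seed <- as.integer(seed + f)
    run_fold(dataset, split, f, window_cfg, model_cfg, tc, detector_cfg,
             infer_stride_data, preprocess = preprocess,
             keep_traces = keep_traces)
  })
  agg <- do.call(rbind, lapply(crossval_numeric_fields, function(m) {
    v <- vapply(folds, function(f) as.numeric(f[[m]]), numeric(1))
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  }))
  list(folds = folds, aggregate = agg, split = split)
}

#' Hyperparameter sweep
#'
#' One-at-a-time sweeps over the window length `W` or the detector
#' thresholds `TS` / `TE`. Threshold sweeps reuse the trained fold models
#' and their cached probability traces (re-thresholding is cheap); only a
#' `W` sweep retrains.
#'
#' @param axis `"W"`, `"TS"` or `"TE"`.
#' @param values numeric vector of axis values.
#' @inheritParams run_crossval
#' @return a `sweep_result`: data frame with one row per axis value (pooled
#'   episode metrics plus mean boundary errors across all held-out days).
#' @export
sweep_hyperparam <- function(axis = c("W", "TS", "TE"), values, dataset,
                             k = 5L,
                  window_cfg, model_cfg = model_config(),
                  train_cfg = train_config(),
                  detector_cfg = detector_config(),
                  infer_stride_data = 15L, seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1L)
  if (axis == "W") {
    rows <- lapply(values, function(W) {
      wc <- window_cfg
      wc$W_minutes <- W
      cv <- run_crossval(dataset, k, wc, model_cfg, train_cfg, detector_cfg,
                         infer_stride_data, seed)
      a <- cv$aggregate
      cbind(data.frame(value = W),
            as.data.frame(as.list(structure(a$mean, names = a$metric))))
    })
    out <- do.call(rbind, rows)
  } else {
    cv <- run_crossval(dataset, k, window_cfg, model_cfg, train_cfg,
                       detector_cfg, infer_stride_data, seed,
                       keep_traces = TRUE)
    day_traces <- do.call(c, lapply(cv$folds, function(f) f$traces))
    rate <- dataset[[1L]]$recording$sample_rate
    rows <- lapply(values, function(v) {
      dc <- detector_cfg
      dc[[axis]] <- v
      if (dc$TE > dc$TS) stop("sweep value makes TE > TS (", axis, "=", v, ")")
      TP <- 0L; FP <- 0L; Miss <- 0L
      start_errs <- numeric(); end_errs <- numeric()
      for (dt in day_traces) {
        detections <- detect_episodes(dt$trace, dc, rate)
        conf <- match_episodes(dt$meals, detections)
        TP <- TP + conf$TP; FP <- FP + conf$FP; Miss <- Miss + conf$Miss
        if (conf$TP > 0) {
          be <- boundary_errors(conf)
          start_errs <- c(start_errs, be$per_meal$start_err_min)
          end_errs <- c(end_errs, be$per_meal$end_err_min)
        }
      }
      em <- episode_metrics(list(TP = TP, Miss = Miss, FP = FP),
                            n_days = length(day_traces))
      data.frame(value = v, TPR = em$TPR,
                 FP_per_TP = as.numeric(em$FP_per_TP),
                 FP_per_day = em$FP_per_day,
                 start_err_mean_min = if (length(start_errs))
                   mean(start_errs) else NA_real_,
                 end_err_mean_min = if (length(end_errs))
                   mean(end_errs) else NA_real_)
    })
    out <- do.call(rbind, rows)
  }
  structure(out, axis = axis, class = c("sweep_result", "data.frame"))
}
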