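#' Synthetic-data parameters
#'
#' Parameters of the synthetic day generator. Defaults emulate the
#' statistical structure the detector assumes in free-living wrist-motion
#' data: 13 h waking-day recordings at 15 Hz; 1-6 meals per day (Poisson
#' with mean 3, clamped to at least 1); right-skewed meal durations
#' (log-normal with median 11 min, spread set so the mean is ~14 min,
#' truncated at 1 min); meals built from bite gestures (3-5 s of large wrist
#' rotation with small linear motion) separated by prep and rest gestures;
#' background that mixes rest, cyclic walking (~1.5-2 Hz), and occasional
#' isolated bite-like confounder gestures (default 2/h) that exercise the
#' detector's false-positive behavior.
#'
#' @param day_length_h recording length in hours.
#' @param sample_rate samples per second.
#' @param meals_per_day_mean Poisson mean of the meal count.
#' @param meals_min,meals_max clamp on the meal count.
#' @param meal_dur_median_min,meal_dur_mean_min log-normal duration targets
#'   (minutes); the log-sd is derived as `sqrt(2*log(mean/median))`.
#' @param meal_dur_min_min truncation floor for meal duration (minutes).
#' @param bite_interval_s mean gap between bite gestures inside a meal.
#' @param bite_duration_s range of bite gesture durations, seconds.
#' @param prep_fraction fraction of between-bite time spent in active
#'   prep/manipulation gestures rather than rest.
#' @param background_mix named proportions of `rest` and `walk` background.
#' @param confounder_rate_per_h rate of isolated bite-like gestures outside
#'   meals.
#' @param noise_sd white measurement noise added to every channel.
#' @return a `synth_params` list.
#' @export
synth_params <- function(day_length_h = 13, sample_rate = 15,
                         meals_per_day_mean = 3, meals_min = 1L,
                         meals_max = 6L, meal_dur_median_min = 11,
                         meal_dur_mean_min = 14, meal_dur_min_min = 1,
                         bite_interval_s = 20, bite_duration_s = c(3, 5),
                         prep_fraction = 0.18,
                         background_mix = c(rest = 0.65, walk = 0.35),
                         confounder_rate_per_h = 2, noise_sd = 0.05) {
  stopifnot(day_length_h > 0, sample_rate > 0, meals_min >= 0,
            meals_max >= meals_min, meal_dur_min_min > 0,
            meal_dur_mean_min >= meal_dur_median_min,
            bite_interval_s > 0, length(bite_duration_s) == 2L,
            all(bite_duration_s > 0), prep_fraction >= 0,
            prep_fraction <= 1, confounder_rate_per_h >= 0, noise_sd >= 0)
  background_mix <- background_mix / sum(background_mix)
  structure(list(day_length_h = day_length_h, sample_rate = sample_rate,
                 meals_per_day_mean = meals_per_day_mean,
                 meals_min = as.integer(meals_min),
                 meals_max = as.integer(meals_max),
                 meal_dur_median_min = meal_dur_median_min,
                 meal_dur_mean_min = meal_dur_mean_min,
                 meal_dur_min_min = meal_dur_min_min,
                 bite_interval_s = bite_interval_s,
                 bite_duration_s = bite_duration_s,
                 prep_fraction = prep_fraction,
                 background_mix = background_mix,
                 confounder_rate_per_h = confounder_rate_per_h,
                 noise_sd = noise_sd),
            class = "synth_params")
}

# --- gesture kernels -------------------------------------------------------
# Each returns an n x 6 matrix (a_x a_y a_z, w_x w_y w_z). Amplitudes are in
# arbitrary (pass-through) units; what matters is their structure relative
# to each other: bites are rotation-dominant, walking is cyclic and
# acceleration-dominant, rest is near-still.

# slow random wander: AR(1) noise (time constant ~0.8 s at 15 Hz) rescaled
# to the requested sd; low-frequency content survives the sigma=10 smoothing
lowfreq_noise <- function(n, sd_target, rho = 0.92) {
  if (n <= 2L || sd_target == 0) return(numeric(n))
  x <- as.numeric(stats::filter(rnorm(n), rho, method = "recursive"))
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(numeric(n))
  x / s * sd_target
}

gesture_rest <- function(n, params) {
  out <- matrix(0, n, 6L)
  for (ch in 1:3) out[, ch] <- lowfreq_noise(n, 0.06)
  for (ch in 4:6) out[, ch] <- lowfreq_noise(n, 0.04)
  out
}

gesture_walk <- function(n, params) {
  rate <- params$sample_rate
  f <- runif(1, 1.5, 2)                 # step frequency, Hz
  t <- (seq_len(n) - 1) / rate
  out <- matrix(0, n, 6L)
  for (ch in 1:3) {
    amp <- runif(1, 0.6, 1)
    out[, ch] <- amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
      lowfreq_noise(n, 0.05)
  }
  for (ch in 4:6)
    out[, ch] <- 0.15 * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
      lowfreq_noise(n, 0.04)
  out
}

# hand-to-mouth ingestion gesture: a smooth rotation bump, large on the
# gyro channels and small on the accelerometer
gesture_bite <- function(n, params) {
  bump <- sin(pi * (seq_len(n) - 0.5) / n)       # half-sine envelope
  out <- matrix(0, n, 6L)
  for (ch in 1:3) {
    amp <- runif(1, 0.1, 0.3) * sample(c(-1, 1), 1)
    out[, ch] <- amp * bump + lowfreq_noise(n, 0.05)
  }
  amps <- runif(3, 1.2, 2.2) * sample(c(-1, 1), 3, replace = TRUE)
  dom <- sample.int(3, 1)
  amps[dom] <- amps[dom] * 1.5          # one dominant rotation axis
  for (ch in 4:6)
    out[, ch] <- amps[ch - 3L] * bump + lowfreq_noise(n, 0.05)
  out
}

# food preparation / manipulation: moderate irregular motion on all axes
gesture_prep <- function(n, params) {
  out <- matrix(0, n, 6L)
  for (ch in 1:3) out[, ch] <- lowfreq_noise(n, 0.25)
  for (ch in 4:6) out[, ch] <- lowfreq_noise(n, 0.5)
  out
}

gesture_confounder <- function(n, params) gesture_bite(n, params)

#' Generate one gesture snippet
#'
#' Exposed mainly so the kernels' structural invariants can be checked:
#' bites are rotation-dominant (gyro RMS > accel RMS), walking is cyclic
#' with a 1.5-2 Hz spectral peak on the accelerometer channels.
#'
#' @param name one of `"bite"`, `"prep"`, `"rest"`, `"walk"`,
#'   `"confounder"`.
#' @param duration_s snippet duration in seconds.
#' @param params a [synth_params()].
#' @return an `n x 6` numeric matrix.
#' @export
gesture_kernel <- function(name = c("bite", "prep", "rest", "walk",
                                    "confounder"),
                           duration_s, params = synth_params()) {
  name <- match.arg(name)
  n <- max(2L, as.integer(round(duration_s * params$sample_rate)))
  switch(name,
         bite = gesture_bite(n, params),
         prep = gesture_prep(n, params),
         rest = gesture_rest(n, params),
         walk = gesture_walk(n, params),
         confounder = gesture_confounder(n, params))
}

# a meal: alternating {gap, bite} where gaps split into prep/rest
make_meal <- function(dur_s, params) {
  rate <- params$sample_rate
  n <- as.integer(round(dur_s * rate))
  out <- gesture_rest(n, params)
  pos <- 1L
  while (pos < n) {
    gap_s <- rgamma(1, shape = 2, scale = (params$bite_interval_s - 4) / 2)
    gap_n <- as.integer(round(gap_s * rate))
    # gaps make up ~(interval - bite)/interval of a meal; scale the prep
    # probability so prep occupies ~prep_fraction of the whole meal
    p_prep <- min(1, params$prep_fraction * params$bite_interval_s /
                       max(1, params$bite_interval_s - 4))
    if (gap_n > 1L && pos + gap_n <= n) {
      if (runif(1) < p_prep) {
        out[pos:(pos + gap_n - 1L), ] <- gesture_prep(gap_n, params)
      }
      pos <- pos + gap_n
    } else {
      break
    }
    bite_s <- runif(1, params$bite_duration_s[1L], params$bite_duration_s[2L])
    bite_n <- as.integer(round(bite_s * rate))
    if (pos + bite_n > n) break
    out[pos:(pos + bite_n - 1L), ] <- gesture_bite(bite_n, params)
    pos <- pos + bite_n
  }
  out
}

draw_meal_durations <- function(m, params) {
  meanlog <- log(params$meal_dur_median_min * 60)
  sdlog <- sqrt(2 * log(params$meal_dur_mean_min / params$meal_dur_median_min))
  d <- rlnorm(m, meanlog, sdlog)
  pmax(d, params$meal_dur_min_min * 60)
}

#' Generate one synthetic day
#'
#' Builds a full day of 6-axis motion: a background tiling of rest and walk
#' segments with occasional isolated confounder gestures, and non-overlapping
#' meals (each a prep/bite/rest gesture sequence) whose hulls become the
#' ground-truth annotations. Deterministic given `seed`.
#'
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @param subject_id id to attach to the recording.
#' @return list with elements `recording` ([motion_recording()]) and
#'   `meals` ([episode_list()]).
#' @export
generate_day <- function(params = synth_params(), seed = 1L,
                         subject_id = "S001") {
  withr::with_seed(as.integer(seed), {
    rate <- params$sample_rate
    n <- as.integer(round(params$day_length_h * 3600 * rate))
    day_s <- n / rate

    # meal count and durations
    m <- min(max(rpois(1, params$meals_per_day_mean), params$meals_min),
             params$meals_max)
    durs <- if (m > 0) draw_meal_durations(m, params) else numeric()
    margin <- 180                      # seconds kept clear around meals
    free <- day_s - sum(durs) - (m + 1) * margin
    if (free < 0)
      stop("meal placement failed: meals (", round(sum(durs)),
           " s) do not fit in the day")
    # split the free time into m+1 gaps (Dirichlet via gamma weights)
    w <- rgamma(m + 1, shape = 1)
    gaps <- margin + free * w / sum(w)
    starts_s <- cumsum(c(0, durs)) + cumsum(gaps)
    starts_s <- starts_s[seq_len(m)]

    # background tiling
    data <- matrix(0, n, 6L)
    pos <- 1L
    while (pos <= n) {
      seg_n <- min(as.integer(round(runif(1, 30, 120) * rate)), n - pos + 1L)
      kind <- sample(names(params$background_mix), 1,
                     prob = params$background_mix)
      data[pos:(pos + seg_n - 1L), ] <-
        if (kind == "walk") gesture_walk(seg_n, params)
        else gesture_rest(seg_n, params)
      pos <- pos + seg_n
    }

    # meals overwrite background
    meal_start_idx <- as.integer(round(starts_s * rate)) + 1L
    for (i in seq_len(m)) {
      mi <- meal_start_idx[i]
      mn <- as.integer(round(durs[i] * rate))
      data[mi:(mi + mn - 1L), ] <- make_meal(durs[i], params)
    }
    meal_start_s <- (meal_start_idx - 1) / rate
    meal_end_s <- meal_start_s + round(durs * rate) / rate

    # isolated confounder gestures outside meals
    n_conf <- rpois(1, params$confounder_rate_per_h * params$day_length_h)
    placed <- 0L; tries <- 0L
    while (placed < n_conf && tries < 50L * n_conf) {
      tries <- tries + 1L
      cs <- runif(1, 0, day_s - 10)
      # keep clear of meals so annotations stay exact
      if (m > 0 && any(cs + 10 > meal_start_s - 30 & cs < meal_end_s + 30))
        next
      cd <- runif(1, params$bite_duration_s[1L], params$bite_duration_s[2L])
      ci <- as.integer(round(cs * rate)) + 1L
      cn <- as.integer(round(cd * rate))
      data[ci:(ci + cn - 1L), ] <- gesture_confounder(cn, params)
      placed <- placed + 1L
    }

    if (params$noise_sd > 0)
      data <- data + matrix(rnorm(length(data), 0, params$noise_sd), n, 6L)

    list(recording = motion_recording(data, rate, subject_id),
         meals = episode_list(meal_start_s, meal_end_s, "meal",
                              reference = subject_id))
  })
}

#' Generate a synthetic dataset
#'
#' One synthetic subject per day (ids `S001`, `S002`, ...), with per-day
#' seeds derived deterministically from the master seed.
#'
#' @param n_days number of days to generate.
#' @param params a [synth_params()].
#' @param seed master integer seed.
#' @return list of `n_days` elements, each `list(recording, meals)`.
#' @export
generate_dataset <- function(n_days, params = synth_params(), seed = 1L) {
  stopifnot(n_days >= 1L)
  day_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n_days))
  lapply(seq_len(n_days), function(i)
    generate_day(params, seed = day_seeds[i],
                 subject_id = sprintf("S%03d", i)))
}
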