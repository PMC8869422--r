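# Independent reference implementations used as oracles. These are written
# as plain, per-element loops, deliberately sharing no code with the package.

# hysteresis state machine, one datum at a time
oracle_hysteresis <- function(p, TS, TE) {
  starts <- integer(); ends <- integer()
  open <- FALSE; st <- NA_integer_
  for (i in seq_along(p)) {
    if (!open && p[i] > TS) {
      open <- TRUE; st <- i
    } else if (open && p[i] < TE) {
      starts <- c(starts, st); ends <- c(ends, i); open <- FALSE
    }
  }
  if (open) { starts <- c(starts, st); ends <- c(ends, length(p) + 1L) }
  data.frame(start_datum = starts, end_datum = ends)
}

oracle_merge <- function(seg, gap_s, rate) {
  if (nrow(seg) <= 1L) return(seg)
  repeat {
    gaps <- (seg$start_datum[-1L] - seg$end_datum[-nrow(seg)]) / rate
    i <- which(gaps <= gap_s)
    if (!length(i)) return(seg)
    i <- i[1L]
    seg$end_datum[i] <- seg$end_datum[i + 1L]
    seg <- seg[-(i + 1L), , drop = FALSE]
    rownames(seg) <- NULL
  }
}

oracle_drop <- function(seg, min_s, rate) {
  seg[(seg$end_datum - seg$start_datum) / rate >= min_s, , drop = FALSE]
}

oracle_detect <- function(p, TS, TE, gap_s, min_s, rate) {
  seg <- oracle_drop(oracle_merge(oracle_hysteresis(p, TS, TE), gap_s, rate),
                     min_s, rate)
  rownames(seg) <- NULL
  seg
}

# overlap length of [a1,a2) and [b1,b2)
oracle_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

# episode matching by exhaustive pairwise overlap
oracle_match <- function(meals, dets) {
  nm <- nrow(meals); nd <- nrow(dets)
  ov <- matrix(FALSE, nm, nd)
  for (i in seq_len(nm)) for (j in seq_len(nd))
    ov[i, j] <- oracle_overlap(meals$start_s[i], meals$end_s[i],
                               dets$start_s[j], dets$end_s[j]) > 0
  list(TP = sum(apply(ov, 1, any) | logical(nm)),
       Miss = nm - sum(apply(ov, 1, any) | logical(nm)),
       FP = if (nd) sum(!apply(ov, 2, any)) else 0L)
}

# random, sorted, non-overlapping episode list in [0, horizon)
random_episodes <- function(n, horizon, min_len = 1, max_len = 50) {
  if (n == 0L) return(episode_list())
  repeat {
    starts <- sort(runif(n, 0, horizon))
    lens <- runif(n, min_len, max_len)
    ends <- pmin(starts + lens, horizon)
    ok <- all(ends > starts) &&
      (n == 1L || all(starts[-1L] >= ends[-n]))
    if (ok) return(episode_list(starts, ends))
  }
}

# small recording with a prescribed number of samples of low-freq content
toy_recording <- function(n, rate = 15, subject = "T1", sd = 1) {
  motion_recording(matrix(rnorm(n * 6, sd = sd), ncol = 6), rate, subject)
}

# trivially separable window set: class 1 has much larger gyro variance
separable_windows <- function(n_per_class, n_samples = 120, seed = 1) {
  withr::with_seed(seed, {
    B <- 2L * n_per_class
    x <- array(0, dim = c(n_samples, 6L, B))
    y <- rep(c(0L, 1L), each = n_per_class)
    for (i in seq_len(B)) {
      sd_gyro <- if (y[i] == 1L) 1.5 else 0.3
      x[, 1:3, i] <- rnorm(n_samples * 3, 0, 0.3)
      x[, 4:6, i] <- rnorm(n_samples * 3, 0, sd_gyro)
    }
    list(x = x, y = y)
  })
}

# the default-parameter 30-day study set, generated once per session and
# shared between the end-to-end and the generator-statistics tests
default_synth_days <- local({
  cache <- new.env()
  function(seed = 101) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_dataset(30, synth_params(), seed = seed)
    cache[[key]]
  }
})
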