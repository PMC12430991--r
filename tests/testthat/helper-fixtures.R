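# Fixtures built in code: hand-sized sessions and signals with known
# structure.

# A 12 s, two-trial session with a known hesitation, failure pattern, a
# still-and-silent gap, and optional GSR ramp.
make_toy_session <- function(with_gsr = TRUE, condition = "red_light") {
  # motion: active 0-6 s (drifting), frozen 6-9.8 s, active again after
  tm <- seq(0, 12, by = 0.1)
  x <- ifelse(tm < 6, 0.01 * tm, 0.06)
  x[tm > 9.8] <- 0.06 + 0.01 * (tm[tm > 9.8] - 9.8)
  motion <- tibble::tibble(t = tm, x = x, y = 0, z = 0)
  events <- tibble::tibble(
    t = c(1.0, 3.5, 4.0, 4.6, 5.2, 6.0),
    kind = c("prompt", "action", "failure", "failure", "success", "prompt"),
    task_id = c("a", "a", "a", "a", "a", "b")
  )
  gsr <- if (with_gsr) {
    tg <- seq(0, 12, by = 0.2)
    tibble::tibble(t = tg, conductance_uS = 0.5 + 0.01 * tg)
  }
  stressors <- if (condition == "baseline") NULL else {
    tibble::tibble(t_onset = 2, kind = "red_light", duration = 3)
  }
  vr_session(id = "toy", condition = condition, motion = motion,
             events = events, gsr = gsr, stressors = stressors)
}

# Sinusoidal motion trace for tremor analysis.
make_sine_motion <- function(freq = 10, amp = 0.05, fs = 90, dur = 3) {
  t <- seq(0, dur, by = 1 / fs)
  tibble::tibble(t = t, x = amp * sin(2 * pi * freq * t), y = 0.5, z = -0.2)
}

# Uniform GSR series from a function of time.
make_series <- function(f, dur = 10, fs = 5, t0 = 0) {
  t <- seq(t0, t0 + dur, by = 1 / fs)
  gsr_series(f(t), t0 = t0, fs = fs)
}

# Rolling physiological-flag series: Sp at every admissible tick.
slope_flag_series <- function(series, params = gsr_params()) {
  n_w <- as.integer(round(params$slope_window * params$fs))
  n <- length(series$values)
  if (n < n_w) return(tibble::tibble(t = double(), slope = double(), Sp = integer()))
  purrr::map_dfr(n_w:n, function(k) {
    sub <- gsr_series(series$values[seq_len(k)], t0 = series$t0, fs = series$fs)
    sl <- gsr_slope(sub, params)
    tibble::tibble(t = series$t0 + (k - 1) / series$fs,
                   slope = sl$slope, Sp = sl$Sp)
  })
}

# Brute-force Mann-Whitney AUC: pairs won + half ties over all pairs.
mw_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Stream a session through a detector in fixed-width chunks and compare to
# the batch path.
stream_in_chunks <- function(session, chunk_s = 4, ...) {
  det <- stress_detector(...)
  t_end <- session_end(session)
  bounds <- c(-1, seq(chunk_s, t_end + chunk_s, by = chunk_s))
  out <- lapply(seq_len(length(bounds) - 1), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    stream_step(det,
                motion = session$motion[session$motion$t > lo & session$motion$t <= hi, ],
                events = session$events[session$events$t > lo & session$events$t <= hi, ],
                gsr = if (!is.null(session$gsr)) {
                  session$gsr[session$gsr$t > lo & session$gsr$t <= hi, ]
                })
  })
  dplyr::bind_rows(c(out, list(detector_finalize(det, t_end))))
}
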