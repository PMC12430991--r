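# Behavioral indicators: hesitation, repeated errors, inactivity, tremor,
# and the summed behavioral score Sb (0-4).

#' Thresholds for the behavioral indicators
#'
#' Defaults are the rule system's operating points: hesitation delay
#' strictly greater than 2 s, at least 2 failed attempts, no input for
#' strictly more than 3 s, and tremor RMS strictly above 0.03 tracker units.
#' `highpass_window_s` is the span of the centered moving average subtracted
#' from the motion trace to isolate jitter (0.5 s passes the 4–12 Hz
#' physiological tremor band while removing voluntary reach motion), and
#' `motion_eps` is the instantaneous speed below which the controller counts
#' as still for the inactivity detector.
#'
#' @param hesitation_s Hesitation delay threshold, seconds.
#' @param min_failures Failure count threshold for the repeated-error flag.
#' @param inactivity_s Inactivity gap threshold, seconds.
#' @param jitter_units Tremor RMS threshold, tracker units.
#' @param highpass_window_s Moving-average high-pass span, seconds.
#' @param motion_eps Stillness speed threshold, tracker units per second.
#' @return A `behavior_thresholds` list.
#' @export
behavior_thresholds <- function(hesitation_s = 2.0, min_failures = 2L,
                                inactivity_s = 3.0, jitter_units = 0.03,
                                highpass_window_s = 0.5, motion_eps = 1e-4) {
  th <- list(hesitation_s = hesitation_s, min_failures = min_failures,
             inactivity_s = inactivity_s, jitter_units = jitter_units,
             highpass_window_s = highpass_window_s, motion_eps = motion_eps)
  if (any(vapply(th, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all behavior thresholds must be strictly positive", call. = FALSE)
  }
  structure(th, class = "behavior_thresholds")
}

#' Hesitation delay and flag
#'
#' Delay is the time from prompt to first action; for trials with no action
#' (timeouts) the delay is the full trial duration, so hesitation is never
#' undefined. The flag is 1 iff delay strictly exceeds the threshold.
#'
#' @param trials Trial tibble from [derive_trials()] (vectorized over rows).
#' @param thresholds A [behavior_thresholds()] list.
#' @return `trials` with columns `delay_s` and `hesitation_flag` appended.
#' @export
hesitation <- function(trials, thresholds = behavior_thresholds()) {
  trials <- tibble::as_tibble(trials)
  delay <- ifelse(is.na(trials$t_first_action),
                  trials$t_end - trials$t_prompt,
                  trials$t_first_action - trials$t_prompt)
  dplyr::mutate(trials,
                delay_s = delay,
                hesitation_flag = as.integer(delay > thresholds$hesitation_s))
}

#' Repeated-failure count and flag
#'
#' @inheritParams hesitation
#' @return `trials` with column `error_flag` appended (1 iff
#'   `failure_count >= min_failures`).
#' @export
repeated_failures <- function(trials, thresholds = behavior_thresholds()) {
  trials <- tibble::as_tibble(trials)
  dplyr::mutate(trials,
                error_flag = as.integer(.data$failure_count >= thresholds$min_failures))
}

motion_speed <- function(motion) {
  n <- nrow(motion)
  if (n < 2) return(rep(0, n))
  dt <- diff(motion$t)
  d <- sqrt(diff(motion$x)^2 + diff(motion$y)^2 + diff(motion$z)^2)
  c(0, d / dt)  # first sample carries no displacement information
}

#' Longest quiet gap and inactivity flag
#'
#' A time interval is quiet when it contains no input event and no motion
#' sample whose instantaneous (finite-difference) speed exceeds
#' `motion_eps`. Returns the longest quiet sub-interval of the window and
#' the flag, which is 1 iff the gap strictly exceeds the threshold.
#'
#' @param motion Motion tibble (`t, x, y, z`).
#' @param events Event tibble (`t, ...`).
#' @param window Closed interval `c(t0, t1)` with `t1 > t0`.
#' @param thresholds A [behavior_thresholds()] list.
#' @return A list with `max_gap` (seconds) and `inactivity_flag`.
#' @export
inactivity <- function(motion, events, window,
                       thresholds = behavior_thresholds()) {
  if (length(window) != 2 || !(window[2] > window[1])) {
    stop("window must be a nonempty interval c(t0, t1)", call. = FALSE)
  }
  speed <- motion_speed(motion)
  active <- c(
    events$t[events$t >= window[1] & events$t <= window[2]],
    motion$t[speed > thresholds$motion_eps &
             motion$t >= window[1] & motion$t <= window[2]]
  )
  marks <- sort(unique(c(window[1], active, window[2])))
  max_gap <- max(diff(marks))
  list(max_gap = max_gap,
       inactivity_flag = as.integer(max_gap > thresholds$inactivity_s))
}

# Centered moving average; exact for constant inputs, NA at the edges.
moving_average <- function(x, k) {
  if (length(unique(x)) == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Tremor RMS, dominant frequency, and flag
#'
#' Isolates jitter by subtracting, per axis, a centered moving average over
#' `highpass_window_s`, combines the three axes as a Euclidean magnitude,
#' and reports its root mean square over the window core (the samples where
#' the centered average is defined). The dominant frequency is the
#' zero-crossing rate of the first jitter axis divided by two. The flag is
#' 1 iff the RMS strictly exceeds `jitter_units`.
#'
#' @inheritParams inactivity
#' @return A list with `rms` (tracker units), `dominant_freq` (Hz) and
#'   `tremor_flag`.
#' @export
tremor <- function(motion, window, thresholds = behavior_thresholds()) {
  m <- motion[motion$t >= window[1] & motion$t <= window[2], ]
  n <- nrow(m)
  if (n < 4) stop("too few motion samples in window for tremor analysis",
                  call. = FALSE)
  dur <- m$t[n] - m$t[1]
  if (dur < 2 * thresholds$highpass_window_s) {
    stop("tremor window must span at least twice the high-pass window",
         call. = FALSE)
  }
  fs <- (n - 1) / dur
  k <- max(3L, as.integer(2 * floor(thresholds$highpass_window_s * fs / 2) + 1))
  if (k >= n) stop("too few motion samples in window for tremor analysis",
                   call. = FALSE)
  jx <- m$x - moving_average(m$x, k)
  jy <- m$y - moving_average(m$y, k)
  jz <- m$z - moving_average(m$z, k)
  core <- which(!is.na(jx) & !is.na(jy) & !is.na(jz))
  mag2 <- jx[core]^2 + jy[core]^2 + jz[core]^2
  rms <- sqrt(mean(mag2))
  # zero-crossing rate of the first jitter axis, per second, halved
  s <- sign(jx[core])
  s <- s[s != 0]
  crossings <- sum(diff(s) != 0)
  core_dur <- m$t[core[length(core)]] - m$t[core[1]]
  dominant_freq <- if (core_dur > 0) crossings / core_dur / 2 else 0
  list(rms = rms, dominant_freq = dominant_freq,
       tremor_flag = as.integer(rms > thresholds$jitter_units))
}

#' Behavioral score Sb
#'
#' The sum of the four binary indicators (hesitation, repeated errors,
#' inactivity, tremor); range 0–4.
#'
#' @param hesitation_flag,error_flag,inactivity_flag,tremor_flag Binary
#'   indicators (each 0 or 1; vectorized).
#' @return Integer score(s) in 0–4.
#' @export
behavioral_score <- function(hesitation_flag, error_flag, inactivity_flag,
                             tremor_flag) {
  flags <- cbind(hesitation_flag, error_flag, inactivity_flag, tremor_flag)
  if (!all(flags %in% c(0, 1))) {
    stop("behavioral indicators must be binary (0/1)", call. = FALSE)
  }
  as.integer(rowSums(flags))
}

#' Extract the per-trial behavioral feature table from a session
#'
#' Derives trials from the event log, then computes all four indicators and
#' Sb per trial. Tremor and inactivity are evaluated over each trial's
#' half-open window; trials whose window is too short for tremor analysis
#' get `NA` RMS and a zero tremor flag.
#'
#' @param session A [vr_session()].
#' @param thresholds A [behavior_thresholds()] list.
#' @return A tibble with one row per trial: `session_id, task_id, t_prompt,
#'   delay_s, hesitation_flag, failures, error_flag, gap_s,
#'   inactivity_flag, tremor_rms, tremor_freq_hz, tremor_flag, Sb`.
#' @export
extract_behavior <- function(session, thresholds = behavior_thresholds()) {
  validate_session(session)
  trials <- derive_trials(session$events, t_end = session_end(session))
  if (nrow(trials) == 0) {
    return(tibble::tibble(
      session_id = character(), task_id = character(), t_prompt = double(),
      delay_s = double(), hesitation_flag = integer(), failures = integer(),
      error_flag = integer(), gap_s = double(), inactivity_flag = integer(),
      tremor_rms = double(), tremor_freq_hz = double(),
      tremor_flag = integer(), Sb = integer()
    ))
  }
  trials <- hesitation(trials, thresholds)
  trials <- repeated_failures(trials, thresholds)
  per_trial <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    win <- c(trials$t_prompt[i], trials$t_end[i])
    ina <- inactivity(session$motion, session$events, win, thresholds)
    tr <- tryCatch(tremor(session$motion, win, thresholds),
                   error = function(e) list(rms = NA_real_,
                                            dominant_freq = NA_real_,
                                            tremor_flag = 0L))
    tibble::tibble(gap_s = ina$max_gap, inactivity_flag = ina$inactivity_flag,
                   tremor_rms = tr$rms, tremor_freq_hz = tr$dominant_freq,
                   tremor_flag = tr$tremor_flag)
  })
  dplyr::bind_cols(trials, per_trial) |>
    dplyr::transmute(
      session_id = session$id,
      task_id = .data$task_id,
      t_prompt = .data$t_prompt,
      delay_s = .data$delay_s,
      hesitation_flag = .data$hesitation_flag,
      failures = .data$failure_count,
      error_flag = .data$error_flag,
      gap_s = .data$gap_s,
      inactivity_flag = .data$inactivity_flag,
      tremor_rms = .data$tremor_rms,
      tremor_freq_hz = .data$tremor_freq_hz,
      tremor_flag = .data$tremor_flag,
      Sb = behavioral_score(.data$hesitation_flag, .data$error_flag,
                            .data$inactivity_flag, .data$tremor_flag)
    )
}
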