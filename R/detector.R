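# Online stress detection. A single, strictly causal per-tick kernel is
# shared by the streaming and batch entry points, so feeding a session
# incrementally reproduces the batch decision sequence exactly.
#
# Decision cadence: one decision per GSR tick (5 Hz by default, the slowest
# mandatory signal clock); in behavior-only mode, one decision per trial
# close.

#' Create a streaming stress detector
#'
#' The detector accumulates motion samples, input events and (optionally)
#' raw GSR samples via [stream_step()] and emits one [tier_decision()] per
#' GSR tick once the slope window (and, if auto-calibrating, the
#' calibration window) is covered. In behavior-only mode it emits one
#' decision per trial close instead.
#'
#' @param thresholds A [behavior_thresholds()] list.
#' @param gsr_params A [gsr_params()] list.
#' @param fusion A [fusion_params()] list.
#' @param ctx Optional [normalization_context()] for Gnorm. When `NULL` and
#'   GSR is present, a per-user min-max calibration is taken over the first
#'   `calib_s` seconds of the smoothed trace (widened to a 0.05 uS span if
#'   degenerate).
#' @param behavior_only If `TRUE`, GSR input is ignored and decisions use
#'   `S = B` at trial closes.
#' @param tremor_lookback_s Trailing motion window for per-tick tremor
#'   analysis, seconds.
#' @param calib_s Auto-calibration span, seconds.
#' @return A `stress_detector` object (mutable).
#' @seealso [stream_step()], [detector_finalize()], [detect_session()]
#' @export
stress_detector <- function(thresholds = behavior_thresholds(),
                            gsr_params = NULL,
                            fusion = fusion_params(),
                            ctx = NULL, behavior_only = FALSE,
                            tremor_lookback_s = 1.5, calib_s = 10) {
  if (is.null(gsr_params)) gsr_params <- vrstress::gsr_params()
  det <- new.env(parent = emptyenv())
  det$thresholds <- thresholds
  det$gsr_params <- gsr_params
  det$fusion <- fusion
  det$ctx <- ctx
  det$behavior_only <- behavior_only
  det$tremor_lookback_s <- tremor_lookback_s
  det$calib_s <- calib_s
  det$motion <- tibble::tibble(t = double(), x = double(), y = double(),
                               z = double())
  det$events <- tibble::tibble(t = double(), kind = character(),
                               task_id = character())
  det$gsr <- tibble::tibble(t = double(), conductance_uS = double())
  det$smoothed <- numeric(0)    # smoothed values on the uniform grid
  det$g0 <- NA_real_            # grid origin (first raw GSR time)
  det$ticks_emitted <- 0L
  det$trials_emitted <- 0L
  class(det) <- "stress_detector"
  det
}

#' @export
print.stress_detector <- function(x, ...) {
  cat("<stress_detector> ",
      if (x$behavior_only) "behavior-only" else "GSR-fused",
      "; ", nrow(x$motion), " motion / ", nrow(x$events), " event / ",
      nrow(x$gsr), " GSR samples buffered; ",
      x$ticks_emitted + x$trials_emitted, " decisions emitted\n", sep = "")
  invisible(x)
}

append_ordered <- function(old_t, new_t, what, strict = TRUE) {
  if (length(new_t) == 0) return(invisible(TRUE))
  check_sorted(new_t, what, strict = strict)
  if (length(old_t) > 0) {
    bad <- if (strict) new_t[1] <= old_t[length(old_t)]
           else new_t[1] < old_t[length(old_t)]
    if (bad) {
      stop(what, ": out-of-order sample (t = ", new_t[1],
           " arrives after t = ", old_t[length(old_t)], ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- causal per-tick kernel ------------------------------------------------

behavior_at <- function(det, t) {
  th <- det$thresholds
  ev <- det$events[det$events$t <= t, ]
  prompts <- ev[ev$kind == "prompt", ]
  if (nrow(prompts) > 0) {
    tp <- prompts$t[nrow(prompts)]
    task <- prompts$task_id[nrow(prompts)]
    acts <- ev$t[ev$kind == "action" & ev$task_id == task & ev$t >= tp]
    delay <- if (length(acts)) min(acts) - tp else t - tp
    hes <- as.integer(delay > th$hesitation_s)
    nfail <- sum(ev$kind == "failure" & ev$task_id == task & ev$t >= tp)
    err <- as.integer(nfail >= th$min_failures)
  } else {
    hes <- 0L; err <- 0L
  }
  m <- det$motion[det$motion$t <= t, ]
  speed <- motion_speed(m)
  last_active <- max(0, ev$t, m$t[speed > th$motion_eps])
  ina <- as.integer((t - last_active) > th$inactivity_s)
  tr <- tryCatch(tremor(m, c(t - det$tremor_lookback_s, t), th),
                 error = function(e) list(rms = NA_real_,
                                          dominant_freq = NA_real_,
                                          tremor_flag = 0L))
  list(hesitation_flag = hes, error_flag = err, inactivity_flag = ina,
       tremor_flag = tr$tremor_flag, tremor_rms = tr$rms,
       tremor_freq_hz = tr$dominant_freq)
}

extend_smoothed <- function(det) {
  fs <- det$gsr_params$fs
  n_raw <- nrow(det$gsr)
  if (n_raw < 2) return(invisible(det))
  if (is.na(det$g0)) det$g0 <- det$gsr$t[1]
  t_last <- det$gsr$t[n_raw]
  n_ready <- floor((t_last - det$g0) * fs + 1e-9) + 1
  k0 <- length(det$smoothed)
  if (n_ready <= k0) return(invisible(det))
  new_t <- det$g0 + (k0:(n_ready - 1)) / fs
  v <- stats::approx(det$gsr$t, det$gsr$conductance_uS, xout = new_t,
                     rule = 2)$y
  a <- 1 - exp(-(1 / fs) / det$gsr_params$smooth_tau)
  y_prev <- if (k0 > 0) det$smoothed[k0] else v[1]
  y <- numeric(length(v))
  for (i in seq_along(v)) {
    y_prev <- y_prev + a * (v[i] - y_prev)
    y[i] <- y_prev
  }
  det$smoothed <- c(det$smoothed, y)
  invisible(det)
}

detector_warmup <- function(det) {
  n_w <- as.integer(round(det$gsr_params$slope_window * det$gsr_params$fs))
  if (is.null(det$ctx)) {
    max(n_w, as.integer(ceiling(det$calib_s * det$gsr_params$fs)) + 1L)
  } else {
    n_w
  }
}

resolve_ctx <- function(det) {
  if (!is.null(det$ctx)) return(det$ctx)
  n_cal <- as.integer(ceiling(det$calib_s * det$gsr_params$fs)) + 1L
  v <- det$smoothed[seq_len(n_cal)]
  lo <- min(v); hi <- max(v)
  if (hi - lo < 0.05) {  # widen a flat calibration segment to a usable span
    mid <- (hi + lo) / 2
    lo <- mid - 0.025; hi <- mid + 0.025
  }
  det$ctx <- normalization_context(calibration_min = lo, calibration_max = hi)
  det$ctx
}

emit_gsr_ticks <- function(det) {
  extend_smoothed(det)
  warm <- detector_warmup(det)
  n_avail <- length(det$smoothed)
  if (n_avail < warm) return(NULL)
  first_k <- max(warm, det$ticks_emitted + 1L)
  if (first_k > n_avail) return(NULL)
  fs <- det$gsr_params$fs
  ctx <- resolve_ctx(det)
  rows <- purrr::map_dfr(first_k:n_avail, function(k) {
    t_k <- det$g0 + (k - 1) / fs
    series <- gsr_series(det$smoothed[seq_len(k)], t0 = det$g0, fs = fs)
    gs <- gsr_state(series, det$gsr_params, ctx)
    beh <- behavior_at(det, t_k)
    dec <- tier_decision(beh, gs, det$fusion)
    dplyr::bind_cols(tibble::tibble(t = t_k), dec,
                     tibble::tibble(gsr_level = gs$level,
                                    gsr_slope = gs$slope))
  })
  det$ticks_emitted <- n_avail
  rows
}

closed_trial_decisions <- function(det, upto = NULL) {
  ev <- det$events
  prompts_t <- ev$t[ev$kind == "prompt"]
  n_closed <- if (is.null(upto)) max(0L, length(prompts_t) - 1L)
              else length(prompts_t)
  if (n_closed <= det$trials_emitted) return(NULL)
  t_end <- if (is.null(upto)) prompts_t[length(prompts_t)] else upto
  trials <- derive_trials(ev, t_end = t_end)
  idx <- (det$trials_emitted + 1L):n_closed
  rows <- purrr::map_dfr(idx, function(i) {
    trial <- trials[i, ]
    trial <- hesitation(trial, det$thresholds)
    trial <- repeated_failures(trial, det$thresholds)
    win <- c(trial$t_prompt, trial$t_end)
    ina <- inactivity(det$motion, det$events, win, det$thresholds)
    tr <- tryCatch(tremor(det$motion, win, det$thresholds),
                   error = function(e) list(rms = NA_real_,
                                            dominant_freq = NA_real_,
                                            tremor_flag = 0L))
    beh <- list(hesitation_flag = trial$hesitation_flag,
                error_flag = trial$error_flag,
                inactivity_flag = ina$inactivity_flag,
                tremor_flag = tr$tremor_flag,
                tremor_freq_hz = tr$dominant_freq)
    dec <- tier_decision(beh, NULL, det$fusion)
    dplyr::bind_cols(tibble::tibble(t = trial$t_end), dec,
                     tibble::tibble(gsr_level = NA_real_,
                                    gsr_slope = NA_real_))
  })
  det$trials_emitted <- n_closed
  rows
}

#' Feed new samples to a streaming detector
#'
#' Appends new, time-ordered samples to the detector's buffers and returns
#' any decisions that became computable. Samples arriving out of order (at
#' or before an already-seen timestamp) raise an error. An empty update
#' emits nothing.
#'
#' @param det A [stress_detector()].
#' @param motion,events,gsr Optional tibbles of new samples in the session
#'   schemas.
#' @return A tibble of newly emitted decisions (possibly zero rows) with
#'   columns `t, Sb, Sp, B, Gnorm, Sf, stress, tier, S, alert, reason,
#'   gsr_level, gsr_slope`.
#' @export
stream_step <- function(det, motion = NULL, events = NULL, gsr = NULL) {
  stopifnot(inherits(det, "stress_detector"))
  if (!is.null(motion) && nrow(motion) > 0) {
    append_ordered(det$motion$t, motion$t, "motion", strict = TRUE)
    det$motion <- dplyr::bind_rows(det$motion, tibble::as_tibble(motion))
  }
  if (!is.null(events) && nrow(events) > 0) {
    append_ordered(det$events$t, events$t, "events", strict = FALSE)
    det$events <- dplyr::bind_rows(det$events, tibble::as_tibble(events))
  }
  if (!det$behavior_only && !is.null(gsr) && nrow(gsr) > 0) {
    append_ordered(det$gsr$t, gsr$t, "gsr", strict = TRUE)
    det$gsr <- dplyr::bind_rows(det$gsr, tibble::as_tibble(gsr))
  }
  out <- if (det$behavior_only) closed_trial_decisions(det)
         else emit_gsr_ticks(det)
  if (is.null(out)) decision_prototype() else out
}

#' Flush a streaming detector at session end
#'
#' In behavior-only mode, closes and scores the final open trial at
#' `t_end`. In GSR mode all decisions are emitted as ticks become covered,
#' so this returns any remaining ticks only.
#'
#' @param det A [stress_detector()].
#' @param t_end Session end time; defaults to the last buffered timestamp.
#' @return A tibble of final decisions (possibly zero rows).
#' @export
detector_finalize <- function(det, t_end = NULL) {
  stopifnot(inherits(det, "stress_detector"))
  if (det$behavior_only) {
    if (is.null(t_end)) {
      t_end <- max(0, det$motion$t, det$events$t)
    }
    out <- closed_trial_decisions(det, upto = t_end)
  } else {
    out <- emit_gsr_ticks(det)
  }
  if (is.null(out)) decision_prototype() else out
}

decision_prototype <- function() {
  tibble::tibble(t = double(), Sb = integer(), Sp = integer(), B = double(),
                 Gnorm = double(), Sf = double(), stress = logical(),
                 tier = integer(), S = double(), alert = logical(),
                 reason = character(), gsr_level = double(),
                 gsr_slope = double())
}

#' Batch stress detection over a recorded session
#'
#' Runs the streaming detector over a complete session in one pass. By
#' construction this is identical to feeding the session incrementally
#' through [stream_step()].
#'
#' @param session A [vr_session()].
#' @param ... Passed to [stress_detector()] (`thresholds`, `gsr_params`,
#'   `fusion`, `ctx`, `behavior_only`, ...).
#' @return A decisions tibble, one row per GSR tick (or per trial in
#'   behavior-only mode).
#' @export
detect_session <- function(session, ...) {
  validate_session(session)
  args <- list(...)
  if (is.null(args$behavior_only)) {
    args$behavior_only <- is.null(session$gsr)
  }
  det <- do.call(stress_detector, args)
  out1 <- stream_step(det, motion = session$motion, events = session$events,
                      gsr = session$gsr)
  out2 <- detector_finalize(det, t_end = session_end(session))
  dplyr::bind_rows(out1, out2)
}

#' Continuous stress scores for ROC ranking
#'
#' The per-tick fused score `Sf` (and the tier-2 fusion score `S` where
#' defined), suitable as ranking scores for ROC analysis of the rule
#' system.
#'
#' @inheritParams detect_session
#' @return A tibble with columns `t, Sf, S`.
#' @export
continuous_score <- function(session, ...) {
  dplyr::select(detect_session(session, ...), "t", "Sf", "S")
}
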