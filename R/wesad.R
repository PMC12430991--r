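# Adapter for WESAD-style wearable recordings: wrist EDA (4 Hz) plus heart
# rate estimated from blood volume pulse (BVP, 64 Hz), binary baseline
# (label 1) vs stress (label 2) threshold classification.
#
# The dataset's native serialized container is converted outside this
# module by a documented one-time export to long-format CSV
# (t, channel, value, label); the core library stays free of
# dataset-specific deserialization.

#' Load a WESAD-style wearable recording
#'
#' Reads a long-format CSV with columns `t` (seconds), `channel`
#' (`"eda"`/`"bvp"`), `value`, `label` (condition code; 1 = baseline,
#' 2 = stress). Channels are separated, resampled onto uniform 4 Hz (EDA)
#' and 64 Hz (BVP) grids, and EDA samples whose label lies outside
#' \{1, 2\} are dropped, together with their aligned labels.
#'
#' @param path CSV file path.
#' @param eda_fs,bvp_fs Target rates, Hz.
#' @return A `wearable_recording`: list with `eda` (tibble `t, value,
#'   label`, labels in \{1, 2\}), `bvp` (a [gsr_series()]-style uniform
#'   series), `eda_fs`.
#' @export
load_recording <- function(path, eda_fs = 4, bvp_fs = 64) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    t = "d", channel = "c", value = "d", label = "d"), progress = FALSE)
  for (ch in c("eda", "bvp")) {
    if (!any(raw$channel == ch)) {
      stop("recording is missing the ", toupper(ch), " channel", call. = FALSE)
    }
  }
  eda_raw <- dplyr::arrange(dplyr::filter(raw, .data$channel == "eda"), .data$t)
  bvp_raw <- dplyr::arrange(dplyr::filter(raw, .data$channel == "bvp"), .data$t)
  grid_e <- seq(min(eda_raw$t), max(eda_raw$t), by = 1 / eda_fs)
  eda <- tibble::tibble(
    t = grid_e,
    value = stats::approx(eda_raw$t, eda_raw$value, xout = grid_e, rule = 2)$y,
    label = stats::approx(eda_raw$t, eda_raw$label, xout = grid_e,
                          method = "constant", rule = 2)$y
  )
  eda <- dplyr::filter(eda, .data$label %in% c(1, 2))
  if (nrow(eda) == 0) {
    stop("no EDA samples left after filtering to labels {1, 2}", call. = FALSE)
  }
  grid_b <- seq(min(bvp_raw$t), max(bvp_raw$t), by = 1 / bvp_fs)
  bvp <- gsr_series(
    stats::approx(bvp_raw$t, bvp_raw$value, xout = grid_b, rule = 2)$y,
    t0 = min(bvp_raw$t), fs = bvp_fs, units = "a.u."
  )
  structure(list(eda = eda, bvp = bvp, eda_fs = eda_fs),
            class = "wearable_recording")
}

#' @export
print.wearable_recording <- function(x, ...) {
  cat("<wearable_recording> EDA: ", nrow(x$eda), " samples @ ", x$eda_fs,
      " Hz; BVP: ", length(x$bvp$values), " samples @ ", x$bvp$fs, " Hz\n",
      sep = "")
  invisible(x)
}

#' Estimate heart rate from a blood volume pulse waveform
#'
#' Detects pulse peaks (local maxima at least 0.33 s apart, above a
#' noise-scaled amplitude floor), converts inter-beat intervals to
#' instantaneous heart rate (60/IBI), keeps physiologically valid beats
#' (20–250 bpm), and interpolates onto a uniform output grid.
#'
#' @param bvp A uniform BVP series (at least 10 s).
#' @param out_fs Output rate, Hz.
#' @param min_ibi_s Minimum inter-peak interval, seconds.
#' @return A uniform heart-rate series (bpm) spanning the detected beats.
#' @export
hr_from_bvp <- function(bvp, out_fs = 4, min_ibi_s = 0.33) {
  stopifnot(inherits(bvp, "vrs_series"))
  x <- bvp$values
  if (length(x) / bvp$fs < 10) {
    stop("need at least 10 s of BVP signal", call. = FALSE)
  }
  floor_amp <- mean(x) + 0.25 * stats::sd(x)
  pk <- pracma::findpeaks(x, minpeakheight = floor_amp,
                          minpeakdistance = max(1L, round(min_ibi_s * bvp$fs)))
  if (is.null(pk) || nrow(pk) < 3) {
    stop("no reliable pulse peaks found in BVP signal", call. = FALSE)
  }
  peak_t <- sort(series_times(bvp)[pk[, 2]])
  ibi <- diff(peak_t)
  hr <- 60 / ibi
  t_hr <- peak_t[-1]
  valid <- hr > 20 & hr < 250
  if (!any(valid)) {
    stop("no physiologically valid beats (20-250 bpm) in BVP signal",
         call. = FALSE)
  }
  hr <- hr[valid]
  t_hr <- t_hr[valid]
  grid <- seq(t_hr[1], t_hr[length(t_hr)], by = 1 / out_fs)
  gsr_series(stats::approx(t_hr, hr, xout = grid, rule = 2)$y,
             t0 = grid[1], fs = out_fs, units = "bpm")
}

#' EDA calibration over a baseline segment
#'
#' Mean and standard deviation of EDA over the baseline-labeled samples
#' (label 1), optionally restricted to a time window.
#'
#' @param recording A [load_recording()] result.
#' @param window Optional time interval `c(t0, t1)` to restrict the
#'   baseline segment.
#' @return A list with `mean` and `sd`.
#' @export
wesad_calibration <- function(recording, window = NULL) {
  e <- recording$eda
  base <- e[e$label == 1, ]
  if (!is.null(window)) {
    base <- base[base$t >= window[1] & base$t <= window[2], ]
  }
  if (nrow(base) == 0) {
    stop("empty calibration segment: no baseline-labeled EDA samples",
         call. = FALSE)
  }
  list(mean = mean(base$value), sd = max(stats::sd(base$value), 1e-9))
}

#' Threshold classification of a wearable recording
#'
#' Scores each EDA sample as its z score relative to the baseline
#' calibration; when `use_hr` is enabled the heart-rate z score (relative
#' to baseline-labeled HR samples) contributes with the same 0.6/0.4
#' weighting as tier-2 fusion. Predicts stress (label 2) when the score
#' strictly exceeds `k` baseline standard deviations; the continuous score
#' series is returned for ROC analysis.
#'
#' @param recording A [load_recording()] result.
#' @param hr Optional heart-rate series from [hr_from_bvp()]; required when
#'   `use_hr = TRUE`.
#' @param calibration A [wesad_calibration()] list.
#' @param k Decision threshold in baseline standard deviations.
#' @param use_hr Include the HR z score with weight 0.4.
#' @param w_eda,w_hr Fusion weights when `use_hr = TRUE`.
#' @return A tibble: `t, label, score, pred` (`pred` in \{1, 2\}).
#' @export
classify_recording <- function(recording, hr = NULL,
                               calibration = wesad_calibration(recording),
                               k = 1.0, use_hr = FALSE,
                               w_eda = 0.6, w_hr = 0.4) {
  e <- recording$eda
  z_eda <- (e$value - calibration$mean) / calibration$sd
  score <- z_eda
  if (use_hr) {
    if (is.null(hr)) stop("use_hr = TRUE requires an hr series", call. = FALSE)
    hr_t <- series_times(hr)
    hr_at <- stats::approx(hr_t, hr$values, xout = e$t, rule = 2)$y
    base <- e$label == 1
    hr_mu <- mean(hr_at[base])
    hr_sd <- max(stats::sd(hr_at[base]), 1e-9)
    score <- w_eda * z_eda + w_hr * (hr_at - hr_mu) / hr_sd
  }
  tibble::tibble(t = e$t, label = as.integer(e$label), score = score,
                 pred = ifelse(score > k, 2L, 1L))
}
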