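# GSR (electrodermal) conditioning: uniform resampling, causal exponential
# smoothing, slope detection (physiological flag Sp), level flag, min-max
# normalization (Gnorm), and baseline-relative changes.

#' Uniformly sampled signal series
#'
#' Lightweight container for a uniformly sampled signal: start time `t0`,
#' sampling rate `fs` (Hz), and the value vector. Used for GSR traces
#' (microsiemens) and derived wearable series (heart rate).
#'
#' @param values Numeric vector of samples.
#' @param t0 Time of the first sample, seconds.
#' @param fs Sampling rate, Hz (`> 0`).
#' @param units Unit label carried for display.
#' @return A `vrs_series` object.
#' @export
gsr_series <- function(values, t0 = 0, fs = 5, units = "uS") {
  stopifnot(is.numeric(values), fs > 0)
  structure(list(t0 = t0, fs = fs, values = as.numeric(values), units = units),
            class = "vrs_series")
}

#' @export
print.vrs_series <- function(x, ...) {
  cat("<vrs_series> ", length(x$values), " samples @ ", x$fs, " Hz from t0 = ",
      x$t0, " s [", x$units, "]\n", sep = "")
  invisible(x)
}

series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) / series$fs
}

#' @export
as_tibble.vrs_series <- function(x, ...) {
  tibble::tibble(t = series_times(x), value = x$values)
}

#' Parameters of the GSR processing chain
#'
#' Defaults: the physiological flag Sp fires when the ordinary-least-squares
#' slope of the (smoothed) conductance over the trailing 3 s window strictly
#' exceeds 0.05 uS/s; the level flag fires when the current smoothed
#' conductance strictly exceeds 0.7 uS; smoothing is first-order exponential
#' with a 1 s time constant.
#'
#' @param slope_thresh Slope threshold, uS/s.
#' @param slope_window Trailing slope window, seconds (15 samples at 5 Hz).
#' @param level_thresh Conductance level threshold, uS.
#' @param smooth_tau Exponential smoothing time constant, seconds.
#' @param fs Nominal sampling rate, Hz.
#' @return A `gsr_params` list.
#' @export
gsr_params <- function(slope_thresh = 0.05, slope_window = 3.0,
                       level_thresh = 0.7, smooth_tau = 1.0, fs = 5) {
  p <- list(slope_thresh = slope_thresh, slope_window = slope_window,
            level_thresh = level_thresh, smooth_tau = smooth_tau, fs = fs)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all GSR parameters must be strictly positive", call. = FALSE)
  }
  structure(p, class = "gsr_params")
}

#' Resample a raw GSR trace onto a uniform grid
#'
#' Linear interpolation onto the grid `t[1] + k/fs` spanning the raw trace.
#' Exact on affine signals; the identity when the input is already on-grid.
#'
#' @param gsr Tibble with columns `t, conductance_uS` (`t` strictly
#'   increasing, at least 2 samples).
#' @param fs Target rate, Hz.
#' @return A [gsr_series()].
#' @export
gsr_resample <- function(gsr, fs = 5) {
  gsr <- tibble::as_tibble(gsr)
  if (nrow(gsr) < 2) stop("need at least 2 GSR samples to resample", call. = FALSE)
  check_sorted(gsr$t, "gsr", strict = TRUE)
  grid <- seq(gsr$t[1], gsr$t[nrow(gsr)] + 1e-12, by = 1 / fs)
  grid <- grid[grid <= gsr$t[nrow(gsr)] + 1e-9]
  v <- stats::approx(gsr$t, gsr$conductance_uS, xout = grid, rule = 2)$y
  gsr_series(v, t0 = gsr$t[1], fs = fs)
}

#' First-order exponential smoothing
#'
#' Causal filter `y_i = y_{i-1} + a (x_i - y_{i-1})` with
#' `a = 1 - exp(-dt/tau)`, initialized at the first sample. A constant
#' series is a fixed point; a unit step reaches `1 - exp(-1)` of its height
#' one time constant after the edge.
#'
#' @param series A [gsr_series()].
#' @param tau Time constant, seconds (`> 0`).
#' @return A smoothed [gsr_series()] on the same grid.
#' @export
gsr_smooth <- function(series, tau = 1.0) {
  stopifnot(inherits(series, "vrs_series"))
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  x <- series$values
  if (length(x) == 0) return(series)
  a <- 1 - exp(-(1 / series$fs) / tau)
  y <- as.numeric(stats::filter(a * x, 1 - a, method = "recursive",
                                init = x[1]))
  gsr_series(y, t0 = series$t0, fs = series$fs, units = series$units)
}

ols_slope <- function(t, v) {
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc^2)
}

#' GSR slope detector (physiological flag Sp)
#'
#' Ordinary-least-squares slope of conductance against time over the
#' trailing `slope_window` (15 samples at 5 Hz); Sp = 1 iff the slope
#' strictly exceeds `slope_thresh`. Adding a constant offset to the whole
#' series leaves the slope, and hence Sp, unchanged.
#'
#' @param series A (typically smoothed) [gsr_series()].
#' @param params A [gsr_params()] list.
#' @return A list with `slope` (uS/s) and `Sp` (0/1).
#' @export
gsr_slope <- function(series, params = gsr_params()) {
  stopifnot(inherits(series, "vrs_series"))
  n_w <- as.integer(round(params$slope_window * series$fs))
  n <- length(series$values)
  if (n < n_w) stop("series shorter than the slope window", call. = FALSE)
  idx <- (n - n_w + 1):n
  t <- series_times(series)[idx]
  slope <- ols_slope(t, series$values[idx])
  list(slope = slope, Sp = as.integer(slope > params$slope_thresh))
}

#' GSR level flag
#'
#' 1 iff the current (last) value strictly exceeds `level_thresh`.
#'
#' @inheritParams gsr_slope
#' @return 0 or 1.
#' @export
gsr_level <- function(series, params = gsr_params()) {
  stopifnot(inherits(series, "vrs_series"))
  if (length(series$values) == 0) stop("empty series", call. = FALSE)
  as.integer(series$values[length(series$values)] > params$level_thresh)
}

#' Min-max normalization to \eqn{[0, 1]} (Gnorm)
#'
#' `(v - min)/(max - min)`, clamped to `[0, 1]`, per sample. Monotone in the
#' input; exact 0/1 at the calibration anchors.
#'
#' @param values Numeric vector (or a [gsr_series()], normalized in place).
#' @param ctx A [normalization_context()] (or any list with
#'   `calibration_min`/`calibration_max`).
#' @return Normalized values (same shape as the input).
#' @export
gsr_normalize <- function(values, ctx) {
  lo <- ctx$calibration_min
  hi <- ctx$calibration_max
  if (!is.numeric(lo) || !is.numeric(hi) || !(hi > lo)) {
    stop("degenerate calibration range: calibration_max must exceed calibration_min",
         call. = FALSE)
  }
  norm1 <- function(v) pmin(1, pmax(0, (v - lo) / (hi - lo)))
  if (inherits(values, "vrs_series")) {
    out <- values
    out$values <- norm1(values$values)
    out$units <- "Gnorm"
    return(out)
  }
  norm1(values)
}

#' Baseline-relative change
#'
#' `(value - baseline)/baseline`; the dimensionless deviation of a feature
#' from its non-stress baseline.
#'
#' @param value Observed value(s).
#' @param baseline Baseline mean (`> 0`).
#' @return Dimensionless relative change(s).
#' @export
relative_change <- function(value, baseline) {
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    stop("baseline must be strictly positive", call. = FALSE)
  }
  (value - baseline) / baseline
}

#' Normalization context
#'
#' Per-feature baseline means (from non-stress classes) plus the min-max
#' calibration range used for Gnorm.
#'
#' @param baseline_mean Named numeric vector of per-feature baseline means.
#' @param calibration_min,calibration_max GSR calibration anchors, uS
#'   (`calibration_max > calibration_min`).
#' @return A `normalization_context` list.
#' @export
normalization_context <- function(baseline_mean = NULL, calibration_min,
                                  calibration_max) {
  if (!(calibration_max > calibration_min)) {
    stop("degenerate calibration range: calibration_max must exceed calibration_min",
         call. = FALSE)
  }
  if (!is.null(baseline_mean) && any(baseline_mean <= 0)) {
    stop("baseline means must be strictly positive for relative change",
         call. = FALSE)
  }
  structure(list(baseline_mean = baseline_mean,
                 calibration_min = calibration_min,
                 calibration_max = calibration_max),
            class = "normalization_context")
}

#' Derive a normalization context from a labeled feature table
#'
#' The baseline is the mean of each feature over the non-stress classes
#' (`Negative` and `Neutral`); the Gnorm calibration range is the min/max
#' GSR over those rows.
#'
#' @param features Tibble with columns `class` (or `class_label`),
#'   `hesitation_s`, `tremble_units`, `gsr_uS`.
#' @return A [normalization_context()].
#' @export
baseline_from_dataset <- function(features) {
  features <- tibble::as_tibble(features)
  cls_col <- intersect(c("class", "class_label"), names(features))[1]
  if (is.na(cls_col)) stop("feature table needs a class or class_label column",
                           call. = FALSE)
  ns <- features[features[[cls_col]] %in% c("Negative", "Neutral"), ]
  if (nrow(ns) == 0) stop("no non-stress (Negative/Neutral) rows in feature table",
                          call. = FALSE)
  feats <- intersect(c("hesitation_s", "tremble_units", "gsr_uS"), names(ns))
  bm <- vapply(feats, function(f) mean(ns[[f]]), numeric(1))
  lo <- min(ns$gsr_uS)
  hi <- max(ns$gsr_uS)
  if (!(hi > lo)) {           # single-row calibration still needs a range
    lo <- lo - 0.05
    hi <- hi + 0.05
  }
  normalization_context(baseline_mean = bm, calibration_min = lo,
                        calibration_max = hi)
}

#' Instantaneous GSR state
#'
#' Bundles the slope detector, level flag and normalized level at the end of
#' a (smoothed) series into the physiological half of a stress decision.
#'
#' @inheritParams gsr_slope
#' @param ctx Optional [normalization_context()]; without it `Gnorm` is `NA`.
#' @return A one-row tibble: `slope, Sp, level, level_flag, Gnorm`.
#' @export
gsr_state <- function(series, params = gsr_params(), ctx = NULL) {
  sl <- gsr_slope(series, params)
  level <- series$values[length(series$values)]
  tibble::tibble(
    slope = sl$slope,
    Sp = sl$Sp,
    level = level,
    level_flag = gsr_level(series, params),
    Gnorm = if (is.null(ctx)) NA_real_ else gsr_normalize(level, ctx)
  )
}
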