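gp <- gsr_params()

test_that("resampling is the identity on-grid and exact on affine signals", {
  tg <- seq(0, 4, by = 0.2)
  tbl <- tibble::tibble(t = tg, conductance_uS = 0.5 + 0.03 * tg)
  r <- gsr_resample(tbl, fs = 5)
  expect_equal(r$values, tbl$conductance_uS, tolerance = 1e-12)

  # 10 Hz linear ramp down to 5 Hz: interpolation of a line is exact
  t10 <- seq(0, 4, by = 0.1)
  tbl10 <- tibble::tibble(t = t10, conductance_uS = 0.2 + 0.07 * t10)
  r5 <- gsr_resample(tbl10, fs = 5)
  t5 <- seq(0, 4, by = 0.2)
  expect_equal(r5$values, 0.2 + 0.07 * t5, tolerance = 1e-12)

  expect_error(gsr_resample(tibble::tibble(t = 1, conductance_uS = 0.5)),
               "at least 2")
})

test_that("exponential smoothing has the first-order fixed point and step response", {
  const <- make_series(function(t) rep(0.8, length(t)))
  expect_equal(gsr_smooth(const, tau = 1)$values, const$values)

  # unit step: one time constant after the edge the response is 1 - 1/e
  x <- c(rep(0, 10), rep(1, 30))
  step <- gsr_series(x, t0 = 0, fs = 5)
  y <- gsr_smooth(step, tau = 1)$values
  expect_equal(y[10 + 5], 1 - exp(-1), tolerance = 1e-12)

  # a single-sample spike is attenuated
  spike <- gsr_series(c(rep(0, 10), 5, rep(0, 10)), t0 = 0, fs = 5)
  expect_lt(max(gsr_smooth(spike, tau = 1)$values), 5)

  expect_error(gsr_smooth(const, tau = 0), "tau")
})

test_that("slope detector fires strictly above 0.05 uS/s", {
  ramp <- function(rate) make_series(function(t) 0.5 + rate * t, dur = 5)
  expect_identical(gsr_slope(ramp(0.1), gp)$Sp, 1L)
  expect_equal(gsr_slope(ramp(0.1), gp)$slope, 0.1, tolerance = 1e-9)
  flat <- gsr_slope(ramp(0), gp)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_identical(flat$Sp, 0L)
  expect_identical(gsr_slope(ramp(0.05), gp)$Sp, 0L)  # strict boundary
  short <- gsr_series(c(0.5, 0.6), fs = 5)
  expect_error(gsr_slope(short, gp), "shorter than")
})

test_that("OLS slope matches the closed-form least-squares oracle", {
  set.seed(11)
  for (rep in 1:20) {
    v <- rnorm(15, 0.7, 0.05)
    s <- gsr_series(v, t0 = runif(1, 0, 10), fs = 5)
    t <- s$t0 + (0:14) / 5
    beta <- (sum(t * v) - 15 * mean(t) * mean(v)) /
            (sum(t^2) - 15 * mean(t)^2)
    expect_equal(gsr_slope(s, gp)$slope, beta, tolerance = 1e-9)
  }
})

test_that("Sp is offset-invariant; the level flag is not", {
  set.seed(3)
  v <- 0.4 + cumsum(rnorm(25, 0.01, 0.01))
  s <- gsr_series(v, fs = 5)
  s_off <- gsr_series(v + 2, fs = 5)
  expect_identical(gsr_slope(s, gp)$Sp, gsr_slope(s_off, gp)$Sp)
  expect_equal(gsr_slope(s, gp)$slope, gsr_slope(s_off, gp)$slope,
               tolerance = 1e-9)
  expect_identical(gsr_level(gsr_series(0.6, fs = 5), gp), 0L)
  expect_identical(gsr_level(gsr_series(0.6 + 2, fs = 5), gp), 1L)
})

test_that("level flag is strict at 0.7 uS", {
  expect_identical(gsr_level(gsr_series(c(0.2, 0.75), fs = 5), gp), 1L)
  expect_identical(gsr_level(gsr_series(c(0.9, 0.60), fs = 5), gp), 0L)
  expect_identical(gsr_level(gsr_series(0.70, fs = 5), gp), 0L)
})

test_that("min-max normalization anchors, clamps, and stays monotone", {
  ctx <- normalization_context(calibration_min = 0.5, calibration_max = 0.9)
  expect_equal(gsr_normalize(0.5, ctx), 0)
  expect_equal(gsr_normalize(0.9, ctx), 1)
  expect_equal(gsr_normalize(1.4, ctx), 1)   # clamped
  expect_equal(gsr_normalize(0.1, ctx), 0)   # clamped
  v <- seq(0, 2, by = 0.01)
  g <- gsr_normalize(v, ctx)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) >= 0))
  expect_error(normalization_context(calibration_min = 1, calibration_max = 1),
               "degenerate")
})

test_that("relative change is (value - baseline)/baseline", {
  expect_equal(relative_change(1.2, 1.0), 0.2)
  expect_equal(relative_change(0.77, 0.77), 0)
  expect_error(relative_change(1, 0), "positive")
})

test_that("baseline context averages the non-stress classes", {
  tbl <- tibble::tibble(
    class = c("Negative", "Neutral", "Positive"),
    hesitation_s = c(0.99, 1.69, 0.91),
    tremble_units = c(0.006, 0.016, 0.005),
    gsr_uS = c(0.62, 0.77, 0.61)
  )
  ctx <- baseline_from_dataset(tbl)
  expect_equal(unname(ctx$baseline_mean["gsr_uS"]), mean(c(0.62, 0.77)))
  expect_equal(ctx$calibration_min, 0.62)
  expect_equal(ctx$calibration_max, 0.77)

  expect_error(baseline_from_dataset(tbl[3, ]), "non-stress")

  # single non-stress row: baseline is that row, range widened to be usable
  ctx1 <- baseline_from_dataset(tbl[1, ])
  expect_equal(unname(ctx1$baseline_mean["hesitation_s"]), 0.99)
  expect_gt(ctx1$calibration_max, ctx1$calibration_min)
})
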