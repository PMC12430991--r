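th <- behavior_thresholds()

test_that("hesitation delay and flag follow the strict 2 s rule", {
  trials <- tibble::tibble(
    task_id = c("a", "b", "c"),
    t_prompt = c(5.0, 10.0, 20.0),
    t_first_action = c(7.5, 12.0, NA),
    t_end = c(9.0, 14.0, 26.0),
    failure_count = c(0L, 0L, 0L),
    outcome = c("success", "success", "timeout")
  )
  h <- hesitation(trials, th)
  expect_equal(h$delay_s, c(2.5, 2.0, 6.0))
  # 2.5 > 2 flags; exactly 2.0 does not (strict); timeouts use full duration
  expect_equal(h$hesitation_flag, c(1L, 0L, 1L))
})

test_that("repeated failures flag at >= 2 failed attempts", {
  trials <- tibble::tibble(task_id = "x", t_prompt = 0, t_first_action = 1,
                           t_end = 5, failure_count = c(0L, 1L, 2L, 3L),
                           outcome = "failure")
  expect_equal(repeated_failures(trials, th)$error_flag, c(0L, 0L, 1L, 1L))
})

test_that("inactivity finds the longest still-and-silent gap, strict at 3 s", {
  # motion moves until t = 4, freezes until 7.5, moves after
  t <- seq(0, 10, by = 0.1)
  x <- ifelse(t <= 4, 0.05 * t, 0.2)
  x[t > 7.5] <- 0.2 + 0.05 * (t[t > 7.5] - 7.5)
  motion <- tibble::tibble(t = t, x = x, y = 0, z = 0)
  events <- tibble::tibble(t = numeric(0), kind = character(0),
                           task_id = character(0))
  r <- inactivity(motion, events, c(0, 10), th)
  expect_gt(r$max_gap, 3)
  expect_identical(r$inactivity_flag, 1L)

  # an event inside the gap splits it below threshold
  events2 <- tibble::tibble(t = 5.8, kind = "action", task_id = "a")
  r2 <- inactivity(motion, events2, c(0, 10), th)
  expect_identical(r2$inactivity_flag, 0L)

  # continuous motion: no gap beyond the sampling interval
  busy <- tibble::tibble(t = t, x = 0.05 * t, y = 0, z = 0)
  r3 <- inactivity(busy, events, c(0, 10), th)
  expect_lt(r3$max_gap, 0.2)
  expect_identical(r3$inactivity_flag, 0L)

  # gap of exactly 3.0 s does not flag (strict)
  ev_edges <- tibble::tibble(t = c(0, 3), kind = "action", task_id = "a")
  no_motion <- tibble::tibble(t = numeric(0), x = numeric(0), y = numeric(0),
                              z = numeric(0))
  r4 <- inactivity(no_motion, ev_edges, c(0, 3), th)
  expect_equal(r4$max_gap, 3)
  expect_identical(r4$inactivity_flag, 0L)

  expect_error(inactivity(motion, events, c(5, 5), th), "window")
})

test_that("tremor RMS of a sinusoid matches A/sqrt(2) and flags at 0.03", {
  m <- make_sine_motion(freq = 10, amp = 0.05)
  r <- tremor(m, c(0, 3), th)
  expect_equal(r$rms, 0.05 / sqrt(2), tolerance = 5e-3)
  expect_identical(r$tremor_flag, 1L)
  expect_equal(r$dominant_freq, 10, tolerance = 0.3)

  r2 <- tremor(make_sine_motion(freq = 10, amp = 0.04), c(0, 3), th)
  expect_equal(r2$rms, 0.04 / sqrt(2), tolerance = 5e-3)
  expect_identical(r2$tremor_flag, 0L)
})

test_that("tremor equals a brute-force two-pass moving-average computation", {
  set.seed(7)
  t <- seq(0, 4, by = 1 / 60)
  m <- tibble::tibble(t = t,
                      x = cumsum(rnorm(length(t), 0, 0.01)),
                      y = sin(2 * pi * 6 * t) * 0.02,
                      z = rnorm(length(t), 0, 0.005))
  r <- tremor(m, c(0, 4), th)
  # oracle: explicit loops
  fs <- (nrow(m) - 1) / (max(t) - min(t))
  k <- as.integer(2 * floor(th$highpass_window_s * fs / 2) + 1)
  h <- (k - 1) %/% 2
  n <- nrow(m)
  acc <- c()
  for (i in (h + 1):(n - h)) {
    mx <- mean(m$x[(i - h):(i + h)])
    my <- mean(m$y[(i - h):(i + h)])
    mz <- mean(m$z[(i - h):(i + h)])
    acc <- c(acc, (m$x[i] - mx)^2 + (m$y[i] - my)^2 + (m$z[i] - mz)^2)
  }
  expect_equal(r$rms, sqrt(mean(acc)), tolerance = 1e-9)
})

test_that("a constant-position trace has exactly zero tremor RMS", {
  t <- seq(0, 2, by = 1 / 90)
  m <- tibble::tibble(t = t, x = 0.1, y = -2.5, z = 0.37)
  r <- tremor(m, c(0, 2), th)
  expect_identical(r$rms, 0)
  expect_identical(r$tremor_flag, 0L)
})

test_that("tremor errors on windows too short for the high-pass", {
  m <- make_sine_motion(dur = 0.6)
  expect_error(tremor(m, c(0, 0.6), th), "twice the high-pass")
})

test_that("behavioral score sums the four flags and rejects non-binary input", {
  expect_identical(behavioral_score(1, 1, 1, 1), 4L)
  expect_identical(behavioral_score(0, 0, 0, 0), 0L)
  expect_identical(behavioral_score(1, 1, 0, 0), 2L)
  expect_error(behavioral_score(2, 0, 0, 0), "binary")
  # monotone: setting any flag never decreases Sb
  flags <- expand.grid(h = 0:1, e = 0:1, i = 0:1, t = 0:1)
  sb <- with(flags, behavioral_score(h, e, i, t))
  for (j in 1:4) {
    lo <- flags[, j] == 0
    hi <- flags
    hi[, j] <- 1
    sb_hi <- with(hi, behavioral_score(h, e, i, t))
    expect_true(all(sb_hi[lo] >= sb[lo]))
  }
})

test_that("extract_behavior produces a coherent per-trial feature table", {
  s <- make_toy_session()
  f <- extract_behavior(s)
  expect_identical(nrow(f), 2L)
  expect_equal(f$delay_s[1], 2.5)
  expect_identical(f$hesitation_flag[1], 1L)
  expect_identical(f$failures[1], 2L)
  expect_identical(f$error_flag[1], 1L)
  # trial 2 contains the frozen 6-9.8 s interval: inactivity flags
  expect_gt(f$gap_s[2], 3)
  expect_identical(f$inactivity_flag[2], 1L)
  expect_identical(f$Sb, behavioral_score(f$hesitation_flag, f$error_flag,
                                          f$inactivity_flag, f$tremor_flag))
})
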