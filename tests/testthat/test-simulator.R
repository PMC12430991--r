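test_that("fit_location_scale matches feasible targets to numerical quadrature", {
  fit <- fit_location_scale(1.0, 1.1, lower_bound = 0, scale_max = Inf)
  # oracle: mean by quadrature of the fitted density, median by CDF root
  dens <- function(x) vrstress:::tn_density(x, fit$location, fit$scale, 0)
  mass <- stats::integrate(dens, 0, Inf)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  mean_q <- stats::integrate(function(x) x * dens(x), 0, Inf)$value
  expect_equal(mean_q, 1.1, tolerance = 1e-5)
  cdf <- function(m) stats::integrate(dens, 0, m)$value
  expect_equal(cdf(1.0), 0.5, tolerance = 1e-5)
})

test_that("a symmetric target pair with negligible truncation recovers location", {
  # median = mean with the bound far below: location = target, tiny skew
  fit <- fit_location_scale(5, 5.0000001, lower_bound = 0, scale_max = Inf)
  expect_equal(fit$location, 5, tolerance = 1e-3)
})

test_that("infeasible moment targets are rejected", {
  expect_error(fit_location_scale(1.69, 1.68, 0), "infeasible")
  expect_error(fit_location_scale(1.0, 0.5, 0), "infeasible")
  expect_error(fit_location_scale(1.0, -1, 0), "lower bound")
  # feasible pair whose required scale exceeds the admissible bound
  expect_error(fit_location_scale(0.016, 0.017, 0), "scale_max|exceeds")
})

test_that("coupling limits: unit loadings are comonotone, zero loadings independent", {
  cfg1 <- sim_config(loadings = c(hesitation_s = 1, tremble_units = 1, gsr_uS = 1))
  f1 <- withr::with_seed(2, sample_trial_features(200, "Neutral", cfg1))
  expect_equal(cor(f1$gsr_uS, f1$hesitation_s, method = "spearman"), 1)
  expect_equal(cor(f1$gsr_uS, f1$tremble_units, method = "spearman"), 1)

  cfg0 <- sim_config(loadings = c(hesitation_s = 0, tremble_units = 0, gsr_uS = 0))
  f0 <- withr::with_seed(2, sample_trial_features(2000, "Neutral", cfg0))
  expect_lt(abs(cor(f0$gsr_uS, f0$hesitation_s, method = "spearman")), 0.08)
})

test_that("the dataset is deterministic under seed and has the right shape", {
  cfg <- sim_config(n_per_class = 4, n_trials_per_session = 2, seed = 123)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$features, d2$features)
  expect_identical(nrow(d1$features), 12L)
  expect_identical(sort(unique(d1$features$class)),
                   c("Negative", "Neutral", "Positive"))
  for (nm in names(d1$sessions)) {
    expect_equal(as.data.frame(d1$sessions[[nm]]$gsr),
                 as.data.frame(d2$sessions[[nm]]$gsr))
    expect_equal(as.data.frame(d1$sessions[[nm]]$motion),
                 as.data.frame(d2$sessions[[nm]]$motion))
  }
  d3 <- simulate_dataset(sim_config(n_per_class = 1, seed = 123),
                         sessions = FALSE)
  expect_identical(nrow(d3$features), 3L)
})

test_that("sample marginals track the fitted generator targets", {
  cfg <- sim_config(n_per_class = 200, seed = 42)
  f <- simulate_dataset(cfg, sessions = FALSE)$features
  for (i in seq_len(nrow(cfg$class_params))) {
    p <- cfg$class_params[i, ]
    v <- f[[p$feature]][f$class == p$class]
    m_target <- vrstress:::tn_median(p$location, p$scale, 0)
    mean_target <- vrstress:::tn_mean(p$location, p$scale, 0)
    expect_equal(median(v), m_target, tolerance = 0.05,
                 label = paste("median", p$class, p$feature))
    expect_equal(mean(v), mean_target, tolerance = 0.05,
                 label = paste("mean", p$class, p$feature))
  }
})

test_that("baseline sessions are null scenarios: no stressors, no slope firings", {
  cfg <- sim_config(n_trials_per_session = 4, seed = 6)
  s <- synth_session("baseline", cfg, seed = 61)
  expect_identical(nrow(s$stressors), 0L)
  expect_null(attr(s, "scr_events"))
  sm <- gsr_smooth(gsr_resample(s$gsr, cfg$gsr_fs), gsr_params()$smooth_tau)
  flags <- slope_flag_series(sm)
  expect_identical(sum(flags$Sp), 0L)
})

test_that("every synthetic stress response respects the 1-3 s latency window", {
  cfg <- sim_config(n_trials_per_session = 4, seed = 8)
  for (seed in 1:5) {
    s <- synth_session("high_stress", cfg, seed = seed)
    scr <- attr(s, "scr_events")
    expect_true(all(scr$latency >= 1 & scr$latency <= 3))
    expect_true(all(scr$peak_t - scr$t_onset >= 1))
    expect_true(all(scr$peak_t - scr$t_onset <= 3))
  }
})

test_that("synthesized traces realize the sampled features", {
  cfg <- sim_config(n_trials_per_session = 4, seed = 14)
  s <- synth_session("high_stress", cfg, seed = 77)
  f <- attr(s, "trial_features")
  ext <- extract_behavior(s)
  # hesitation is embedded exactly (up to the event log round trip)
  expect_equal(ext$delay_s, pmin(f$hesitation_s, cfg$trial_period_s - 1),
               tolerance = 1e-6)
  # measured tremor RMS tracks the sampled tremble amplitude
  expect_equal(ext$tremor_rms, f$tremble_units, tolerance = 0.25)
})
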