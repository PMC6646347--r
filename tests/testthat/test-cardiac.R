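test_that("R-peak detection recovers noiseless synthetic beats within 2 ms", {
  set.seed(1)
  cfg <- cardiac_sim_config(rr_cv = 0, arrhythmia_rate = 0, noise_sd = 0)
  e <- simulate_ecg(cfg, 60)
  expect_length(e$beat_times, 300)            # exactly floor(60 / 0.2) beats
  b <- detect_r_peaks(e$signal)
  # the final beat sits exactly at the session edge where its template is
  # truncated; all interior beats must be found, each within 2 ms
  expect_gte(length(b$r_peak_times), 299)
  interior <- e$beat_times[e$beat_times < 60 - 0.025]
  err <- vapply(interior, function(t) min(abs(b$r_peak_times - t)), numeric(1))
  expect_lt(max(err), 0.002)
  expect_true(all(diff(b$r_peak_times) > 0))
})

test_that("R-peak detection stays above 99% sensitivity and precision at SNR 10", {
  set.seed(2)
  cfg <- cardiac_sim_config(rr_cv = 0.05, arrhythmia_rate = 0, noise_sd = 0.1)
  e <- simulate_ecg(cfg, 600)
  b <- detect_r_peaks(e$signal)
  tol <- 0.010
  sens <- mean(vapply(e$beat_times,
                      function(t) any(abs(b$r_peak_times - t) <= tol), logical(1)))
  prec <- mean(vapply(b$r_peak_times,
                      function(t) any(abs(e$beat_times - t) <= tol), logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(prec, 0.99)
})

test_that("flat and too-low-rate ECG inputs are handled explicitly", {
  flat <- channel_signal(numeric(5000), 1000, "ECG")
  b <- detect_r_peaks(flat)
  expect_length(b$r_peak_times, 0)
  slow <- channel_signal(rnorm(1000), 250, "ECG")
  expect_error(detect_r_peaks(slow), "sampling rate")
})

test_that("arrhythmia rule flags only intervals exceeding 1.5x the local median", {
  # constant RR: no events
  expect_length(detect_arrhythmia(make_beats(rep(0.2, 100))), 0)
  # a single doubled interval is flagged at its midpoint
  rr <- rep(0.2, 100); rr[50] <- 0.4
  ev <- detect_arrhythmia(make_beats(rr))
  expect_length(ev, 1)
  tp <- make_beats(rr)$r_peak_times
  expect_equal(ev, (tp[50] + tp[51]) / 2)
  # uniformly slow heart: rule is relative, no events
  expect_length(detect_arrhythmia(make_beats(rep(0.4, 100))), 0)
  # an interval at exactly 1.5x the median is not flagged (strict >)
  rr2 <- rep(0.2, 100); rr2[50] <- 0.3
  expect_length(detect_arrhythmia(make_beats(rr2)), 0)
})

test_that("per-minute metrics follow their closed forms", {
  # constant RR: zero HRV everywhere
  b <- make_beats(rep(0.2, 600))
  m <- compute_minute_metrics(b, numeric(0), 120)
  expect_equal(m$hrv_per_min, rep(0, 2))
  # alternating 0.18/0.22 s: population CV = 0.02/0.20 = 0.1
  b2 <- make_beats(rep(c(0.18, 0.22), 150))
  m2 <- compute_minute_metrics(b2, numeric(0), 60)
  expect_equal(m2$hrv_per_min[1], 0.1, tolerance = 1e-6)
  # arrhythmia counting lands in the right bin
  m3 <- compute_minute_metrics(b, c(300.5, 310.2, 330.9), 600)
  expect_equal(m3$arrhythmia_rate_per_min[6], 3)
  expect_equal(sum(m3$arrhythmia_rate_per_min), 3)
  # bins with < 2 RR intervals give missing HRV
  b4 <- make_beats(c(0.2))
  m4 <- compute_minute_metrics(b4, numeric(0), 120)
  expect_true(all(is.na(m4$hrv_per_min)))
})

test_that("delta metrics subtract the pre baseline from the post window", {
  pre <- make_metrics(arr = rep(0.1, 15), hrv = rep(0.03, 15))
  post <- make_metrics(arr = rep(0.5, 35), hrv = rep(0.03, 35))
  d <- compute_deltas(pre, post)
  expect_equal(d$delta_arr, 0.4)
  expect_equal(d$delta_hrv, 0)
  # identical metrics give (0, 0)
  d0 <- compute_deltas(make_metrics(rep(0.2, 10), rep(0.05, 10)),
                       make_metrics(rep(0.2, 30), rep(0.05, 30)))
  expect_equal(d0$delta_arr, 0)
  expect_equal(d0$delta_hrv, 0)
  # missing HRV bins are excluded from the means
  hrv <- c(rep(NA, 5), rep(0.06, 30))
  d1 <- compute_deltas(pre, make_metrics(rep(0, 35), hrv))
  expect_equal(d1$delta_hrv, 0.03)
  # insufficient coverage errors
  expect_error(compute_deltas(make_metrics(rep(0, 5), rep(0, 5)), post), "pre")
})

test_that("susceptibility rule is a strict OR over the two thresholds", {
  expect_identical(classify_susceptibility(0.25, 0.00), "susceptible")
  expect_identical(classify_susceptibility(0.00, 0.03), "susceptible")
  expect_identical(classify_susceptibility(0.10, 0.01), "resilient")
  # boundary values read "more than" literally
  expect_identical(classify_susceptibility(0.20, 0.02), "resilient")
  expect_error(classify_susceptibility(NA, 0.01))
})

test_that("end-to-end HRV and arrhythmia-rate recovery on 30-min ECG", {
  set.seed(3)
  cfg <- cardiac_sim_config(rr_cv = 0.05, arrhythmia_rate = 0, noise_sd = 0.1)
  e <- simulate_ecg(cfg, 1800)
  b <- detect_r_peaks(e$signal)
  m <- compute_minute_metrics(b, detect_arrhythmia(b), 1800)
  expect_lt(abs(mean(m$hrv_per_min, na.rm = TRUE) - 0.05) / 0.05, 0.1)

  set.seed(4)
  cfg2 <- cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0.5, noise_sd = 0.1)
  e2 <- simulate_ecg(cfg2, 1800)
  b2 <- detect_r_peaks(e2$signal)
  n_det <- length(detect_arrhythmia(b2))
  # within the Poisson 95% interval of rate 0.5/min over 30 min
  expect_gte(n_det, qpois(0.025, 15))
  expect_lte(n_det, qpois(0.975, 15))
})
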