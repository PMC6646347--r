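test_that("zero-jitter, zero-arrhythmia ECG gives the deterministic beat grid", {
  set.seed(1)
  cfg <- cardiac_sim_config(rr_cv = 0, arrhythmia_rate = 0, noise_sd = 0)
  bt <- simulate_beat_times(cfg, 60)
  expect_length(bt$beat_times, 300)
  expect_equal(diff(bt$beat_times), rep(0.2, 299), tolerance = 1e-9)
  expect_length(bt$arrhythmia_times, 0)
})

test_that("skipped-beat counts follow the configured Poisson law", {
  # 100 seeds at 1/min over 600 s: total deletions ~ Poisson(1000)
  counts <- vapply(1:100, function(s) {
    set.seed(s)
    cfg <- cardiac_sim_config(arrhythmia_rate = 1)
    length(simulate_beat_times(cfg, 600)$arrhythmia_times)
  }, numeric(1))
  total <- sum(counts)
  expect_gt(total, qpois(0.005, 100 * 10))
  expect_lt(total, qpois(0.995, 100 * 10))
  # per-run spread is Poisson-like, not degenerate
  expect_gt(var(counts), 0)
})

test_that("generated RR coefficient of variation matches the configured value", {
  set.seed(2)
  cfg <- cardiac_sim_config(rr_cv = 0.05, arrhythmia_rate = 0)
  bt <- simulate_beat_times(cfg, 1800)
  cv <- sd(bt$beat_times |> diff()) / mean(diff(bt$beat_times))
  expect_lt(abs(cv - 0.05) / 0.05, 0.05)
})

test_that("excessive RR jitter is rejected rather than silently truncated", {
  set.seed(3)
  cfg <- cardiac_sim_config(rr_cv = 5)
  expect_error(simulate_beat_times(cfg, 60), "truncation")
})

test_that("EMG generator honors bout structure and target rms", {
  set.seed(4)
  # sleep disabled
  cfg <- emg_sim_config(mean_bout_s = list(wake = 30, sleep = 0), fs = 500)
  e <- simulate_emg(cfg, 120)
  expect_equal(nrow(e$sleep_intervals), 0)
  # wake rms within 10% in 0.5-s bins
  r <- compute_rms(e$signal, 0.5)
  expect_lt(abs(mean(r$rms) - cfg$wake_rms) / cfg$wake_rms, 0.1)

  # near-deterministic single sleep bout: tiny wake bouts impossible, so use
  # construction via long means and check interval bookkeeping instead
  set.seed(5)
  cfg2 <- emg_sim_config(mean_bout_s = list(wake = 1e6, sleep = 30), fs = 200)
  e2 <- simulate_emg(cfg2, 120)
  expect_equal(nrow(e2$sleep_intervals), 0)  # first (wake) bout spans the session
})

test_that("LFP envelope correlation endpoints are recovered by the pipeline", {
  pipeline_r <- function(rho, pink, dur = 300, seed = 6) {
    set.seed(seed)
    cfg <- lfp_sim_config(regions = c("PPC", "RSC"), fs = 400,
                          band_params = list(theta = list(lo = 6, hi = 10,
                                                          rho = rho, amplitude = 1)),
                          pink_noise_sd = pink)
    l <- simulate_lfp(cfg, dur)
    sp <- lapply(l$signals, function(ch) compute_spectrogram(downsample_lfp(ch)))
    unname(pairwise_power_correlation(sp, "theta")["PPC-RSC"])
  }
  # common factor only, no noise: identical envelopes
  expect_equal(pipeline_r(1, pink = 0), 1, tolerance = 0.02)
  # independence: mean over 50 seeds near 0
  r0 <- vapply(1:50, function(s) pipeline_r(0, pink = 0.5, dur = 60, seed = s),
               numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
})

test_that("cohort generation is deterministic and correctly shaped", {
  cfg <- tiny_cohort_config(seed = 11)
  coh1 <- simulate_cohort(cfg)
  expect_length(coh1, 4)
  expect_named(coh1, c("S1", "S2", "R1", "R2"))
  sess <- unlist(coh1, recursive = FALSE)
  expect_length(sess, 8)   # 4 rats x 2 phases
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1, coh2)
  # ground truth present and labeled
  expect_identical(coh1$S1$pre$ground_truth$true_group, "susceptible")
  expect_identical(coh1$R2$post$ground_truth$true_group, "resilient")
  # per-rat streaming matches the batch generator
  expect_identical(simulate_rat(cfg, 3), coh1$R1)
})

test_that("simulated cohort margins put every rat on the right side of the rule", {
  cfg <- tiny_cohort_config(seed = 12, n_susceptible = 3, n_resilient = 3)
  coh <- simulate_cohort(cfg)
  for (id in names(coh)) {
    a <- cardiac_analysis(coh[[id]]$pre, coh[[id]]$post)
    expect_identical(a$label, coh[[id]]$pre$ground_truth$true_group)
  }
})
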