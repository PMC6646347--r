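# Small in-code fixtures shared across tests.

# a minimal valid session: short ECG + EMG, optionally some LFP regions
make_tiny_session <- function(rat_id = "T1", phase = "pre", duration = 2,
                              regions = character(0), fs = 1000) {
  n <- duration * fs
  chans <- list(channel_signal(sin(2 * pi * 5 * (0:(n - 1)) / fs), fs, "ECG"),
                channel_signal(rnorm(n), fs, "EMG"))
  for (r in regions)
    chans <- c(chans, list(channel_signal(rnorm(n), fs, r)))
  recording_session(rat_id, phase, duration, chans)
}

# beat series with given RR intervals starting at t0 (rr stored exactly, so
# threshold comparisons in tests are free of cumsum/diff rounding)
make_beats <- function(rr, t0 = 0.2) {
  times <- t0 + cumsum(c(0, rr))
  structure(list(r_peak_times = times, rr_intervals = rr),
            class = "beat_series")
}

# cardiac_metrics with constant per-minute values
make_metrics <- function(arr, hrv) {
  structure(list(minute = seq_along(arr) - 1L,
                 arrhythmia_rate_per_min = arr,
                 hrv_per_min = hrv,
                 arrhythmia_times = numeric(0)),
            class = "cardiac_metrics")
}

# rms_series directly from values
make_rms <- function(values, bin_s = 0.5) {
  structure(list(bin_times = (seq_along(values) - 1) * bin_s,
                 rms = values, bin_s = bin_s),
            class = "rms_series")
}

# small scaled cohort config for pipeline tests: study-group structure kept,
# durations and rates reduced for runtime
tiny_cohort_config <- function(seed = 11, n_susceptible = 2, n_resilient = 2,
                               with_lfp = FALSE) {
  lfp_regions <- if (with_lfp) c("PL", "S1", "HPC") else character(0)
  cohort_sim_config(
    n_susceptible = n_susceptible, n_resilient = n_resilient,
    cardiac_pre = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0, ecg_fs = 500),
    cardiac_post_susceptible = cardiac_sim_config(rr_cv = 0.07, arrhythmia_rate = 0.4,
                                                  ecg_fs = 500),
    cardiac_post_resilient = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0,
                                                ecg_fs = 500),
    lfp_susceptible = lfp_sim_config(regions = lfp_regions, fs = 400,
      band_params = default_band_params(rho = 0.3, theta_rho = 0.25)),
    lfp_resilient = lfp_sim_config(regions = lfp_regions, fs = 400,
      band_params = default_band_params(rho = 0.3, theta_rho = 0.6)),
    emg = emg_sim_config(fs = 200),
    missing_region_plan = list(),
    duration_pre = 660, duration_post = 1860,
    seed = seed)
}
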