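#' Simulation configuration constructors
#'
#' Configuration objects for the synthetic biosignal generators. Defaults
#' emulate a resting adult rat: mean RR interval 0.2 s (300 bpm), beat-to-beat
#' coefficient of variation 0.03 at rest, no arrhythmias at rest, unit R-wave
#' amplitude with additive white noise of SD 0.1 (amplitude SNR 10).
#'
#' @param mean_rr Mean RR interval in seconds.
#' @param rr_cv Coefficient of variation of the RR intervals (unitless).
#' @param arrhythmia_rate Poisson rate of skipped beats, events/min.
#' @param ecg_fs ECG sampling rate, Hz.
#' @param noise_sd SD of additive white noise, in units of the R-wave amplitude.
#' @return A config list.
#' @name sim-configs
#' @export
cardiac_sim_config <- function(mean_rr = 0.2, rr_cv = 0.03, arrhythmia_rate = 0,
                               ecg_fs = 1000, noise_sd = 0.1) {
  stopifnot(mean_rr > 0, rr_cv >= 0, arrhythmia_rate >= 0, ecg_fs > 0, noise_sd >= 0)
  list(mean_rr = mean_rr, rr_cv = rr_cv, arrhythmia_rate = arrhythmia_rate,
       ecg_fs = ecg_fs, noise_sd = noise_sd)
}

#' @rdname sim-configs
#' @param wake_rms,sleep_rms Target EMG rms amplitude during wake and sleep
#'   bouts (signal units); `sleep_rms < wake_rms`.
#' @param mean_bout_s Named list with exponential mean bout durations in
#'   seconds for `wake` and `sleep`; a `sleep` mean of 0 disables sleep.
#' @param fs EMG sampling rate, Hz.
#' @export
emg_sim_config <- function(wake_rms = 1, sleep_rms = 0.2,
                           mean_bout_s = list(wake = 120, sleep = 60),
                           fs = 1000) {
  stopifnot(sleep_rms >= 0, sleep_rms < wake_rms, fs > 0,
            mean_bout_s$wake > 0, mean_bout_s$sleep >= 0)
  list(wake_rms = wake_rms, sleep_rms = sleep_rms, mean_bout_s = mean_bout_s, fs = fs)
}

#' @rdname sim-configs
#' @param regions Character vector of LFP regions to simulate (subset of
#'   [LFP_REGIONS]).
#' @param band_params Named list, one entry per band, each with elements
#'   `lo`, `hi` (carrier band edges in Hz), `rho` (target pairwise power
#'   envelope correlation, in `[0, 1]`) and `amplitude`.
#' @param envelope_log_sd SD of the log power envelope (see vignette).
#' @param pink_noise_sd SD of the additive 1/f background noise.
#' @export
lfp_sim_config <- function(regions = LFP_REGIONS, fs = 2000,
                           band_params = default_band_params(),
                           envelope_log_sd = 0.5, pink_noise_sd = 0.5) {
  stopifnot(all(regions %in% LFP_REGIONS), fs > 0, envelope_log_sd >= 0,
            pink_noise_sd >= 0)
  for (bp in band_params)
    stopifnot(bp$lo < bp$hi, bp$rho >= 0, bp$rho <= 1, bp$amplitude >= 0)
  list(regions = regions, fs = fs, band_params = band_params,
       envelope_log_sd = envelope_log_sd, pink_noise_sd = pink_noise_sd)
}

#' Default LFP band parameters for the generator
#'
#' One carrier per analysis band (delta 1-4, mid 4-6, theta 6-10, beta 10-25,
#' gamma 25-45 Hz) with amplitudes decreasing with frequency, as in rodent
#' cortical LFP, and a common envelope correlation `rho` per band.
#'
#' @param rho Envelope correlation applied to every band (default 0.3).
#' @param theta_rho Optional override for the theta band.
#' @return Named list of per-band parameter lists.
#' @export
default_band_params <- function(rho = 0.3, theta_rho = rho) {
  bands <- lfp_bands()
  amp <- c(delta = 1, mid = 0.8, theta = 0.8, beta = 0.5, gamma = 0.3)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    b <- bands$name[i]
    list(lo = bands$lo[i], hi = bands$hi[i],
         rho = if (b == "theta") theta_rho else rho,
         amplitude = unname(amp[b]))
  })
  names(out) <- bands$name
  out
}

#' Simulate beat times with skipped-beat arrhythmias
#'
#' RR intervals are drawn from a truncated normal distribution (mean
#' `mean_rr`, SD `rr_cv * mean_rr`, symmetrically truncated to
#' `(0, 2 * mean_rr)`, which preserves the mean) and summed cumulatively. Arrhythmia events arrive as a Poisson process at
#' `arrhythmia_rate` per minute; each event deletes one interior beat,
#' locally doubling the RR interval (a "skipped" R-peak).
#'
#' @param cfg A [cardiac_sim_config()].
#' @param duration Duration in seconds (> 0).
#' @return List with `beat_times` (surviving beats, s) and
#'   `arrhythmia_times` (times of the deleted beats, s).
#' @export
simulate_beat_times <- function(cfg, duration) {
  stopifnot(duration > 0)
  sd_rr <- cfg$rr_cv * cfg$mean_rr
  n_exp <- ceiling(duration / cfg$mean_rr * 1.2) + 10
  beats <- numeric(0)
  t <- 0
  repeat {
    rr <- stats::rnorm(n_exp, cfg$mean_rr, sd_rr)
    # symmetric truncation to (0, 2*mean_rr): keeps the mean exact and keeps
    # normal RR jitter clearly below the doubled interval of a skipped beat
    ok <- rr > 0 & rr < 2 * cfg$mean_rr
    if (mean(ok) < 0.5)
      stop("rr_cv too large: truncation rejects more than 50% of RR draws")
    rr <- rr[ok]
    new <- t + cumsum(rr)
    beats <- c(beats, new)
    t <- beats[length(beats)]
    if (t > duration) break
  }
  beats <- beats[beats <= duration]
  arrhythmia_times <- numeric(0)
  if (cfg$arrhythmia_rate > 0 && length(beats) > 4) {
    n_ev <- stats::rpois(1, cfg$arrhythmia_rate * duration / 60)
    if (n_ev > 0) {
      ev_t <- stats::runif(n_ev, 0, duration)
      # delete the beat nearest each event; interior beats only, no double hits
      idx <- vapply(ev_t, function(tt) which.min(abs(beats - tt)), integer(1))
      idx <- pmin(pmax(idx, 2L), length(beats) - 1L)
      idx <- unique(idx)
      arrhythmia_times <- sort(beats[idx])
      beats <- beats[-idx]
    }
  }
  list(beat_times = beats, arrhythmia_times = arrhythmia_times)
}

# unit-amplitude Gaussian R-wave template (sd 5 ms) evaluated on sample grid
add_r_waves <- function(x, fs, beat_times, sigma = 0.005) {
  half <- ceiling(5 * sigma * fs)
  n <- length(x)
  for (bt in beat_times) {
    c_idx <- round(bt * fs) + 1
    lo <- max(1, c_idx - half); hi <- min(n, c_idx + half)
    if (lo > hi) next
    tt <- ((lo:hi) - 1) / fs
    x[lo:hi] <- x[lo:hi] + exp(-(tt - bt)^2 / (2 * sigma^2))
  }
  x
}

#' Simulate an ECG channel
#'
#' Generates beat times via [simulate_beat_times()] and renders a waveform as
#' a unit-amplitude Gaussian R-wave template (SD 5 ms) at each surviving beat
#' plus white noise.
#'
#' @inheritParams simulate_beat_times
#' @return List with `signal` (a [channel_signal()] labeled `"ECG"`),
#'   `beat_times` and `arrhythmia_times`.
#' @export
simulate_ecg <- function(cfg, duration) {
  bt <- simulate_beat_times(cfg, duration)
  n <- round(duration * cfg$ecg_fs)
  x <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  x <- add_r_waves(x, cfg$ecg_fs, bt$beat_times)
  list(signal = channel_signal(x, cfg$ecg_fs, "ECG"),
       beat_times = bt$beat_times, arrhythmia_times = bt$arrhythmia_times)
}

#' Simulate an EMG channel with wake/sleep bouts
#'
#' The session alternates wake and sleep bouts with exponentially distributed
#' durations (starting awake); the signal is white noise whose SD equals the
#' state's target rms. True sleep intervals are returned exactly.
#'
#' @param cfg An [emg_sim_config()].
#' @param duration Duration in seconds.
#' @return List with `signal` (a [channel_signal()] labeled `"EMG"`) and
#'   `sleep_intervals` (two-column matrix of `[start, end]` times in s,
#'   zero rows when sleep is disabled).
#' @export
simulate_emg <- function(cfg, duration) {
  stopifnot(duration > 0)
  bouts <- list(); t <- 0; state <- "wake"
  while (t < duration) {
    len <- if (state == "sleep" && cfg$mean_bout_s$sleep == 0) 0 else
      stats::rexp(1, 1 / cfg$mean_bout_s[[state]])
    if (len > 0) {
      end <- min(t + len, duration)
      bouts <- c(bouts, list(list(state = state, start = t, end = end)))
      t <- end
    }
    state <- if (state == "wake") "sleep" else "wake"
  }
  n <- round(duration * cfg$fs)
  x <- stats::rnorm(n)
  sleep <- matrix(numeric(0), ncol = 2)
  for (b in bouts) {
    i0 <- floor(b$start * cfg$fs) + 1
    i1 <- min(n, ceiling(b$end * cfg$fs))
    rms <- if (b$state == "wake") cfg$wake_rms else cfg$sleep_rms
    x[i0:i1] <- x[i0:i1] * rms
    if (b$state == "sleep") sleep <- rbind(sleep, c(b$start, b$end))
  }
  colnames(sleep) <- c("start", "end")
  list(signal = channel_signal(x, cfg$fs, "EMG"), sleep_intervals = sleep)
}

# band-limited unit-variance noise via frequency-domain synthesis:
# complex Gaussian coefficients on [lo, hi) Hz, zero elsewhere, inverse FFT.
synth_band_noise <- function(n, fs, lo, hi) {
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:floor(n / 2)              # positive non-DC, non-Nyquist bins
  inband <- half[freqs[half] >= lo & freqs[half] < hi]
  coef <- complex(real = stats::rnorm(length(inband)),
                  imaginary = stats::rnorm(length(inband)))
  spec <- complex(length.out = n)
  spec[inband] <- coef
  spec[n + 2 - inband] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# 1/f ("pink") noise over 1-100 Hz, scaled to target sd
synth_pink_noise <- function(n, fs, sd_target, f_lo = 1, f_hi = 100) {
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:floor(n / 2)
  inband <- half[freqs[half] >= f_lo & freqs[half] < min(f_hi, fs / 2)]
  amp <- 1 / sqrt(freqs[inband])
  coef <- amp * complex(real = stats::rnorm(length(inband)),
                        imaginary = stats::rnorm(length(inband)))
  spec <- complex(length.out = n)
  spec[inband] <- coef
  spec[n + 2 - inband] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x) * sd_target
}

#' Simulate multichannel LFP with controlled envelope correlation
#'
#' For each band and region, a log-normal power envelope at 5-s resolution is
#' built from a shared latent factor: `g = sqrt(rho_lat) * z_common +
#' sqrt(1 - rho_lat) * z_region`, power envelope `exp(sigma * g)` with
#' `sigma = envelope_log_sd`. The latent correlation `rho_lat` inverts the
#' log-normal Pearson distortion so that the power envelopes of every region
#' pair have Pearson correlation `rho` exactly in expectation. The amplitude
#' envelope (the square root of the power envelope) modulates a band-limited
#' carrier normalized to unit Hann-weighted power within each 5-s window, so
#' the spectrogram band power of every region tracks its power envelope.
#' Carriers are summed across bands and 1/f noise is added.
#'
#' @param cfg An [lfp_sim_config()].
#' @param duration Duration in seconds (>= 30).
#' @param window_s Envelope resolution in seconds (default 5, matching the
#'   spectrogram window).
#' @return List with `signals` (named list of [channel_signal()] per region)
#'   and `band_pair_correlations` (named numeric, configured `rho` per band).
#' @export
simulate_lfp <- function(cfg, duration, window_s = 5) {
  if (length(cfg$regions) == 0) stop("region set is empty")
  stopifnot(duration >= 30)
  fs <- cfg$fs
  n <- round(duration * fs)
  spw <- round(window_s * fs)                # samples per envelope window
  n_win <- ceiling(n / spw)
  win_of_sample <- rep(seq_len(n_win), each = spw, length.out = n)
  sigma <- cfg$envelope_log_sd
  sig <- matrix(0, n, length(cfg$regions))
  colnames(sig) <- cfg$regions
  for (bname in names(cfg$band_params)) {
    bp <- cfg$band_params[[bname]]
    # latent Gaussian correlation that yields Pearson correlation rho between
    # the log-normal POWER envelopes: inverts the log-normal distortion
    rho_lat <- if (sigma > 0)
      log(1 + bp$rho * (exp(sigma^2) - 1)) / sigma^2 else bp$rho
    z_common <- stats::rnorm(n_win)
    for (j in seq_along(cfg$regions)) {
      z_j <- stats::rnorm(n_win)
      g <- sqrt(rho_lat) * z_common + sqrt(1 - rho_lat) * z_j
      amp_env <- exp(sigma * g / 2)          # power envelope exp(sigma * g)
      carrier <- synth_band_noise(n, fs, bp$lo, bp$hi)
      # normalize each 5-s window to unit Hann-weighted power, the quantity a
      # Hann-tapered spectrogram measures, so band power follows the envelope
      hann <- 0.5 * (1 - cos(2 * pi * (0:(spw - 1)) / (spw - 1)))
      w2 <- rep_len(hann^2, n)
      w_rms <- sqrt(tapply(w2 * carrier^2, win_of_sample, sum) /
                      tapply(w2, win_of_sample, sum))
      carrier <- carrier / w_rms[win_of_sample]
      sig[, j] <- sig[, j] + bp$amplitude * amp_env[win_of_sample] * carrier
    }
  }
  if (cfg$pink_noise_sd > 0)
    for (j in seq_along(cfg$regions))
      sig[, j] <- sig[, j] + synth_pink_noise(n, fs, cfg$pink_noise_sd)
  signals <- lapply(seq_along(cfg$regions), function(j)
    channel_signal(sig[, j], fs, cfg$regions[j]))
  names(signals) <- cfg$regions
  rho <- vapply(cfg$band_params, function(bp) bp$rho, numeric(1))
  list(signals = signals, band_pair_correlations = rho)
}
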