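#' Frequency band definitions
#'
#' The five analysis bands on half-open intervals: delta `[1, 4)`, a middle
#' 4--6 Hz band between delta and theta, theta `[6, 10)`, beta `[10, 25)` and
#' gamma `[25, 45)` Hz. Half-open intervals make the bands an exact partition
#' of `[1, 45)`.
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
lfp_bands <- function() {
  data.frame(name = c("delta", "mid", "theta", "beta", "gamma"),
             lo = c(1, 4, 6, 10, 25),
             hi = c(4, 6, 10, 25, 45),
             stringsAsFactors = FALSE)
}

#' Downsample an LFP channel
#'
#' Anti-alias low-pass filtering (8th-order Butterworth, cutoff 80 Hz,
#' zero-phase) followed by decimation by the integer ratio
#' `sampling_rate / target_fs`.
#'
#' @param lfp A [channel_signal()].
#' @param target_fs Target sampling rate in Hz (default 200); the ratio to
#'   the input rate must be an integer.
#' @param cutoff_hz Anti-alias cutoff (default 80 Hz).
#' @return A [channel_signal()] at `target_fs` with
#'   `floor(n * target_fs / fs)` samples.
#' @export
downsample_lfp <- function(lfp, target_fs = 200, cutoff_hz = 80) {
  fs <- lfp$sampling_rate
  if (fs < target_fs) stop("input rate ", fs, " Hz below target ", target_fs, " Hz")
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sampling ratio ", fs, "/", target_fs, " is not an integer")
  ratio <- round(ratio)
  x <- lfp$samples
  if (ratio > 1) {
    bf <- signal::butter(8, cutoff_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1, length(x), by = ratio)]
  }
  channel_signal(x, target_fs, lfp$label, lfp$start_time)
}

#' Windowed FFT power spectrogram with band aggregation
#'
#' Splits the signal into non-overlapping windows (default 5 s), applies a
#' Hann taper, and computes one-sided FFT power per frequency bin (0.2 Hz
#' spacing at the default window). Bins are restricted to `[1, 45)` Hz and
#' band powers are bin-sums per [lfp_bands()] definition, so the five band
#' powers exactly partition the total `[1, 45)` power in every window.
#'
#' @param lfp A [channel_signal()] (typically the 200 Hz output of
#'   [downsample_lfp()]).
#' @param window_s Window length in seconds (default 5).
#' @param f_lo,f_hi Retained frequency range in Hz (default `[1, 45)`).
#' @return A `band_power_series` list: `region`, `window_times` (window
#'   starts, s), `freq` (bin centers, Hz), `power` (windows x bins matrix,
#'   arbitrary power units) and `band_power` (windows x 5 matrix).
#' @export
compute_spectrogram <- function(lfp, window_s = 5, f_lo = 1, f_hi = 45) {
  fs <- lfp$sampling_rate
  n_win_samp <- round(window_s * fs)
  n_win <- floor(length(lfp$samples) / n_win_samp)
  if (n_win < 1) stop("signal shorter than one ", window_s, "-s window")
  df <- fs / n_win_samp
  freqs <- (0:(n_win_samp - 1)) * df
  keep <- which(freqs >= f_lo & freqs < f_hi)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_win_samp - 1)) / (n_win_samp - 1)))  # Hann
  norm <- 2 / (fs * sum(w^2))
  power <- matrix(0, n_win, length(keep))
  for (k in seq_len(n_win)) {
    seg <- lfp$samples[((k - 1) * n_win_samp + 1):(k * n_win_samp)]
    seg <- seg - mean(seg)    # remove DC so offsets cannot leak into low bins
    X <- stats::fft(w * seg)
    power[k, ] <- norm * Mod(X[keep])^2
  }
  bands <- lfp_bands()
  band_power <- matrix(0, n_win, nrow(bands),
                       dimnames = list(NULL, bands$name))
  for (i in seq_len(nrow(bands))) {
    sel <- freqs[keep] >= bands$lo[i] & freqs[keep] < bands$hi[i]
    band_power[, i] <- if (any(sel)) rowSums(power[, sel, drop = FALSE]) else 0
  }
  structure(list(region = lfp$label,
                 window_times = lfp$start_time + (seq_len(n_win) - 1) * window_s,
                 freq = freqs[keep], power = power, band_power = band_power),
            class = "band_power_series")
}

#' Time-averaged power spectrum
#'
#' Mean power per frequency bin across all windows of a spectrogram
#' (restricted to its retained 1--45 Hz range).
#'
#' @param spectrogram A `band_power_series` from [compute_spectrogram()].
#' @return Named numeric vector of mean power per bin (names = Hz).
#' @export
average_spectrum <- function(spectrogram) {
  stats::setNames(colMeans(spectrogram$power),
                  formatC(spectrogram$freq, format = "f", digits = 1))
}

#' Spectrograms for all LFP regions of a session
#'
#' Downsamples each LFP channel to 200 Hz and computes its spectrogram,
#' optionally restricted to the first `max_duration_s` seconds of the session.
#'
#' @param session A [recording_session()].
#' @param max_duration_s Optional truncation in seconds (e.g. 1800 to analyze
#'   the first 30 min of a post session).
#' @param target_fs Rate passed to [downsample_lfp()].
#' @return Named list of `band_power_series`, one per present region
#'   (possibly empty).
#' @export
session_spectrograms <- function(session, max_duration_s = NULL, target_fs = 200) {
  regs <- session_regions(session)
  out <- lapply(regs, function(r) {
    ch <- session$channels[[r]]
    if (!is.null(max_duration_s)) {
      n <- min(length(ch$samples), round(max_duration_s * ch$sampling_rate))
      ch <- channel_signal(ch$samples[seq_len(n)], ch$sampling_rate, ch$label,
                           ch$start_time)
    }
    compute_spectrogram(downsample_lfp(ch, target_fs))
  })
  names(out) <- regs
  out
}
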