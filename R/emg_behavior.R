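#' EMG root-mean-square per bin
#'
#' The session mean is subtracted once (rms then reflects absolute amplitude
#' changes relative to the average), and the rms is computed in consecutive
#' bins (default 500 ms). A trailing partial bin is kept if it holds at least
#' one sample.
#'
#' @param emg A [channel_signal()] (typically labeled `"EMG"`).
#' @param bin_s Bin width in seconds (> 0, default 0.5).
#' @return An `rms_series` list: `bin_times` (bin start, s), `rms`, `bin_s`.
#' @export
compute_rms <- function(emg, bin_s = 0.5) {
  stopifnot(bin_s > 0)
  x <- emg$samples
  if (length(x) == 0) stop("empty EMG signal")
  x <- x - mean(x)
  spb <- round(bin_s * emg$sampling_rate)
  bin <- (seq_along(x) - 1) %/% spb + 1
  rms <- sqrt(tapply(x^2, bin, mean))
  structure(list(bin_times = emg$start_time + (seq_along(rms) - 1) * bin_s,
                 rms = as.numeric(rms), bin_s = bin_s),
            class = "rms_series")
}

#' Detect sleep periods from the EMG rms
#'
#' The threshold is `mean - SD`, where mean and SD are computed over the rms
#' values lying between their 20th and 80th percentiles (trimmed statistics,
#' robust to sleep and artifact tails). Sleep periods are maximal runs of
#' consecutive bins strictly below the threshold lasting at least
#' `min_duration_s` (default 10 s). The threshold is invariant to a global
#' gain applied to the EMG signal.
#'
#' @param rms An `rms_series` from [compute_rms()] with >= 40 bins.
#' @param min_duration_s Minimum sleep period duration in seconds.
#' @return A two-column matrix (`start`, `end`) of sleep intervals in
#'   seconds; zero rows when no sleep is detected.
#' @export
detect_sleep <- function(rms, min_duration_s = 10) {
  v <- rms$rms
  if (length(v) < 40) stop("need at least 40 rms bins to estimate the threshold")
  q <- stats::quantile(v, c(0.2, 0.8), names = FALSE)
  band <- v[v >= q[1] & v <= q[2]]
  thr <- mean(band) - stats::sd(band)
  below <- v < thr
  min_bins <- ceiling(min_duration_s / rms$bin_s)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_bins
  out <- cbind(start = rms$bin_times[starts[keep]],
               end = rms$bin_times[ends[keep]] + rms$bin_s)
  if (!any(keep)) out <- matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("start", "end")))
  out
}

#' Total sleep duration in seconds
#'
#' @param intervals Matrix from [detect_sleep()].
#' @return Total duration in seconds.
#' @export
sleep_duration <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(intervals[, "end"] - intervals[, "start"])
}

#' Instantaneous locomotion speed from a position track
#'
#' `speed[i]` is the Euclidean displacement from frame `i` to `i + 1` divided
#' by the frame interval (~333 ms at the nominal 3 Hz).
#'
#' @param track A [position_track()] with >= 2 frames.
#' @return List with `times` (frame starts, s) and `speed` (cm/s).
#' @export
compute_speed <- function(track) {
  if (length(track$times) < 2) stop("need at least 2 frames")
  dt <- diff(track$times)
  if (any(dt <= 0)) stop("position times are not strictly increasing")
  d <- sqrt(diff(track$xy[, 1])^2 + diff(track$xy[, 2])^2)
  list(times = track$times[-length(track$times)], speed = d / dt)
}
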