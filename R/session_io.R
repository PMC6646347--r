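#' Channel label vocabulary
#'
#' Six cortical LFP regions in anterior-to-posterior display order, plus the
#' peripheral ECG and EMG channels.
#'
#' @format Character vectors.
#' @name channel-vocabulary
NULL

#' @rdname channel-vocabulary
#' @export
LFP_REGIONS <- c("PL", "S1", "PPC", "HPC", "RSC", "V1")

#' @rdname channel-vocabulary
#' @export
CHANNEL_LABELS <- c(LFP_REGIONS, "ECG", "EMG")

#' Construct a single-channel signal
#'
#' A uniformly sampled signal with a label from the closed channel vocabulary
#' (`PL`, `S1`, `PPC`, `HPC`, `RSC`, `V1`, `ECG`, `EMG`).
#'
#' @param samples Numeric vector of samples (signal units, e.g. mV).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Channel label, one of [CHANNEL_LABELS].
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `channel_signal`.
#' @export
channel_signal <- function(samples, sampling_rate, label, start_time = 0) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!label %in% CHANNEL_LABELS)
    stop("unknown channel label '", label, "'; must be one of: ",
         paste(CHANNEL_LABELS, collapse = ", "))
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         label = label,
         start_time = as.numeric(start_time)),
    class = "channel_signal"
  )
}

#' Construct a position track
#'
#' Video-tracked animal position, nominally at 3 Hz.
#'
#' @param times Frame times in seconds, strictly increasing.
#' @param xy Two-column matrix of x/y coordinates in cm.
#' @return An object of class `position_track`.
#' @export
position_track <- function(times, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must have two columns (x, y)")
  if (length(times) != nrow(xy)) stop("times and xy must have matching length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("position times must be strictly increasing")
  structure(list(times = as.numeric(times), xy = unname(xy)),
            class = "position_track")
}

#' Construct a recording session
#'
#' One rat's multichannel recording for a single phase. A session holds at
#' most one channel per label; ECG and EMG are required for a valid session,
#' and 0--6 LFP regions may be present (recordings with missing regions are
#' analyzed with group-mean imputation downstream).
#'
#' @param rat_id Animal identifier string.
#' @param phase `"pre"` (rest before stress, nominally 1800 s) or `"post"`
#'   (rest after stress, nominally 7200 s).
#' @param duration Session duration in seconds.
#' @param channels List of [channel_signal()] objects.
#' @param position Optional [position_track()].
#' @param ground_truth Optional list of simulation ground truth (see
#'   [simulate_rat()]); present only for synthetic sessions.
#' @return An object of class `recording_session`.
#' @seealso [validate_session()], [write_session()], [read_session()]
#' @export
recording_session <- function(rat_id, phase, duration, channels,
                              position = NULL, ground_truth = NULL) {
  phase <- match.arg(phase, c("pre", "post"))
  labs <- vapply(channels, function(ch) ch$label, character(1))
  names(channels) <- labs
  structure(
    list(rat_id = as.character(rat_id), phase = phase,
         duration = as.numeric(duration), channels = channels,
         position = position, ground_truth = ground_truth),
    class = "recording_session"
  )
}

#' Validate a recording session
#'
#' Checks the session invariants and returns a report instead of throwing:
#' unknown or duplicated channel labels, non-positive sampling rates, missing
#' ECG/EMG, and (as a warning, not an error) sessions shorter than expected,
#' so that short test fixtures remain analyzable.
#'
#' @param session A [recording_session()].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows iff all invariants hold.
#' @export
validate_session <- function(session) {
  viol <- function(sev, msg) data.frame(severity = sev, message = msg,
                                        stringsAsFactors = FALSE)
  out <- list()
  labs <- vapply(session$channels, function(ch) ch$label, character(1))
  bad <- setdiff(labs, CHANNEL_LABELS)
  for (b in bad) out <- c(out, list(viol("error", paste0("unknown channel label '", b, "'"))))
  dup <- unique(labs[duplicated(labs)])
  for (d in dup) out <- c(out, list(viol("error", paste0("duplicate channel label '", d, "'"))))
  for (req in c("ECG", "EMG"))
    if (!req %in% labs)
      out <- c(out, list(viol("error", paste0("required channel '", req, "' is missing"))))
  for (ch in session$channels) {
    if (!is.numeric(ch$sampling_rate) || ch$sampling_rate <= 0)
      out <- c(out, list(viol("error", paste0("channel '", ch$label,
                                              "' has non-positive sampling rate"))))
  }
  nominal <- if (identical(session$phase, "pre")) 1800 else 7200
  if (is.finite(session$duration) && session$duration < nominal)
    out <- c(out, list(viol("warning",
      sprintf("session duration %.1f s is shorter than the nominal %d s %s session",
              session$duration, nominal, session$phase))))
  if (!is.null(session$position) && length(session$position$times) > 1 &&
      any(diff(session$position$times) <= 0))
    out <- c(out, list(viol("error", "position times are not strictly increasing")))
  if (length(out) == 0)
    return(data.frame(severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write a session container to disk
#'
#' The container is a directory holding one numeric column file per channel
#' plus a `metadata.json` sidecar (rat id, phase, duration, per-channel label,
#' sampling rate and file name). Two channel dialects are supported:
#' `"bin"` (little-endian IEEE-754 doubles, lossless and compact) and `"csv"`
#' (header `time_s,value`, UTF-8, `.` decimal). The round trip
#' `read_session(write_session(s))` reproduces samples bit-exactly (binary
#' dialect) and metadata exactly.
#'
#' @param session A valid [recording_session()].
#' @param path Directory to create/overwrite.
#' @param format Channel file dialect, `"bin"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("bin", "csv")) {
  format <- match.arg(format)
  labs <- vapply(session$channels, function(ch) ch$label, character(1))
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) stop("duplicate channel labels: ", paste(dup, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    rat_id = session$rat_id,
    phase = session$phase,
    duration_s = session$duration,
    format = format,
    channels = lapply(session$channels, function(ch) {
      fname <- paste0(ch$label, if (format == "bin") ".f64" else ".csv")
      list(label = ch$label, sampling_rate_hz = ch$sampling_rate,
           start_time_s = ch$start_time, n_samples = length(ch$samples),
           file = fname)
    })
  )
  names(meta$channels) <- NULL
  for (ch in session$channels) {
    fname <- file.path(path, paste0(ch$label, if (format == "bin") ".f64" else ".csv"))
    if (format == "bin") {
      con <- file(fname, "wb")
      writeBin(as.numeric(ch$samples), con, size = 8, endian = "little")
      close(con)
    } else {
      t <- ch$start_time + (seq_along(ch$samples) - 1) / ch$sampling_rate
      utils::write.csv(data.frame(time_s = format(t, digits = 17),
                                  value = format(ch$samples, digits = 17)),
                       fname, row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(session$position)) {
    utils::write.csv(data.frame(time_s = session$position$times,
                                x_cm = session$position$xy[, 1],
                                y_cm = session$position$xy[, 2]),
                     file.path(path, "position.csv"), row.names = FALSE)
    meta$position_file <- "position.csv"
  }
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    meta$ground_truth_file <- "ground_truth.json"
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session container from disk
#'
#' Reads a container written by [write_session()] (binary or CSV channel
#' dialect), restores the [recording_session()] and checks its invariants.
#' Sessions violating hard invariants (missing ECG, non-positive sampling
#' rate, unknown labels, sample count not matching the declared length) raise
#' an error; warning-level violations (e.g. short sessions) are tolerated.
#'
#' @param path Container directory.
#' @return A [recording_session()].
#' @export
read_session <- function(path) {
  mfile <- file.path(path, "metadata.json")
  if (!file.exists(mfile)) stop("not a session container (missing metadata.json): ", path)
  meta <- jsonlite::read_json(mfile, simplifyVector = FALSE)
  for (key in c("rat_id", "phase", "duration_s", "channels"))
    if (is.null(meta[[key]])) stop("malformed metadata: missing key '", key, "'")
  fmt <- if (is.null(meta$format)) "bin" else meta$format
  channels <- lapply(meta$channels, function(cm) {
    if (is.null(cm$label) || is.null(cm$sampling_rate_hz) || is.null(cm$file))
      stop("malformed channel metadata entry")
    if (cm$sampling_rate_hz <= 0)
      stop("channel '", cm$label, "': sampling_rate must be > 0")
    fname <- file.path(path, cm$file)
    if (!file.exists(fname)) stop("channel file missing: ", fname)
    if (fmt == "bin") {
      n_declared <- as.integer(cm$n_samples)
      n_file <- file.size(fname) / 8
      if (n_file != n_declared)
        stop("channel '", cm$label, "': file holds ", n_file,
             " samples but metadata declares ", n_declared, " (length mismatch)")
      con <- file(fname, "rb")
      x <- readBin(con, "double", n = n_declared, size = 8, endian = "little")
      close(con)
    } else {
      tab <- utils::read.csv(fname)
      x <- as.numeric(tab$value)
      if (!is.null(cm$n_samples) && length(x) != cm$n_samples)
        stop("channel '", cm$label, "': file holds ", length(x),
             " samples but metadata declares ", cm$n_samples, " (length mismatch)")
    }
    channel_signal(x, cm$sampling_rate_hz, cm$label,
                   if (is.null(cm$start_time_s)) 0 else cm$start_time_s)
  })
  pos <- NULL
  if (!is.null(meta$position_file)) {
    ptab <- utils::read.csv(file.path(path, meta$position_file))
    pos <- position_track(ptab$time_s, cbind(ptab$x_cm, ptab$y_cm))
  }
  gt <- NULL
  if (!is.null(meta$ground_truth_file))
    gt <- jsonlite::read_json(file.path(path, meta$ground_truth_file),
                              simplifyVector = TRUE)
  s <- recording_session(meta$rat_id, meta$phase, meta$duration_s, channels,
                         position = pos, ground_truth = gt)
  v <- validate_session(s)
  if (any(v$severity == "error"))
    stop("invalid session container: ",
         paste(v$message[v$severity == "error"], collapse = "; "))
  s
}

#' LFP regions present in a session
#'
#' @param session A [recording_session()].
#' @return Character vector of recorded LFP region labels, in the canonical
#'   anterior-to-posterior order.
#' @export
session_regions <- function(session) {
  intersect(LFP_REGIONS, names(session$channels))
}
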