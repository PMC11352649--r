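#' Multichannel EEG recording container
#'
#' Samples are stored as a numeric matrix (rows = samples, columns =
#' channels, microvolts), with a sample rate in samples/s and the time (ms)
#' of the first sample. Time of sample i is `start_ms + (i-1) * 1000 / fs`.
#'
#' @param data numeric matrix, samples x channels
#' @param channels character channel labels (e.g. c("O1", "O2", "Cz"))
#' @param fs sample rate, samples/s
#' @param start_ms time of the first sample, ms
#' @return an `eeg_recording` object
#' @export
eeg_recording <- function(data, channels, fs, start_ms = 0) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channels), fs > 0)
  colnames(data) <- channels
  structure(list(data = data, channels = channels, fs = fs,
                 start_ms = start_ms),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels (%s) @ %g Hz, start %g ms\n",
              nrow(x$data), length(x$channels),
              paste(x$channels, collapse = ", "), x$fs, x$start_ms))
  invisible(x)
}

sample_times_ms <- function(rec) {
  rec$start_ms + (seq_len(nrow(rec$data)) - 1) * 1000 / rec$fs
}

#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass of the given order and applies it
#' forward-backward (`signal::filtfilt`), so event-locked features are not
#' shifted by group delay. The effective magnitude order is doubled.
#'
#' @param rec an `eeg_recording`
#' @param low_hz,high_hz band edges, 0 < low < high < Nyquist
#' @param order filter order (default 3)
#' @return the filtered recording
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  colnames(out$data) <- rec$channels
  out
}

#' Rectified, smoothed, decimated band-amplitude stream
#'
#' The band-limited signal is rectified (absolute value), averaged over
#' non-overlapping blocks of `ma_points` samples (the 8-point moving average
#' aligned with the decimation grid), and thereby decimated by `ma_points`:
#' 256 samples/s in, 32 samples/s out with the default.
#'
#' @param rec a band-passed `eeg_recording`
#' @param ma_points moving-average length = decimation factor (default 8)
#' @return an `eeg_recording` holding the amplitude streams at `fs/ma_points`
#' @export
amplitude_stream <- function(rec, ma_points = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs %% ma_points != 0) {
    stop("sample rate must be an integer multiple of ma_points")
  }
  n <- nrow(rec$data)
  nblk <- n %/% ma_points
  idx <- rep(seq_len(nblk), each = ma_points)
  amp <- apply(abs(rec$data[seq_len(nblk * ma_points), , drop = FALSE]), 2,
               function(x) as.numeric(tapply(x, idx, mean)))
  eeg_recording(amp, rec$channels, rec$fs / ma_points,
                # block mean sits at the center of its 8-sample window
                start_ms = rec$start_ms + (ma_points - 1) / 2 * 1000 / rec$fs)
}

#' Extract stimulus-locked epochs from a single-channel stream
#'
#' One epoch per marker, covering the half-open window `[t_min, t_max)` ms
#' relative to the marker. Markers whose window falls outside the recording
#' are dropped and counted.
#'
#' @param stream an `eeg_recording` (one channel used; pass `channel`)
#' @param markers_ms marker times in ms
#' @param t_min,t_max epoch window in ms relative to each marker
#'   (defaults -1000 and 8000)
#' @param channel channel label to epoch (default: first channel)
#' @param category optional per-marker labels carried into the epoch set
#' @return an `epoch_set`: list with `epochs` (trials x samples matrix),
#'   `time_ms`, `category`, `rejected`, `fs`, `n_dropped`
#' @export
epoch_stream <- function(stream, markers_ms, t_min = -1000, t_max = 8000,
                         channel = NULL, category = NULL) {
  stopifnot(inherits(stream, "eeg_recording"), t_max > t_min)
  if (is.null(channel)) channel <- stream$channels[1]
  x <- stream$data[, channel]
  fs <- stream$fs
  n_samp <- round((t_max - t_min) * fs / 1000)
  if (is.null(category)) category <- rep(NA_character_, length(markers_ms))
  stopifnot(length(category) == length(markers_ms))
  i0 <- round((markers_ms + t_min - stream$start_ms) * fs / 1000) + 1
  ok <- i0 >= 1 & (i0 + n_samp - 1) <= length(x)
  mat <- matrix(NA_real_, sum(ok), n_samp)
  for (r in seq_len(sum(ok))) {
    s <- i0[ok][r]
    mat[r, ] <- x[s:(s + n_samp - 1)]
  }
  structure(list(
    epochs = mat,
    time_ms = t_min + (seq_len(n_samp) - 1) * 1000 / fs,
    category = category[ok],
    rejected = rep(FALSE, sum(ok)),
    fs = fs,
    n_dropped = sum(!ok)
  ), class = "epoch_set")
}

#' Flag artifact epochs by a k-SD deviation rule
#'
#' Per-epoch statistic: maximum absolute deviation from that epoch's own
#' mean. Epochs whose statistic exceeds mean + k * SD of the statistic
#' across epochs are flagged in a single pass (default k = 3).
#'
#' @param epochs an `epoch_set`
#' @param k rejection multiplier (default 3)
#' @return the `epoch_set` with `rejected` flags set and a `rejection_report`
#'   attribute listing flagged trial indices
#' @export
reject_artifact_epochs <- function(epochs, k = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- nrow(epochs$epochs)
  if (n < 3) {
    warning("fewer than 3 epochs; nothing flagged")
    attr(epochs, "rejection_report") <- integer(0)
    return(epochs)
  }
  stat <- apply(epochs$epochs, 1, function(e) max(abs(e - mean(e))))
  thr <- mean(stat) + k * stats::sd(stat)
  flagged <- which(stat > thr)
  epochs$rejected <- epochs$rejected | (stat > thr)
  attr(epochs, "rejection_report") <- flagged
  epochs
}

#' Grand average with SEM band and baseline correction
#'
#' Each unrejected epoch is first baseline-corrected by subtracting its own
#' mean over `baseline_window` (ms, inclusive ends); the mean and pointwise
#' SEM across epochs are then computed. With `baseline_window = NULL` no
#' correction is applied (used e.g. before envelope normalization of power
#' traces).
#'
#' @param epochs an `epoch_set`
#' @param baseline_window length-2 ms window, or NULL to skip correction
#' @return a `trace_sem`: list with `time_ms`, `mean`, `sem`, `n`,
#'   `baseline_ms`
#' @export
grand_average <- function(epochs, baseline_window = c(-500, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- !epochs$rejected
  if (!any(keep)) stop("all epochs rejected; no grand average")
  m <- epochs$epochs[keep, , drop = FALSE]
  if (!is.null(baseline_window)) {
    bl <- epochs$time_ms >= baseline_window[1] & epochs$time_ms <= baseline_window[2]
    if (!any(bl)) stop("baseline window contains no samples")
    m <- m - rowMeans(m[, bl, drop = FALSE])
  }
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  structure(list(time_ms = epochs$time_ms, mean = mu, sem = sem, n = n,
                 baseline_ms = baseline_window),
            class = "trace_sem")
}

#' @export
print.trace_sem <- function(x, ...) {
  cat(sprintf("<trace_sem> %d samples [%g, %g] ms, n = %d epochs\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms), x$n))
  invisible(x)
}

#' Write / read an EEG recording as CSV
#'
#' Plain-text container: first column `time_ms`, then one column per
#' channel (microvolts).
#'
#' @param rec an `eeg_recording`
#' @param path CSV path
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(time_ms = sample_times_ms(rec), rec$data,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fs <- round(1000 / stats::median(diff(df$time_ms)))
  eeg_recording(as.matrix(df[, -1, drop = FALSE]),
                channels = colnames(df)[-1], fs = fs, start_ms = df$time_ms[1])
}
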