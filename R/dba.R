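#' Event-related deep-brain activity (ER-DBA) stage
#'
#' The DBA index is the mean power of the occipital alpha-2 (10-13 Hz)
#' amplitude streams from O1 and O2: each channel is band-passed, rectified,
#' smoothed and decimated to 32 samples/s ([amplitude_stream()]), squared to
#' power (uV^2), and the two channels averaged. Stimulus-locked,
#' baseline-corrected grand averages of this series form the ER-DBA traces;
#' event-related deactivation (ERD, power dip) marks proactive trials and
#' activation (ERS, power rise) reactive/avoid trials.
#'
#' @name dba
NULL

#' DBA index series from occipital channels
#'
#' @param rec an `eeg_recording` containing channels O1 and O2 at 256
#'   samples/s
#' @param band alpha-2 band edges Hz (default c(10, 13))
#' @param order Butterworth order (default 3)
#' @param ma_points smoothing/decimation factor (default 8; 256 -> 32 SPS)
#' @return an `eeg_recording` with single channel "DBA" holding the power
#'   series (uV^2) at 32 samples/s
#' @export
dba_index_series <- function(rec, band = c(10, 13), order = 3, ma_points = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (ch in c("O1", "O2")) {
    if (!(ch %in% rec$channels)) stop(sprintf("channel %s missing from recording", ch))
  }
  occ <- eeg_recording(rec$data[, c("O1", "O2")], c("O1", "O2"),
                       rec$fs, rec$start_ms)
  filt <- bandpass_filter(occ, band[1], band[2], order = order)
  amp <- amplitude_stream(filt, ma_points = ma_points)
  pw <- amp$data^2
  dba <- rowMeans(pw)
  eeg_recording(matrix(dba, ncol = 1), "DBA", amp$fs, amp$start_ms)
}

#' Category-wise ER-DBA traces
#'
#' Epochs the DBA series around the supplied markers, applies the 3-SD
#' artifact rule, and grand-averages per category with SEM bands and
#' baseline correction.
#'
#' @param dba_series output of [dba_index_series()]
#' @param markers_by_category named list of marker-time vectors (ms), one
#'   entry per behavioral category (e.g. hit / miss / CR / FA, hits
#'   optionally split by RT sign)
#' @param window epoch window ms (default c(-1000, 8000))
#' @param baseline baseline window ms (default c(-500, 0)); NULL to skip
#' @param k rejection multiplier (default 3)
#' @return named list of `trace_sem`; empty categories are omitted with a
#'   message
#' @export
erdba_traces <- function(dba_series, markers_by_category,
                         window = c(-1000, 8000), baseline = c(-500, 0),
                         k = 3) {
  out <- list()
  for (cat in names(markers_by_category)) {
    mk <- markers_by_category[[cat]]
    if (length(mk) == 0) { message("category ", cat, " empty; omitted"); next }
    ep <- epoch_stream(dba_series, mk, t_min = window[1], t_max = window[2])
    if (nrow(ep$epochs) == 0) { message("category ", cat, " has no usable epochs"); next }
    if (nrow(ep$epochs) >= 3) ep <- reject_artifact_epochs(ep, k = k)
    out[[cat]] <- grand_average(ep, baseline_window = baseline)
  }
  out
}

#' Envelope normalization of an ER-DBA trace
#'
#' Upper and lower envelopes are built by natural cubic interpolation
#' through the interior local maxima/minima (edges extended with the first
#' and last extremum values); the midline is their mean. Only extrema whose
#' prominence reaches `prom_frac` of the trace range are used, so the
#' envelopes track the slow event-locked excursion rather than residual
#' sample-level ripple. The normalization constant is the median over time
#' of the midline; the excursion amplitude Delta is the median of
#' (upper - lower). A flat trace normalizes to 1 with Delta = 0.
#'
#' @param trace a `trace_sem` (typically an uncorrected power trace)
#' @param prom_frac minimum extremum prominence as a fraction of the trace
#'   range (default 0.25)
#' @return list(normalized, midline, upper, lower, constant, delta)
#' @export
envelope_normalize <- function(trace, prom_frac = 0.25) {
  y <- trace$mean; t <- trace$time_ms
  rng <- diff(range(y))
  keep_prominent <- function(z, ix) {
    if (length(ix) == 0 || rng == 0) return(ix)
    prom <- vapply(ix, function(i) {
      h <- z[i]
      left <- if (i > 1) rev(z[1:(i - 1)]) else numeric(0)
      stop_l <- which(left > h)[1]
      col_l <- if (length(left) == 0) h else
        min(left[seq_len(if (is.na(stop_l)) length(left) else stop_l - 1)], h)
      right <- if (i < length(z)) z[(i + 1):length(z)] else numeric(0)
      stop_r <- which(right > h)[1]
      col_r <- if (length(right) == 0) h else
        min(right[seq_len(if (is.na(stop_r)) length(right) else stop_r - 1)], h)
      h - max(col_l, col_r)
    }, numeric(1))
    ix[prom >= prom_frac * rng]
  }
  imax <- keep_prominent(y, local_maxima(y))
  imin <- keep_prominent(-y, local_maxima(-y))
  interp_env <- function(ix) {
    if (length(ix) == 0) return(y)
    xs <- t[ix]; ys <- y[ix]
    # edge extension: hold the first/last extremum value at the trace ends
    xs <- c(t[1], xs, t[length(t)])
    ys <- c(ys[1], ys, ys[length(ys)])
    stats::spline(xs, ys, xout = t, method = "natural")$y
  }
  upper <- interp_env(imax)
  lower <- interp_env(imin)
  midline <- (upper + lower) / 2
  konst <- stats::median(midline)
  delta <- stats::median(upper - lower)
  normalized <- if (konst != 0) y / konst else rep(1, length(y))
  list(normalized = normalized, midline = midline, upper = upper,
       lower = lower, constant = konst, delta = delta)
}

#' Detect dips and peaks in an ER-DBA trace
#'
#' Local minima (dips) and maxima (peaks) inside the analysis window with
#' prominence at or above the threshold. The prominence of an extremum is
#' its height above (below) the higher of the in-window levels reachable on
#' either side. Default threshold: 5% of the trace's in-window range.
#'
#' Each dip also carries a heuristic `dissolution_ms`: the first time after
#' the dip at which the trace re-crosses the midline (by default the
#' in-window median), i.e. when the deactivation has dissolved.
#'
#' @param trace a `trace_sem`
#' @param window analysis window ms (default whole trace)
#' @param min_prominence prominence threshold in trace units, or NULL for
#'   0.05 x in-window range
#' @param midline reference level for dip dissolution (default in-window
#'   median of the trace)
#' @return list(dips, peaks): data.frames with time_ms, value, prominence
#'   (dips also dissolution_ms), ordered by time
#' @export
detect_extrema_features <- function(trace, window = NULL,
                                    min_prominence = NULL, midline = NULL) {
  t <- trace$time_ms; y <- trace$mean
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  ts <- t[sel]; ys <- y[sel]
  if (is.null(min_prominence)) min_prominence <- 0.05 * diff(range(ys))
  if (is.null(midline)) midline <- stats::median(ys)
  feat <- function(z, sign) {
    ix <- local_maxima(z)
    if (length(ix) == 0) return(data.frame(time_ms = numeric(0),
                                           value = numeric(0),
                                           prominence = numeric(0)))
    prom <- vapply(ix, function(i) {
      # walk outwards to the nearest higher point on each side; prominence
      # is the drop to the higher of the two intervening valley floors
      h <- z[i]
      left <- if (i > 1) rev(z[1:(i - 1)]) else numeric(0)
      stop_l <- which(left > h)[1]
      col_l <- if (length(left) == 0) h else
        min(left[seq_len(if (is.na(stop_l)) length(left) else stop_l - 1)], h)
      right <- if (i < length(z)) z[(i + 1):length(z)] else numeric(0)
      stop_r <- which(right > h)[1]
      col_r <- if (length(right) == 0) h else
        min(right[seq_len(if (is.na(stop_r)) length(right) else stop_r - 1)], h)
      h - max(col_l, col_r)
    }, numeric(1))
    keep <- prom >= min_prominence
    data.frame(time_ms = ts[ix[keep]], value = sign * z[ix[keep]],
               prominence = prom[keep])
  }
  peaks <- feat(ys, 1)
  dips <- feat(-ys, -1)
  dips$dissolution_ms <- vapply(dips$time_ms, function(td) {
    after <- which(ts > td & ys >= midline)
    if (length(after)) ts[after[1]] else NA_real_
  }, numeric(1))
  list(dips = dips[order(dips$time_ms), , drop = FALSE],
       peaks = peaks[order(peaks$time_ms), , drop = FALSE])
}

#' Classify ERD vs ERS by a power t-test
#'
#' Per epoch, the statistic is the mean power in `test_window` minus the
#' mean power in `baseline_window`. Without a reference, a one-sample
#' (paired against baseline) t-test is used: label "ERD" if test-window
#' power is significantly below baseline, "ERS" if above. With `ref`
#' (a second condition's epochs), the per-epoch statistics of the two
#' conditions are compared by a Welch t-test and the label is relative to
#' the reference condition — this is how trial groups (negative- vs
#' positive-RT taps, avoid vs tap) are contrasted, and it cancels any
#' modulation that neighboring pulses leak into both conditions alike.
#'
#' @param epochs an `epoch_set` of DBA power epochs
#' @param test_window,baseline_window ms windows
#' @param alpha significance level (default 0.05)
#' @param ref optional reference `epoch_set` for a two-condition contrast
#' @return list(label, t, p)
#' @export
classify_erd_ers <- function(epochs, test_window, baseline_window = c(-500, 0),
                             alpha = 0.05, ref = NULL) {
  win_stat <- function(ep) {
    keep <- !ep$rejected
    m <- ep$epochs[keep, , drop = FALSE]
    tw <- ep$time_ms >= test_window[1] & ep$time_ms <= test_window[2]
    bw <- ep$time_ms >= baseline_window[1] & ep$time_ms <= baseline_window[2]
    rowMeans(m[, tw, drop = FALSE]) - rowMeans(m[, bw, drop = FALSE])
  }
  stopifnot(inherits(epochs, "epoch_set"))
  d <- win_stat(epochs)
  if (length(d) < 2) stop("need at least 2 epochs")
  if (is.null(ref)) {
    if (stats::sd(d) == 0) {
      warning("degenerate variance; label none")
      return(list(label = "none", t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(d)
    effect <- mean(d)
  } else {
    stopifnot(inherits(ref, "epoch_set"))
    dr <- win_stat(ref)
    if (length(dr) < 2) stop("need at least 2 reference epochs")
    if (stats::sd(d) == 0 && stats::sd(dr) == 0) {
      warning("degenerate variance; label none")
      return(list(label = "none", t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(d, dr)
    effect <- mean(d) - mean(dr)
  }
  label <- if (tt$p.value < alpha) {
    if (effect < 0) "ERD" else "ERS"
  } else "none"
  list(label = label, t = unname(tt$statistic), p = tt$p.value)
}
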