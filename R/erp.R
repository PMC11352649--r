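#' ERP stage at Cz
#'
#' Cz is band-passed 0.01-45 Hz (third-order Butterworth, zero-phase),
#' epoched around stimulus-onset markers, cleaned by the 3-SD rule and
#' grand-averaged per behavioral category with a [-200, 0] ms baseline.
#' Late auditory components (P1, N1, P2, N2, LPC) are read off windowed
#' extrema; omission responses (oN1, oP2) on missing-pulse traces are
#' scored by the polarity-reversal correlation with the real-pulse trace.
#'
#' @name erp
NULL

#' Category-wise grand-averaged ERP traces
#'
#' @param rec an `eeg_recording` containing channel Cz
#' @param markers_by_category named list of marker times (ms) per category
#' @param band filter band Hz (default c(0.01, 45))
#' @param window epoch window ms (default c(-1000, 8000))
#' @param baseline baseline window ms (default c(-200, 0))
#' @param k rejection multiplier (default 3)
#' @return named list of `trace_sem`
#' @export
erp_traces <- function(rec, markers_by_category, band = c(0.01, 45),
                       window = c(-1000, 8000), baseline = c(-200, 0),
                       k = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!("Cz" %in% rec$channels)) stop("channel Cz missing from recording")
  cz <- eeg_recording(rec$data[, "Cz", drop = FALSE], "Cz", rec$fs,
                      rec$start_ms)
  filt <- bandpass_filter(cz, band[1], band[2], order = 3)
  out <- list()
  for (cat in names(markers_by_category)) {
    mk <- markers_by_category[[cat]]
    if (length(mk) == 0) { message("category ", cat, " empty; omitted"); next }
    ep <- epoch_stream(filt, mk, t_min = window[1], t_max = window[2])
    if (nrow(ep$epochs) == 0) { message("category ", cat, " has no usable epochs"); next }
    if (nrow(ep$epochs) >= 3) ep <- reject_artifact_epochs(ep, k = k)
    out[[cat]] <- grand_average(ep, baseline_window = baseline)
  }
  out
}

#' Default component search windows (ms)
#'
#' Approximate late-auditory latency ranges; positive components are sought
#' as maxima, negative as minima. All configurable.
#' @export
default_component_windows <- function() {
  list(P1 = c(40, 80), N1 = c(80, 150), P2 = c(150, 250),
       N2 = c(250, 480), LPC = c(480, 800))
}

#' Detect ERP components in a grand-averaged trace
#'
#' Per component, the signed extremum inside its search window (maximum for
#' P components, minimum for N components); a component is flagged present
#' when its amplitude exceeds `sem_mult` times the SEM at that latency.
#' CNV is the mean amplitude over the pre-onset window before the next
#' expected pulse, `[isi - 200, isi]` ms.
#'
#' @param trace a baseline-corrected `trace_sem`
#' @param windows named list of c(lo, hi) ms windows; names starting with
#'   "P"/"oP" are positive, "N"/"oN" negative
#'   (default [default_component_windows()])
#' @param sem_mult presence criterion multiplier (default 2)
#' @param isi nominal inter-stimulus interval ms for the CNV window
#'   (default 1000)
#' @return list(components = data.frame(component, latency_ms, amplitude_uv,
#'   present), cnv_mean)
#' @export
detect_components <- function(trace, windows = default_component_windows(),
                              sem_mult = 2, isi = 1000) {
  t <- trace$time_ms
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- which(t >= w[1] & t <= w[2])
    if (length(sel) == 0) {
      return(data.frame(component = nm, latency_ms = NA_real_,
                        amplitude_uv = NA_real_, present = FALSE))
    }
    positive <- grepl("^o?P", nm)
    i <- if (positive) sel[which.max(trace$mean[sel])]
         else sel[which.min(trace$mean[sel])]
    amp <- trace$mean[i]
    present <- abs(amp) > sem_mult * trace$sem[i] &&
      ((positive && amp > 0) || (!positive && amp < 0))
    data.frame(component = nm, latency_ms = t[i], amplitude_uv = amp,
               present = present)
  })
  cnv_sel <- t >= (isi - 200) & t <= isi
  list(components = do.call(rbind, rows),
       cnv_mean = if (any(cnv_sel)) mean(trace$mean[cnv_sel]) else NA_real_)
}

#' Omission-response reversal score
#'
#' Pearson correlation between the missing-pulse and real-pulse traces over
#' a common window: a score near -1 indicates a polarity-reversed omission
#' response, near +1 identity.
#'
#' @param trace_missing,trace_real `trace_sem` objects on a common time axis
#' @param window scoring window ms (default c(0, 600))
#' @return correlation in \[-1, 1\]
#' @export
omission_reversal_score <- function(trace_missing, trace_real,
                                    window = c(0, 600)) {
  stopifnot(isTRUE(all.equal(trace_missing$time_ms, trace_real$time_ms)))
  sel <- trace_missing$time_ms >= window[1] & trace_missing$time_ms <= window[2]
  a <- trace_missing$mean[sel]; b <- trace_real$mean[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance trace in scoring window; reversal score undefined")
  }
  stats::cor(a, b)
}
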