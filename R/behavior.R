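#' Behavioral analysis: reaction times, trial categories, dual-lobe RT
#' decomposition
#'
#' Taps are matched to pulse slots inside a +/-500 ms window, classified into
#' the five behavioral categories (CH correct hit, FH false hit, FA false
#' alarm, CR correct rejection, miss), and the pooled RT distribution is
#' decomposed by kernel density estimation into a proactive lobe (negative
#' mean asynchrony, peak near -50 ms) and a reactive lobe (positive mean
#' asynchrony, peak near +200 ms).
#'
#' @name behavior
NULL

#' Match tap times to pulse slots
#'
#' Each tap is assigned to the unique slot whose half-open window
#' `[onset + window[1], onset + window[2])` contains it; RT = tap - onset.
#' The first tap per slot is kept; extras and out-of-window taps are counted
#' in attributes `n_extra` and `n_unmatched`.
#'
#' @param seq a `pulse_sequence`
#' @param taps_ms sorted tap times, ms
#' @param window assignment window relative to slot onset, default c(-500, 500)
#' @return data.frame(slot_index, rt_ms), one row per responded slot
#' @export
match_taps_to_pulses <- function(seq, taps_ms, window = c(-500, 500)) {
  stopifnot(inherits(seq, "pulse_sequence"))
  taps_ms <- sort(taps_ms)
  # slot whose window starts at or before the tap
  slot <- findInterval(taps_ms, seq$onset_ms + window[1])
  in_win <- slot >= 1 & (taps_ms - ifelse(slot >= 1, seq$onset_ms[pmax(slot, 1)], NA)) < window[2]
  in_win[is.na(in_win)] <- FALSE
  slot_ok <- slot[in_win]
  rt <- taps_ms[in_win] - seq$onset_ms[slot_ok]
  first <- !duplicated(slot_ok)
  out <- data.frame(slot_index = seq$slot_index[slot_ok[first]],
                    rt_ms = rt[first])
  attr(out, "n_unmatched") <- sum(!in_win)
  attr(out, "n_extra") <- sum(!first)
  out
}

#' Classify trials into CH / FH / FA / CR / miss
#'
#' Real slot with a tap: FH (proactive) if RT < `mode_boundary`, else CH
#' (reactive). Real slot without a tap: miss. Missing slot with a tap: FA
#' (proactive, imagery-driven). Missing slot without: CR.
#'
#' @param seq an annotated `pulse_sequence`
#' @param matched output of [match_taps_to_pulses()]
#' @param mode_boundary FH/CH boundary in ms; use the per-participant KDE
#'   antimode when bimodal, falling back to +100 ms
#' @param participant optional participant id carried through
#' @return data.frame of trial records: participant, slot_index, kind,
#'   lag_post, lag_pre, category, rt_ms, mode
#' @export
classify_trials <- function(seq, matched, mode_boundary = 100,
                            participant = NA_character_) {
  stopifnot(inherits(seq, "pulse_sequence"))
  rt <- rep(NA_real_, nrow(seq))
  rt[match(matched$slot_index, seq$slot_index)] <- matched$rt_ms
  tapped <- !is.na(rt)
  real <- seq$kind == "real"
  category <- ifelse(real & tapped & rt < mode_boundary, "FH",
              ifelse(real & tapped, "CH",
              ifelse(real, "miss",
              ifelse(tapped, "FA", "CR"))))
  mode <- ifelse(category %in% c("FH", "FA"), "proactive",
          ifelse(category == "CH", "reactive", "none"))
  data.frame(participant = participant,
             slot_index = seq$slot_index,
             kind = seq$kind,
             lag_post = seq$lag_post,
             lag_pre = seq$lag_pre,
             category = category,
             rt_ms = rt,
             mode = mode,
             stringsAsFactors = FALSE)
}

#' Gaussian kernel density of reaction times
#'
#' Density on a 1-ms grid over `[from, to]`; bandwidth by Silverman's rule
#' (`stats::bw.nrd0`) unless given.
#'
#' @param rts reaction times, ms (>= 2 values)
#' @param bandwidth kernel bandwidth ms, or NULL for Silverman
#' @param from,to grid range ms (defaults -500, 500)
#' @return list(x, y, bw, n)
#' @export
kde_density <- function(rts, bandwidth = NULL, from = -500, to = 500) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) stop("need at least 2 reaction times for a density")
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(rts) else bandwidth
  d <- stats::density(rts, bw = bw, kernel = "gaussian",
                      from = from, to = to, n = (to - from) + 1)
  list(x = d$x, y = d$y, bw = bw, n = length(rts))
}

local_maxima <- function(y) {
  which(diff(sign(diff(y))) == -2) + 1L
}

#' Decompose a dual-lobe RT density into proactive and reactive lobes
#'
#' Local maxima of the density are ranked by height; if a second peak is
#' prominent (its valley toward the tallest peak dips at least
#' `min_rel_prominence` below the lower of the two peaks), the two tallest
#' become the lobe peaks and the density minimum between them the antimode.
#' `P_F` and `P_C` are the density heights at the proactive (earlier) and
#' reactive (later) peaks; `weight_pro` is the density mass left of the
#' antimode. A unimodal density yields a single peak and a null antimode
#' (downstream falls back to a +100 ms boundary).
#'
#' @param density output of [kde_density()]
#' @param min_rel_prominence relative valley depth required to call the
#'   density bimodal (default 0.05)
#' @return list(peak_rt_pro, peak_rt_rea, antimode, P_F, P_C, weight_pro,
#'   bandwidth, bimodal)
#' @export
decompose_dual_lobe <- function(density, min_rel_prominence = 0.05) {
  x <- density$x; y <- density$y
  pk <- local_maxima(y)
  if (length(pk) == 0) pk <- which.max(y)
  pk <- pk[order(y[pk], decreasing = TRUE)]
  bimodal <- FALSE
  if (length(pk) >= 2) {
    p1 <- pk[1]; p2 <- pk[2]
    lo <- min(p1, p2); hi <- max(p1, p2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    lower_peak <- min(y[p1], y[p2])
    bimodal <- (lower_peak - y[valley]) >= min_rel_prominence * lower_peak
  }
  if (bimodal) {
    pro_i <- min(p1, p2); rea_i <- max(p1, p2)
    dx <- x[2] - x[1]
    list(peak_rt_pro = x[pro_i], peak_rt_rea = x[rea_i],
         antimode = x[valley],
         P_F = y[pro_i], P_C = y[rea_i],
         weight_pro = sum(y[x < x[valley]]) * dx / (sum(y) * dx),
         bandwidth = density$bw, bimodal = TRUE)
  } else {
    p <- pk[1]
    list(peak_rt_pro = if (x[p] < 100) x[p] else NA_real_,
         peak_rt_rea = if (x[p] >= 100) x[p] else NA_real_,
         antimode = NULL,
         P_F = if (x[p] < 100) y[p] else 0,
         P_C = if (x[p] >= 100) y[p] else 0,
         weight_pro = if (x[p] < 100) 1 else 0,
         bandwidth = density$bw, bimodal = FALSE)
  }
}

#' Per-participant behavioral rates
#'
#' FAR = FA / missing slots, CRR = 1 - FAR; CHR is the reactive fraction
#' from the KDE population heights, CHR = P_C / (P_C + P_F), and
#' FHR = 1 - CHR. Falls back to the CH/(CH+FH) count ratio when the RT
#' density is unimodal or heights are degenerate.
#'
#' @param records trial records from [classify_trials()] for one participant
#' @param decomposition a [decompose_dual_lobe()] result for this
#'   participant's real-pulse RTs, or NULL to use count ratios
#' @return list(FAR, CRR, CHR, FHR, n_missing, n_real)
#' @export
participant_rates <- function(records, decomposition = NULL) {
  n_missing <- sum(records$kind == "missing")
  if (n_missing == 0) stop("no missing slots: FAR undefined")
  n_fa <- sum(records$category == "FA")
  far <- n_fa / n_missing
  heights_ok <- !is.null(decomposition) && isTRUE(decomposition$bimodal) &&
    (decomposition$P_F + decomposition$P_C) > 0
  if (heights_ok) {
    chr <- decomposition$P_C / (decomposition$P_C + decomposition$P_F)
  } else {
    n_ch <- sum(records$category == "CH"); n_fh <- sum(records$category == "FH")
    chr <- if (n_ch + n_fh > 0) n_ch / (n_ch + n_fh) else NA_real_
  }
  list(FAR = far, CRR = 1 - far, CHR = chr, FHR = 1 - chr,
       n_missing = n_missing, n_real = sum(records$kind == "real"))
}

#' Lag-locked behavioral profile
#'
#' Summaries per lag number N locked to the missing-pulse site (N = 0):
#' mean RT with SEM, CH ratio CH/(CH+FH), and per-mode mean RTs. A slot
#' lying between two omissions contributes at both of its lag labels.
#'
#' @param records trial records (possibly pooled across participants)
#' @param lags lag numbers to report (default -2..8)
#' @return data.frame(lag, n, mean_rt, sem_rt, ch_ratio, ch_rt, fh_rt)
#' @export
lag_locked_profile <- function(records, lags = -2:8) {
  rows <- lapply(lags, function(L) {
    if (L < 0) {
      sel <- records[!is.na(records$lag_pre) & records$lag_pre == L, ]
    } else if (L == 0) {
      sel <- records[records$kind == "missing", ]
    } else {
      sel <- records[!is.na(records$lag_post) & records$lag_post == L, ]
    }
    rt <- sel$rt_ms[!is.na(sel$rt_ms)]
    n_ch <- sum(sel$category == "CH"); n_fh <- sum(sel$category == "FH")
    data.frame(
      lag = L, n = nrow(sel),
      mean_rt = if (length(rt)) mean(rt) else NA_real_,
      sem_rt = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt)) else NA_real_,
      ch_ratio = if (n_ch + n_fh > 0) n_ch / (n_ch + n_fh) else NA_real_,
      ch_rt = if (n_ch) mean(sel$rt_ms[sel$category == "CH"]) else NA_real_,
      fh_rt = if (n_fh) mean(sel$rt_ms[sel$category == "FH"]) else NA_real_
    )
  })
  do.call(rbind, rows)
}
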