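#' Pulse sequence construction and annotation
#'
#' A pulse sequence is the ordered set of stimulus slots of a cued-tapping
#' task: real (audible) pulses and missing (silently omitted) pulses on a
#' nominally isochronous grid. Real slots around each omission are labeled by
#' the lag number N (-2, -1 before; 1, 2, ... after; N = 0 at the omission),
#' and the stretches of real pulses between neighboring omissions carry the
#' segment count M.
#'
#' @name sequences
NULL

new_pulse_sequence <- function(onset_ms, kind, isi) {
  stopifnot(length(onset_ms) == length(kind), all(kind %in% c("real", "missing")))
  if (any(diff(onset_ms) <= 0)) stop("slot onsets must be strictly increasing")
  x <- data.frame(
    slot_index = seq_along(onset_ms) - 1L,
    onset_ms = as.numeric(onset_ms),
    kind = kind,
    lag_post = NA_integer_,
    lag_pre = NA_integer_,
    segment_M = NA_integer_,
    stringsAsFactors = FALSE
  )
  attr(x, "isi") <- isi
  class(x) <- c("pulse_sequence", "data.frame")
  x
}

#' Generate a regular (isochronous) pulse sequence
#'
#' All slots are real pulses on an equal-interval grid, as in the control
#' task (120 pulses, 1000-ms inter-stimulus interval).
#'
#' @param n_pulses number of pulses (>= 1)
#' @param isi inter-stimulus interval in ms (> 0)
#' @return a `pulse_sequence` data frame
#' @export
generate_regular_sequence <- function(n_pulses, isi = 1000) {
  if (n_pulses < 1 || isi <= 0) stop("n_pulses must be >= 1 and isi > 0")
  new_pulse_sequence(onset_ms = (seq_len(n_pulses) - 1) * isi,
                     kind = rep("real", n_pulses), isi = isi)
}

#' Generate a random-interval pulse sequence
#'
#' Successive inter-stimulus gaps are drawn uniformly on `[isi_min, isi_max]`,
#' e.g. the 1000-1500 ms validation sequence. Reproducible given `seed`.
#'
#' @param n_pulses number of pulses
#' @param isi_min,isi_max bounds of the uniform ISI distribution (ms)
#' @param seed RNG seed
#' @return a `pulse_sequence`
#' @export
generate_random_sequence <- function(n_pulses, isi_min = 1000, isi_max = 1500,
                                     seed = NULL) {
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (isi_min > isi_max) stop("isi_min must not exceed isi_max")
  if (!is.null(seed)) set.seed(seed)
  gaps <- stats::runif(max(n_pulses - 1, 0), isi_min, isi_max)
  new_pulse_sequence(onset_ms = cumsum(c(0, gaps)),
                     kind = rep("real", n_pulses),
                     isi = mean(c(isi_min, isi_max)))
}

#' Generate a missing-pulse (missing-oddball) sequence
#'
#' Starts from a regular grid and randomly omits `n_missing` pulses, subject
#' to a minimum slot separation between omissions. The first and last slots
#' are always real so that every omission has flanking real pulses for lag
#' annotation. Omission sets are drawn uniformly over all feasible sets.
#'
#' @param n_total total slot count (e.g. 300)
#' @param n_missing number of missing slots (e.g. 45)
#' @param min_separation minimum slot distance between omissions; 2 (the
#'   default) forbids adjacent omissions, 1 allows them
#' @param isi inter-stimulus interval ms
#' @param seed RNG seed
#' @return an annotated `pulse_sequence`
#' @export
generate_missing_sequence <- function(n_total, n_missing, min_separation = 2,
                                      isi = 1000, seed = NULL) {
  if (n_missing < 0 || n_missing > n_total) stop("need 0 <= n_missing <= n_total")
  if (min_separation < 1) stop("min_separation must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kind <- rep("real", n_total)
  if (n_missing > 0) {
    if (n_total < 3) stop("too few slots to embed a missing pulse with real flanks")
    interior <- n_total - 2L            # candidate slots, 1-based interior indices
    s <- min_separation
    reduced <- interior - (n_missing - 1L) * (s - 1L)
    if (reduced < n_missing) {
      stop(sprintf("infeasible: cannot place %d omissions with separation %d in %d slots",
                   n_missing, s, n_total))
    }
    y <- sort(sample.int(reduced, n_missing))
    pos <- y + (seq_len(n_missing) - 1L) * (s - 1L)   # interior positions, min diff = s
    kind[pos + 1L] <- "missing"                        # shift past the forced-real first slot
  }
  seq <- new_pulse_sequence(onset_ms = (seq_len(n_total) - 1) * isi,
                            kind = kind, isi = isi)
  annotate_lags(seq)
}

#' Annotate lag numbers and segment counts
#'
#' For every real slot, `lag_post` is its distance (in slots) after the
#' nearest preceding missing slot and `lag_pre` the negative distance before
#' the nearest following missing slot; a slot between two omissions carries
#' both. Missing slots get lag 0. `segment_M` holds, on each real slot lying
#' strictly between two omissions, the number M of real pulses in that
#' inter-omission segment. Idempotent; an all-real sequence keeps null lags.
#'
#' @param seq a `pulse_sequence`
#' @return the sequence with `lag_post`, `lag_pre`, `segment_M` filled in
#' @export
annotate_lags <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  miss <- which(seq$kind == "missing")
  seq$lag_post <- NA_integer_
  seq$lag_pre <- NA_integer_
  seq$segment_M <- NA_integer_
  if (length(miss) == 0) return(seq)
  n <- nrow(seq)
  idx <- seq_len(n)
  prev_miss <- findInterval(idx, miss)              # index into miss of last omission <= slot
  prev_pos <- rep(NA_integer_, n)
  prev_pos[prev_miss > 0] <- miss[prev_miss[prev_miss > 0]]
  nxt_pos <- vapply(idx, function(i) {
    j <- miss[miss > i]
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  is_real <- seq$kind == "real"
  seq$lag_post[is_real] <- as.integer(idx[is_real] - prev_pos[is_real])
  seq$lag_pre[is_real] <- as.integer(idx[is_real] - nxt_pos[is_real])
  seq$lag_post[!is_real] <- 0L
  seq$lag_pre[!is_real] <- 0L
  if (length(miss) >= 2) {
    for (g in seq_len(length(miss) - 1L)) {
      inside <- idx > miss[g] & idx < miss[g + 1L]
      seq$segment_M[inside] <- as.integer(sum(inside))
    }
  }
  seq
}

#' Segment counts M between neighboring omissions
#'
#' @param seq an annotated `pulse_sequence`
#' @return integer vector, one M (count of real pulses) per gap between
#'   consecutive missing slots; empty when fewer than two omissions
#' @export
segment_counts <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  miss <- which(seq$kind == "missing")
  if (length(miss) < 2) return(integer(0))
  vapply(seq_len(length(miss) - 1L), function(g) {
    sum(seq$kind[(miss[g] + 1L):(miss[g + 1L] - 1L)] == "real")
  }, integer(1))
}

#' Write / read a stimulus event table
#'
#' Columns: slot_index, onset_ms, kind, lag_post, lag_pre, segment_M
#' (empty when null).
#'
#' @param seq a `pulse_sequence`
#' @param path CSV path
#' @return `read_events_csv` returns a `pulse_sequence`
#' @export
write_events_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- new_pulse_sequence(df$onset_ms, df$kind,
                            isi = stats::median(diff(df$onset_ms)))
  for (col in c("lag_post", "lag_pre", "segment_M")) {
    out[[col]] <- as.integer(df[[col]])
  }
  out
}
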