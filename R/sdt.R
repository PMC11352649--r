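#' Modified signal-detection-theory indices for the missing-oddball task
#'
#' Sensitivity and bias are computed from the correct-hit ratio CHR (the
#' reactive fraction of real-pulse taps, defined from the KDE population
#' heights) and the correct-rejection ratio CRR (1 - FAR over missing
#' slots):
#'
#'   d' = Z(CHR) - Z(CRR)
#'   c  = -1/2 (Z(CHR) + Z(CRR))
#'
#' with Z the standard-normal quantile function. This differs from classical
#' SDT (which would use the false-alarm rate in place of CRR inside d');
#' the classical variant is available via `classical = TRUE`.
#'
#' @name sdt
NULL

#' Standard-normal quantile (inverse CDF)
#'
#' @param p probability strictly inside (0, 1); clip rates first with
#'   [clip_rate()]
#' @return z with |pnorm(z) - p| < 1e-10
#' @export
inverse_normal_cdf <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1); clip first")
  stats::qnorm(p)
}

#' Clip an extreme rate away from 0 and 1
#'
#' The standard 1/(2n) correction: 0 becomes 1/(2n), 1 becomes 1 - 1/(2n),
#' interior rates are unchanged. Never moves a rate across 0.5.
#'
#' @param rate observed rate in \[0, 1\]
#' @param n trial count behind the rate (>= 1)
#' @export
clip_rate <- function(rate, n) {
  stopifnot(all(n >= 1))
  pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' d-prime and criterion from CHR and CRR
#'
#' Rates are clipped with [clip_rate()] using their trial counts, then the
#' index formulas are applied. Vectorized.
#'
#' @param chr correct-hit ratio(s)
#' @param crr correct-rejection ratio(s)
#' @param n_real,n_missing trial counts used for clipping (defaults 255, 45)
#' @param classical if TRUE, use the textbook hit-rate/false-alarm-rate form
#'   d' = Z(CHR) - Z(FAR), c = -1/2 (Z(CHR) + Z(FAR))
#' @return data.frame(d_prime, criterion_c, chr_used, crr_used)
#' @export
sdt_indices <- function(chr, crr, n_real = 255, n_missing = 45,
                        classical = FALSE) {
  chr_c <- clip_rate(chr, n_real)
  crr_c <- clip_rate(crr, n_missing)
  z2 <- if (classical) stats::qnorm(1 - crr_c) else stats::qnorm(crr_c)
  z1 <- stats::qnorm(chr_c)
  data.frame(d_prime = z1 - z2,
             criterion_c = -0.5 * (z1 + z2),
             chr_used = chr_c, crr_used = crr_c)
}

#' Exact inverse of the index formulas
#'
#' Returns the (CHR, CRR) pair that [sdt_indices()] maps to the given
#' (d', c); used for simulation-based validation. chr = Phi(d'/2 - c),
#' crr = Phi(-d'/2 - c).
#'
#' @param d_prime,criterion_c index values
#' @return data.frame(chr, crr)
#' @export
rates_from_indices <- function(d_prime, criterion_c) {
  data.frame(chr = stats::pnorm(d_prime / 2 - criterion_c),
             crr = stats::pnorm(-d_prime / 2 - criterion_c))
}

#' Lag profile of d-prime and criterion, with FAR correlations
#'
#' Per participant, the global CRR comes from the missing slots; the
#' lag-specific CHR is the CH/(CH+FH) count ratio at that lag. Per-lag
#' indices are averaged across participants. Across-participant
#' correlations (criterion vs FAR, d-prime vs FAR, FHR vs FAR at lag -1)
#' are computed with [pearson_regression()].
#'
#' @param records trial records for all participants (from
#'   [classify_trials()], one `participant` value per subject)
#' @param lags lag numbers to profile (default -2..8, omitting 0 where no
#'   CH/FH exist)
#' @return list(per_lag, per_participant, correlations)
#' @export
sdt_lag_profile <- function(records, lags = c(-2, -1, 1:8)) {
  parts <- split(records, records$participant)
  per_part <- lapply(names(parts), function(pid) {
    rec <- parts[[pid]]
    n_missing <- sum(rec$kind == "missing")
    if (n_missing == 0) return(NULL)
    far <- sum(rec$category == "FA") / n_missing
    crr <- 1 - far
    rows <- lapply(lags, function(L) {
      sel <- if (L < 0) rec[!is.na(rec$lag_pre) & rec$lag_pre == L, ]
             else rec[!is.na(rec$lag_post) & rec$lag_post == L, ]
      n_ch <- sum(sel$category == "CH"); n_fh <- sum(sel$category == "FH")
      if (n_ch + n_fh == 0) return(NULL)
      chr <- n_ch / (n_ch + n_fh)
      idx <- sdt_indices(chr, crr, n_real = n_ch + n_fh, n_missing = n_missing)
      cbind(data.frame(participant = pid, lag = L, chr = chr, crr = crr,
                       far = far), idx[, c("d_prime", "criterion_c")])
    })
    do.call(rbind, rows)
  })
  per_part <- do.call(rbind, per_part)
  per_lag <- do.call(rbind, lapply(split(per_part, per_part$lag), function(g) {
    data.frame(lag = g$lag[1], n = nrow(g),
               d_prime = mean(g$d_prime), criterion_c = mean(g$criterion_c),
               sem_d = stats::sd(g$d_prime) / sqrt(nrow(g)),
               sem_c = stats::sd(g$criterion_c) / sqrt(nrow(g)))
  }))
  per_lag <- per_lag[order(per_lag$lag), ]
  # participant-level scatter relations (paper's Fig 10c-e analogues)
  by_part <- do.call(rbind, lapply(split(per_part, per_part$participant),
    function(g) {
      pre <- g[g$lag == -1, ]
      data.frame(participant = g$participant[1], far = g$far[1],
                 d_prime = mean(g$d_prime), criterion_c = mean(g$criterion_c),
                 fhr_pre = if (nrow(pre)) 1 - pre$chr else NA_real_)
    }))
  corr <- list(
    c_vs_far = try_regression(by_part$far, by_part$criterion_c),
    d_vs_far = try_regression(by_part$far, by_part$d_prime),
    fhr_vs_far = try_regression(by_part$far, by_part$fhr_pre)
  )
  list(per_lag = per_lag, per_participant = by_part, correlations = corr)
}

try_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
  pearson_regression(x[ok], y[ok])
}
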