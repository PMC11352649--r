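#' Statistical toolkit
#'
#' The small set of tests and planning formulas the pipeline reports:
#' one-way ANOVA with eta-squared, Holm-Sidak step-down multiple
#' comparisons, Pearson correlation with ANOVA-style F/p/eta-squared,
#' Welch t-test with post-hoc power, and the sample-size planning chain.
#'
#' @name stats-toolkit
NULL

#' One-way ANOVA with effect size
#'
#' F = (SSB/dfB) / (SSW/dfW); eta-squared = SSB / (SSB + SSW); p from the
#' F distribution. Zero within-group variance with nonzero between-group
#' variance yields an infinite F (p = 0).
#'
#' @param groups list of numeric vectors (>= 2 groups)
#' @return list(F, p, eta_squared, df_between, df_within, ssb, ssw)
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n <- vapply(groups, length, integer(1))
  if (any(n < 1)) stop("empty group")
  all_x <- unlist(groups)
  gm <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all_x) - length(groups)
  if (dfw < 1) stop("need at least one residual degree of freedom")
  eta2 <- if (ssb + ssw > 0) ssb / (ssb + ssw) else 0
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / dfb) / (ssw / dfw)
  p <- if (is.infinite(f)) 0 else stats::pf(f, dfb, dfw, lower.tail = FALSE)
  list(F = f, p = p, eta_squared = eta2, df_between = dfb, df_within = dfw,
       ssb = ssb, ssw = ssw)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' p-values are sorted ascending; the i-th (of m) is tested against
#' 1 - (1 - alpha)^(1/(m - i + 1)); rejection proceeds while p <= threshold
#' and stops at the first failure. Flags are returned in the original order.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @param alpha family-wise error rate (default 0.05)
#' @return list(reject, thresholds, order)
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  ord <- order(p_values)
  thr <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= thr[i]) rej_sorted[i] <- TRUE else break
  }
  reject <- logical(m)
  reject[ord] <- rej_sorted
  list(reject = reject, thresholds = thr, order = ord)
}

#' Pearson correlation with ANOVA indices
#'
#' r is the sample correlation; for the implied simple regression,
#' F = r^2 (n - 2) / (1 - r^2), eta-squared = r^2, p from F(1, n - 2).
#' A perfect correlation reports an infinite F with p = 0.
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance
#' @return list(r, F, p, eta_squared, n)
#' @export
pearson_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (1 - r^2 < 1e-12) {
    return(list(r = r, F = Inf, p = 0, eta_squared = 1, n = n))
  }
  f <- r^2 * (n - 2) / (1 - r^2)
  list(r = r, F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       eta_squared = r^2, n = n)
}

#' Welch two-sample t-test with post-hoc power
#'
#' The t statistic, degrees of freedom and p-value follow Welch's
#' unequal-variance form. Post-hoc power is evaluated at the observed
#' effect: the probability, under a noncentral t with the observed
#' noncentrality, that |t| exceeds the two-sided critical value at `alpha`.
#'
#' @param a,b numeric samples (each >= 2)
#' @param alpha significance level (default 0.05)
#' @return list(t, df, p, power, effect_size)
#' @export
two_sample_ttest_with_power <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) stop("zero variance in both samples")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # observed noncentrality = observed t; power at the same design
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- abs(t)
  power <- stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(t = t, df = df, p = p, power = power,
       effect_size = (mean(a) - mean(b)) / sp)
}

#' Minimum epoch sample size from excursion amplitude and pooled SD
#'
#' N = ceil((z * sd / (delta * fraction))^2): the number of epochs needed
#' to resolve a difference of `fraction * delta` at the given z. With the
#' planning values delta = 1.95 uV^2, sd = 5.53 uV^2, z = 1.96 and
#' fraction = 1/3 this gives N = 279.
#'
#' @param delta excursion amplitude, uV^2
#' @param sd pooled standard deviation, uV^2
#' @param z normal quantile for the significance level (default 1.96)
#' @param fraction resolvable fraction of delta (default 1/3)
#' @return integer epoch count
#' @export
required_sample_size <- function(delta, sd, z = 1.96, fraction = 1 / 3) {
  if (delta <= 0 || sd <= 0) stop("delta and sd must be positive")
  as.integer(ceiling((z * sd / (delta * fraction))^2))
}

#' Minimum participant count from an epoch requirement
#'
#' base = ceil(n_epochs_needed / expected_per_participant), inflated for an
#' anticipated exclusion rate: count = ceil(base / (1 - inflation_loss)).
#' With 279 epochs, 13.5 expected usable epochs per participant (45 missing
#' pulses x 0.3 error rate) and a 0.3 exclusion rate this yields 21 and 30.
#'
#' @param n_epochs_needed total epochs required
#' @param expected_per_participant usable epochs each participant contributes
#' @param inflation_loss anticipated exclusion rate in \[0, 1)
#' @return integer participant count
#' @export
required_participants <- function(n_epochs_needed, expected_per_participant,
                                  inflation_loss = 0) {
  stopifnot(n_epochs_needed > 0, expected_per_participant > 0,
            inflation_loss >= 0, inflation_loss < 1)
  base <- ceiling(n_epochs_needed / expected_per_participant)
  # guard against float fuzz promoting an exact ratio to the next integer
  as.integer(ceiling(base / (1 - inflation_loss) - 1e-9))
}
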