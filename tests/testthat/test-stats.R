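test_that("one-way ANOVA matches hand arithmetic and stats::aov", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$eta_squared, 0)

  # hand oracle: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8, eta2 = 0.8
  r <- one_way_anova(list(c(0, 1), c(2, 3)))
  expect_equal(r$F, 8)
  expect_equal(r$eta_squared, 0.8)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 2)

  # cross-check against the installed implementation on random data
  set.seed(10)
  g <- list(rnorm(8), rnorm(10, 0.5), rnorm(7, 1))
  mine <- one_way_anova(g)
  df <- data.frame(y = unlist(g),
                   f = factor(rep(seq_along(g), lengths(g))))
  ref <- summary(stats::aov(y ~ f, df))[[1]]
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  # degenerate within-group variance
  inf <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(inf$F))
  expect_equal(inf$p, 0)

  for (s in 1:20) {
    set.seed(s)
    e <- one_way_anova(list(rnorm(5), rnorm(5)))$eta_squared
    expect_true(e >= 0 && e <= 1)
  }
})

test_that("Holm-Sidak step-down matches the hand-computed instance", {
  expect_true(holm_sidak(0.04, 0.05)$reject)
  expect_false(any(holm_sidak(rep(1, 5))$reject))

  hs <- holm_sidak(c(0.01, 0.03, 0.04), alpha = 0.05)
  # thresholds 1-(0.95)^(1/3) = 0.016952, 1-(0.95)^(1/2) = 0.025321, 0.05
  expect_equal(hs$thresholds[1], 1 - 0.95^(1 / 3), tolerance = 1e-12)
  expect_equal(hs$thresholds[2], 1 - 0.95^(1 / 2), tolerance = 1e-12)
  expect_equal(hs$reject, c(TRUE, FALSE, FALSE))
})

test_that("Holm-Sidak sits between Bonferroni and unadjusted rejection", {
  for (s in 1:25) {
    set.seed(s)
    p <- runif(8)^2
    hs <- holm_sidak(p)$reject
    bonf <- stats::p.adjust(p, "bonferroni") <= 0.05
    raw <- p <= 0.05
    expect_true(all(!(bonf & !hs)))   # rejects a superset of Bonferroni
    expect_true(all(!(hs & !raw)))    # and a subset of unadjusted
  }
})

test_that("Pearson regression returns r, F, p and effect size consistently", {
  x <- 1:10
  perf <- pearson_regression(x, 2 * x + 1)
  expect_equal(perf$r, 1)
  expect_true(is.infinite(perf$F))

  orth <- pearson_regression(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  expect_equal(orth$r, 0)
  expect_equal(orth$F, 0)

  set.seed(12)
  xx <- rnorm(33); yy <- 0.5 * xx + rnorm(33)
  mine <- pearson_regression(xx, yy)
  ref <- stats::cor.test(xx, yy)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_equal(mine$eta_squared, mine$r^2)

  expect_error(pearson_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("FAR versus false-alarm RT recovers a negative relation", {
  sq <- generate_missing_sequence(300, 45, seed = 77)
  signs <- vapply(1:12, function(s) {
    set.seed(1000 + s)
    far <- runif(33, 0.1, 0.6)
    rows <- vapply(seq_len(33), function(i) {
      # higher-FAR participants tap earlier: mu_fa tied to far
      prof <- participant_profile(far = far[i],
                                  mu_fa = 60 - 300 * far[i])
      truth <- simulate_behavior(sq, prof)$truth
      c(mean(truth$rt_ms[truth$category == "FA"]),
        sum(truth$category == "FA") / sum(truth$kind == "missing"))
    }, numeric(2))
    sign(pearson_regression(rows[1, ], rows[2, ])$r)
  }, numeric(1))
  expect_true(mean(signs == -1) >= 0.95)
})

test_that("Welch t-test and post-hoc power match simulation", {
  a <- c(1, 2, 3, 4)
  same <- two_sample_ttest_with_power(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(14)
  x <- rnorm(25); y <- rnorm(25, 0.4)
  ref <- stats::t.test(x, y)
  mine <- two_sample_ttest_with_power(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  # Monte-Carlo oracle at observed effect size 0.8, n = 25/25
  n <- 25
  a8 <- scale(rnorm(n))[, 1]                   # mean 0, sd 1 exactly
  b8 <- scale(rnorm(n))[, 1] + 0.8             # observed effect = 0.8
  pw <- two_sample_ttest_with_power(b8, a8)$power
  set.seed(15)
  R <- 40000
  xa <- matrix(rnorm(n * R), n); xb <- matrix(rnorm(n * R, 0.8), n)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums((xa - rep(ma, each = n))^2) / (n - 1)
  vb <- colSums((xb - rep(mb, each = n))^2) / (n - 1)
  se2 <- va / n + vb / n
  tv <- (mb - ma) / sqrt(se2)
  dfv <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
  rej <- abs(tv) > qt(0.975, dfv)
  expect_lt(abs(pw - mean(rej)), 0.02)

  # power monotone in |effect|
  pws <- vapply(c(0.2, 0.5, 0.8, 1.2), function(es) {
    two_sample_ttest_with_power(scale(rnorm(n))[, 1] + es,
                                scale(rnorm(n))[, 1])$power
  }, numeric(1))
  expect_true(all(diff(pws) > 0))
})

test_that("planning formulas reproduce the 279 / 21 / 30 chain", {
  expect_equal(required_sample_size(1.95, 5.53), 279L)
  # unit ratio: z * sd equals delta * fraction -> N = 1
  expect_equal(required_sample_size(3, 3 / 1.96 * (1 / 3) * 3 / 3, z = 1.96,
                                    fraction = 1 / 3), 1L)
  n1 <- required_sample_size(1.95, 2)
  n2 <- required_sample_size(1.95, 4)
  expect_lte(abs(n2 - 4 * n1), 4)

  expect_equal(required_participants(279, 13.5, 0), 21L)
  expect_equal(required_participants(100, 100, 0), 1L)
  expect_equal(required_participants(279, 13.5, 0.3), 30L)
})
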