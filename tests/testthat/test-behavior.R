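test_that("taps are matched to slots on the half-open +/-500 ms window", {
  sq <- annotate_lags(generate_regular_sequence(5, 1000))
  m <- match_taps_to_pulses(sq, c(1100))
  expect_equal(m$slot_index, 1L)
  expect_equal(m$rt_ms, 100)

  # closed left edge, open right edge
  edges <- match_taps_to_pulses(sq, c(500, 2500))
  expect_equal(edges$slot_index, c(1L, 3L))
  expect_equal(edges$rt_ms, c(-500, -500))

  # first tap per slot kept, extras logged
  extra <- match_taps_to_pulses(sq, c(950, 1100))
  expect_equal(nrow(extra), 1)
  expect_equal(extra$rt_ms, -50)
  expect_equal(attr(extra, "n_extra"), 1)
})

test_that("matched pairs equal generator ground truth", {
  sq <- generate_missing_sequence(120, 18, seed = 4)
  prof <- participant_profile()
  for (s in 1:5) {
    beh <- simulate_behavior(sq, prof, seed = s)
    m <- match_taps_to_pulses(sq, beh$taps_ms)
    truth <- beh$truth[!is.na(beh$truth$rt_ms), ]
    expect_equal(m$slot_index, truth$slot_index)
    expect_equal(m$rt_ms, truth$rt_ms)
    expect_equal(attr(m, "n_unmatched"), 0)
  }
})

test_that("trial classification follows the category scheme", {
  sq <- annotate_lags(generate_regular_sequence(4, 1000))
  sq$kind <- c("real", "real", "missing", "real")
  sq <- annotate_lags(sq)
  matched <- data.frame(slot_index = c(0L, 2L, 3L), rt_ms = c(200, -30, 50))
  rec <- classify_trials(sq, matched, mode_boundary = 100)
  expect_equal(rec$category, c("CH", "miss", "FA", "FH"))
  expect_equal(rec$mode, c("reactive", "none", "proactive", "proactive"))
  expect_equal(rec$rt_ms, c(200, NA, -30, 50))
})

test_that("KDE density normalizes, locates peaks, and is deterministic", {
  set.seed(2)
  rts <- rnorm(5000, 0, 50)
  d <- kde_density(rts)
  expect_lt(abs(sum(d$y) * (d$x[2] - d$x[1]) - 1), 1e-3)
  d2 <- kde_density(rts)
  expect_identical(d$y, d2$y)
  expect_error(kde_density(5), "at least 2")

  # Monte-Carlo consistency: mode estimates center on the true mode
  peaks <- vapply(1:5, function(s) {
    set.seed(s)
    dd <- kde_density(rnorm(5000, 0, 50))
    dd$x[which.max(dd$y)]
  }, numeric(1))
  expect_lt(abs(mean(peaks)), 10)
})

test_that("dual-lobe decomposition recovers mixture structure", {
  set.seed(3)
  rts <- c(rnorm(1000, -50, 40), rnorm(1000, 200, 40))
  dec <- decompose_dual_lobe(kde_density(rts))
  expect_true(dec$bimodal)
  expect_lt(abs(dec$peak_rt_pro + 50), 15)
  expect_lt(abs(dec$peak_rt_rea - 200), 15)
  expect_true(dec$peak_rt_pro < dec$antimode && dec$antimode < dec$peak_rt_rea)
  expect_lt(abs(dec$weight_pro - 0.5), 0.05)

  uni <- decompose_dual_lobe(kde_density(rnorm(2000, 200, 40)))
  expect_false(uni$bimodal)
  expect_null(uni$antimode)

  # density-height ratio tracks mixture weights (equal sigma)
  set.seed(4)
  rts2 <- c(rnorm(1400, -50, 40), rnorm(600, 200, 40))
  dec2 <- decompose_dual_lobe(kde_density(rts2))
  expect_lt(abs(dec2$P_F / dec2$P_C - 7 / 3) / (7 / 3), 0.2)
})

test_that("participant rates follow the definitions", {
  sq <- generate_missing_sequence(300, 45, seed = 6)
  # 9 false alarms among 45 missing slots
  miss_slots <- sq$slot_index[sq$kind == "missing"]
  matched <- data.frame(slot_index = miss_slots[1:9], rt_ms = rep(-20, 9))
  rec <- classify_trials(sq, matched)
  r <- participant_rates(rec)
  expect_equal(r$FAR, 0.2)
  expect_equal(r$CRR, 0.8)

  fake_dec <- list(bimodal = TRUE, P_F = 2, P_C = 2)
  expect_equal(participant_rates(rec, fake_dec)$CHR, 0.5)

  no_missing <- classify_trials(annotate_lags(generate_regular_sequence(5, 1000)),
                                data.frame(slot_index = integer(0),
                                           rt_ms = numeric(0)))
  expect_error(participant_rates(no_missing), "FAR undefined")
})

test_that("empirical FAR converges to the profile probability", {
  sq <- generate_missing_sequence(300, 45, seed = 7)
  prof <- participant_profile(far = 0.3)
  n_fa <- 0; n_miss <- 0
  for (s in 1:40) {
    truth <- simulate_behavior(sq, prof, seed = 100 + s)$truth
    n_fa <- n_fa + sum(truth$category == "FA")
    n_miss <- n_miss + sum(truth$kind == "missing")
  }
  ci <- qbinom(c(0.005, 0.995), n_miss, 0.3)
  expect_gte(n_fa, ci[1])
  expect_lte(n_fa, ci[2])
})

test_that("lag-locked profile recovers configured per-lag means", {
  sq <- generate_missing_sequence(300, 45, seed = 8)
  # reactive everywhere except configured: lag 1 fully reactive at 159.8 ms,
  # missing-slot taps at 20.3 ms (per-lag means mirror the reported table)
  prof <- participant_profile(mu_rea = 159.8, mu_fa = 20.3, far = 1,
                              miss_rate = 0, w_proactive = 0,
                              lag_weight_curve = c("1" = 0))
  recs <- lapply(1:8, function(s) {
    beh <- simulate_behavior(sq, prof, seed = s)
    classify_trials(sq, match_taps_to_pulses(sq, beh$taps_ms),
                    mode_boundary = 100, participant = paste0("P", s))
  })
  prof_tab <- lag_locked_profile(do.call(rbind, recs))
  l0 <- prof_tab[prof_tab$lag == 0, ]
  l1 <- prof_tab[prof_tab$lag == 1, ]
  expect_lt(abs(l0$mean_rt - 20.3), 2 * l0$sem_rt)
  expect_lt(abs(l1$mean_rt - 159.8), 2 * l1$sem_rt)

  # all-proactive: CH ratio ~ 0 everywhere
  prof2 <- participant_profile(w_proactive = 1, lag_weight_curve = NULL,
                               miss_rate = 0)
  beh2 <- simulate_behavior(sq, prof2, seed = 1)
  rec2 <- classify_trials(sq, match_taps_to_pulses(sq, beh2$taps_ms),
                          mode_boundary = 100)
  p2 <- lag_locked_profile(rec2)
  expect_true(all(p2$ch_ratio[!is.na(p2$ch_ratio)] < 0.05))

  # (near-)constant RT: per-lag SEM ~ 0
  prof3 <- participant_profile(w_proactive = 1, lag_weight_curve = NULL,
                               mu_pro = -50, sigma_pro = 1e-6, miss_rate = 0,
                               far = 0)
  beh3 <- simulate_behavior(sq, prof3, seed = 1)
  rec3 <- classify_trials(sq, match_taps_to_pulses(sq, beh3$taps_ms))
  p3 <- lag_locked_profile(rec3)
  expect_true(all(p3$sem_rt[!is.na(p3$sem_rt)] < 1e-6))
})

test_that("category counts conserve slot counts and FAR ignores tap order", {
  sq <- generate_missing_sequence(120, 18, seed = 9)
  beh <- simulate_behavior(sq, participant_profile(), seed = 2)
  rec <- classify_trials(sq, match_taps_to_pulses(sq, beh$taps_ms))
  expect_equal(sum(rec$category %in% c("CH", "FH", "miss")),
               sum(sq$kind == "real"))
  expect_equal(sum(rec$category %in% c("FA", "CR")),
               sum(sq$kind == "missing"))

  shuffled <- match_taps_to_pulses(sq, sample(beh$taps_ms))
  rec2 <- classify_trials(sq, shuffled)
  expect_equal(participant_rates(rec2)$FAR, participant_rates(rec)$FAR)
})
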