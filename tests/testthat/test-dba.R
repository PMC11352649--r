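test_that("DBA series follows the rectified-sine-squared oracle", {
  zero <- eeg_recording(matrix(0, 256 * 4, 2), c("O1", "O2"), 256)
  expect_true(all(dba_index_series(zero)$data == 0))

  A <- 3
  rec <- sine_recording(11.5, amp = A, channels = c("O1", "O2"))
  dba <- dba_index_series(rec)
  expect_equal(dba$fs, 32)
  oracle <- mean(rectified_sine_stream_oracle(11.5, A)^2)
  expect_lt(abs(mean(dba$data) - oracle) / oracle, 0.15)

  # one silent channel halves the index
  half <- rec; half$data[, "O2"] <- 0
  expect_equal(mean(dba_index_series(half)$data), mean(dba$data) / 2,
               tolerance = 0.02)

  # gain g on the raw EEG scales DBA by g^2
  double <- rec; double$data <- 2 * rec$data
  expect_equal(mean(dba_index_series(double)$data), 4 * mean(dba$data),
               tolerance = 1e-6)

  noO2 <- eeg_recording(matrix(0, 512, 1), "O1", 256)
  expect_error(dba_index_series(noO2), "O2")
})

make_power_trace <- function(y, fs = 32, t0 = -1000) {
  structure(list(time_ms = t0 + (seq_along(y) - 1) * 1000 / fs,
                 mean = y, sem = rep(0, length(y)), n = 100,
                 baseline_ms = NULL),
            class = "trace_sem")
}

test_that("envelope normalization matches the sinusoid closed form", {
  tm <- seq(-1000, 8000 - 31.25, by = 31.25)
  const <- make_power_trace(rep(5, length(tm)))
  e0 <- envelope_normalize(const)
  expect_true(all(e0$normalized == 1))
  expect_equal(e0$delta, 0)

  m <- 5; a <- 1.5
  y <- m + a * sin(2 * pi * tm / 1000)
  env <- envelope_normalize(make_power_trace(y))
  expect_lt(abs(env$constant - m) / m, 0.05)
  expect_lt(abs(env$delta - 2 * a) / (2 * a), 0.05)
})

test_that("dip and peak features are located and offset-invariant", {
  tm <- seq(-1000, 8000 - 31.25, by = 31.25)
  carrier <- 5 + 0.3 * sin(2 * pi * tm / 4000)
  dip <- carrier - 2 * exp(-(tm + 50)^2 / (2 * 100^2))
  feats <- detect_extrema_features(make_power_trace(dip), window = c(-600, 600))
  expect_equal(nrow(feats$dips), 1)
  expect_lte(abs(feats$dips$time_ms + 50), 31.25)
  # dissolution: trace regains the midline after the dip
  expect_gt(feats$dips$dissolution_ms, feats$dips$time_ms)
  expect_lt(feats$dips$dissolution_ms, 600)

  flat <- detect_extrema_features(make_power_trace(rep(3, length(tm))))
  expect_equal(nrow(flat$dips) + nrow(flat$peaks), 0)

  two <- carrier - 2 * exp(-(tm + 400)^2 / (2 * 80^2)) -
    1.5 * exp(-(tm - 500)^2 / (2 * 80^2))
  f2 <- detect_extrema_features(make_power_trace(two), window = c(-800, 800))
  expect_equal(nrow(f2$dips), 2)
  expect_true(all(diff(f2$dips$time_ms) > 0))
  expect_lte(abs(f2$dips$time_ms[1] + 400), 31.25)
  expect_lte(abs(f2$dips$time_ms[2] - 500), 31.25)

  shifted <- detect_extrema_features(make_power_trace(two + 10),
                                     window = c(-800, 800))
  expect_equal(shifted$dips$time_ms, f2$dips$time_ms)
})

make_power_epochs <- function(n_epochs, modulation, noise = 0.3, seed = 1) {
  set.seed(seed)
  tm <- seq(-1000, 1000 - 31.25, by = 31.25)
  base <- 5
  m <- matrix(base, n_epochs, length(tm), byrow = TRUE) +
    matrix(rep(modulation(tm), n_epochs), n_epochs, byrow = TRUE) +
    matrix(rnorm(n_epochs * length(tm), 0, noise), n_epochs)
  structure(list(epochs = m, time_ms = tm,
                 category = rep(NA_character_, n_epochs),
                 rejected = rep(FALSE, n_epochs), fs = 32, n_dropped = 0),
            class = "epoch_set")
}

test_that("ERD/ERS classification detects injected power shifts", {
  erd <- make_power_epochs(200, function(t)
    -1.5 * exp(-(t + 50)^2 / (2 * 150^2)), seed = 21)
  r1 <- classify_erd_ers(erd, test_window = c(-200, 400),
                         baseline_window = c(-900, -500))
  expect_equal(r1$label, "ERD")
  expect_lt(r1$p, 0.05)

  ers <- make_power_epochs(200, function(t)
    1.5 * exp(-(t - 200)^2 / (2 * 150^2)), seed = 22)
  r2 <- classify_erd_ers(ers, test_window = c(-200, 400),
                         baseline_window = c(-900, -500))
  expect_equal(r2$label, "ERS")

  # no modulation: false-positive rate near the nominal alpha
  labs <- vapply(1:60, function(s) {
    ep <- make_power_epochs(40, function(t) 0 * t, seed = 100 + s)
    classify_erd_ers(ep, c(-200, 400), c(-900, -500))$label
  }, character(1))
  expect_lte(mean(labs != "none"), 0.15)

  degen <- make_power_epochs(5, function(t) 0 * t, noise = 0, seed = 1)
  expect_warning(out <- classify_erd_ers(degen, c(-200, 400), c(-900, -500)),
                 "degenerate")
  expect_equal(out$label, "none")
})

test_that("event-locked modulation is recovered in ER-DBA traces", {
  sq <- annotate_lags(generate_regular_sequence(40, 1000))
  set.seed(33)
  # proactive-dominant participants: expect a pre-tap power decrease (ERD)
  eps <- list()
  for (i in 1:4) {
    prof <- participant_profile(w_proactive = 1, lag_weight_curve = NULL,
                                miss_rate = 0, far = 0, noise_sd = 2,
                                artifact_rate = 0,
                                alpha_freq = runif(1, 10.2, 12.8))
    beh <- simulate_behavior(sq, prof)
    sim <- simulate_eeg(sq, beh$truth, prof)
    dba <- dba_index_series(sim$rec)
    eps <- c(eps, list(epoch_stream(dba, sq$onset_ms, -1000, 8000)))
  }
  tr <- grand_average(bind_epoch_sets(eps), baseline_window = c(-700, -400))
  dipzone <- tr$time_ms >= -150 & tr$time_ms <= 50
  expect_lt(mean(tr$mean[dipzone]), 0)

  # doubling the modulation depth roughly doubles the recovered excursion
  depth_exc <- function(d, seed) {
    set.seed(seed)
    eps <- list()
    for (i in 1:6) {
      prof <- participant_profile(w_proactive = 1, lag_weight_curve = NULL,
                                  miss_rate = 0, far = 0, noise_sd = 0,
                                  artifact_rate = 0, erd_depth = d,
                                  alpha_freq = runif(1, 10.2, 12.8))
      beh <- simulate_behavior(sq, prof)
      sim <- simulate_eeg(sq, beh$truth, prof)
      dba <- dba_index_series(sim$rec)
      eps <- c(eps, list(epoch_stream(dba, sq$onset_ms, -1000, 8000)))
    }
    tr <- grand_average(bind_epoch_sets(eps), baseline_window = NULL)
    dipzone <- tr$time_ms >= -150 & tr$time_ms <= 50
    plateau <- tr$time_ms >= 300 & tr$time_ms <= 600
    mean(tr$mean[plateau]) - mean(tr$mean[dipzone])
  }
  e1 <- depth_exc(0.1, 41)
  e2 <- depth_exc(0.2, 41)
  expect_lt(abs(e2 / e1 - 2) / 2, 0.1)
})

test_that("unmodulated alpha yields a flat ER-DBA trace", {
  sq <- annotate_lags(generate_regular_sequence(40, 1000))
  set.seed(35)
  eps <- list()
  for (i in 1:4) {
    prof <- participant_profile(erd_depth = 0, ers_gain = 0, noise_sd = 2,
                                artifact_rate = 0,
                                alpha_freq = runif(1, 10.2, 12.8))
    beh <- simulate_behavior(sq, prof)
    sim <- simulate_eeg(sq, beh$truth, prof)
    dba <- dba_index_series(sim$rec)
    eps <- c(eps, list(epoch_stream(dba, sq$onset_ms, -1000, 8000)))
  }
  tr <- grand_average(bind_epoch_sets(eps), baseline_window = c(-500, 0))
  frac_outside <- mean(abs(tr$mean) > 2 * tr$sem)
  expect_lte(frac_outside, 0.2)
})
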