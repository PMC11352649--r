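#' Synthetic cohort generator
#'
#' Generates tap behavior and three-channel EEG (O1, O2, Cz at 256
#' samples/s) with the statistical structure the analysis pipeline assumes:
#' per-participant dual-mode reaction-time mixtures (proactive lobe near
#' -50 ms, reactive near +200 ms), per-missing-slot false-alarm
#' probabilities, an alpha-2 carrier on the occipital channels whose
#' amplitude is event-locked modulated (deactivation around proactive taps,
#' activation on reactive/avoid trials), late-auditory ERP templates and
#' omission templates on Cz, 1/f background noise and occasional
#' high-amplitude artifact bursts. Every draw is reproducible given a seed
#' and ground truth is recorded trial by trial.
#'
#' @name synthetic_cohort
NULL

#' Participant profile
#'
#' Behavioral and electrophysiological parameters of one synthetic
#' participant. Defaults reflect the study conditions: RT lobes at -50 and
#' +200 ms (sigma 40 ms), false alarms centered at the event onset, an
#' alpha-2 carrier whose base amplitude (4.11 uV) and modulation depth
#' (0.33, of which about 0.6 survives the narrowband filter) put the
#' grand-average power excursion near 1.95 uV^2, and a
#' lag-dependent proactive weight following the observed correct-hit-ratio
#' trajectory around the missing-pulse site.
#'
#' @param w_proactive baseline probability a real-pulse tap is proactive
#' @param mu_pro,sigma_pro proactive RT Gaussian, ms
#' @param mu_rea,sigma_rea reactive RT Gaussian, ms
#' @param mu_fa mean RT of false-alarm taps, ms (imagery-driven, near 0)
#' @param far per-missing-slot false-alarm probability
#' @param miss_rate per-real-slot omission probability
#' @param lag_weight_curve named numeric vector mapping lag number to a
#'   proactive-weight override, or NULL
#' @param alpha_freq alpha-2 carrier frequency, Hz (in 10-13)
#' @param alpha_base_amp carrier base amplitude, uV
#' @param erd_depth fractional amplitude dip on proactive trials (0-1)
#' @param ers_gain fractional amplitude gain on reactive/avoid trials
#' @param mod_sigma_ms width (Gaussian sigma) of the event-locked
#'   modulation, ms
#' @param phase_noise carrier phase-diffusion rate, rad per sqrt(s);
#'   dephases the alpha carrier across epochs as real alpha does (finite
#'   coherence time), so rectification ripple is incoherent in averages
#' @param erp_amplitudes named uV amplitudes for
#'   P1, N1, P2, N2, LPC, oN1, oP2
#' @param erp_latencies named ms latencies for the same components
#' @param noise_sd broadband background SD, uV
#' @param artifact_rate artifact bursts per minute
#' @param artifact_amp artifact burst amplitude, uV
#' @return a `participant_profile` list
#' @export
participant_profile <- function(w_proactive = 0.5,
                                mu_pro = -50, sigma_pro = 40,
                                mu_rea = 200, sigma_rea = 40,
                                mu_fa = 0,
                                far = 0.3, miss_rate = 0.03,
                                lag_weight_curve = default_lag_weights(),
                                alpha_freq = 11.5,
                                alpha_base_amp = 4.11,
                                erd_depth = 0.33, ers_gain = 0.33,
                                mod_sigma_ms = 150,
                                phase_noise = 2,
                                erp_amplitudes = c(P1 = 2, N1 = -5, P2 = 4,
                                                   N2 = -3, LPC = 3,
                                                   oN1 = -3, oP2 = 3),
                                erp_latencies = c(P1 = 60, N1 = 100, P2 = 200,
                                                  N2 = 350, LPC = 600,
                                                  oN1 = 200, oP2 = 400),
                                noise_sd = 4, artifact_rate = 0.5,
                                artifact_amp = 200) {
  p <- as.list(environment())
  probs <- c(p$w_proactive, p$far, p$miss_rate, unlist(p$lag_weight_curve))
  stopifnot(all(probs >= 0 & probs <= 1),
            p$sigma_pro > 0, p$sigma_rea > 0,
            p$alpha_freq >= 10, p$alpha_freq <= 13)
  class(p) <- "participant_profile"
  p
}

#' Default lag-dependent proactive weights
#'
#' One minus the correct-hit-ratio trajectory around the missing-pulse
#' site: strongly reactive immediately after an omission (lag 1), drifting
#' back toward proactive dominance over the following pulses.
#' @export
default_lag_weights <- function() {
  c("-2" = 0.30, "-1" = 0.26, "1" = 0.10, "2" = 0.40,
    "3" = 0.46, "4" = 0.49, "5" = 0.39, "6" = 0.35)
}

rtrunc_norm <- function(n, mu, sigma, lo = -480, hi = 480) {
  x <- stats::rnorm(n, mu, sigma)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu, sigma)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

lag_weight <- function(profile, lag_post, lag_pre) {
  curve <- profile$lag_weight_curve
  if (is.null(curve)) return(profile$w_proactive)
  cand <- c(lag_post, lag_pre)
  cand <- cand[!is.na(cand) & as.character(cand) %in% names(curve)]
  if (length(cand) == 0) return(profile$w_proactive)
  # the nearer missing pulse dominates; ties go to the post-missing label
  best <- cand[order(abs(cand), -sign(cand))][1]
  unname(curve[as.character(best)])
}

#' Simulate tap behavior for one participant
#'
#' Each real slot yields a tap with probability `1 - miss_rate`, in
#' proactive or reactive mode (lag-dependent weight) with mode-specific
#' Gaussian RT; each missing slot yields a false-alarm tap with probability
#' `far`, proactive, centered at the event onset. RTs are truncated to
#' (-480, 480) ms so every tap stays inside its slot's matching window.
#'
#' @param seq an annotated `pulse_sequence`
#' @param profile a `participant_profile`
#' @param seed RNG seed
#' @return list(taps_ms, truth) where truth is a ground-truth trial table
#'   (slot_index, kind, lag_post, lag_pre, category, rt_ms, mode)
#' @export
simulate_behavior <- function(seq, profile, seed = NULL) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(seq)
  rt <- rep(NA_real_, n)
  mode <- rep("none", n)
  category <- character(n)
  for (i in seq_len(n)) {
    if (seq$kind[i] == "real") {
      if (stats::runif(1) < profile$miss_rate) {
        category[i] <- "miss"
      } else {
        w <- lag_weight(profile, seq$lag_post[i], seq$lag_pre[i])
        if (stats::runif(1) < w) {
          mode[i] <- "proactive"
          rt[i] <- rtrunc_norm(1, profile$mu_pro, profile$sigma_pro)
          category[i] <- "FH"
        } else {
          mode[i] <- "reactive"
          rt[i] <- rtrunc_norm(1, profile$mu_rea, profile$sigma_rea)
          category[i] <- "CH"
        }
      }
    } else {
      if (stats::runif(1) < profile$far) {
        mode[i] <- "proactive"
        rt[i] <- rtrunc_norm(1, profile$mu_fa, profile$sigma_pro)
        category[i] <- "FA"
      } else {
        category[i] <- "CR"
      }
    }
  }
  truth <- data.frame(slot_index = seq$slot_index, kind = seq$kind,
                      lag_post = seq$lag_post, lag_pre = seq$lag_pre,
                      category = category, rt_ms = rt, mode = mode,
                      stringsAsFactors = FALSE)
  list(taps_ms = seq$onset_ms[!is.na(rt)] + rt[!is.na(rt)], truth = truth)
}

one_over_f_noise <- function(n, fs, sd_total, white_frac = 0.3,
                             f_floor = 1) {
  white <- stats::rnorm(n)
  spec <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f_fold, f_floor))
  shape[1] <- 0
  pink <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)
  x <- sqrt(1 - white_frac) * pink + sqrt(white_frac) * white
  sd_total * x / stats::sd(x)
}

add_gaussian_events <- function(x, t_ms, centers_ms, amps, sigma_ms) {
  dt <- t_ms[2] - t_ms[1]
  half <- ceiling(4 * sigma_ms / dt)
  for (k in seq_along(centers_ms)) {
    i0 <- round((centers_ms[k] - t_ms[1]) / dt) + 1
    lo <- max(1, i0 - half); hi <- min(length(x), i0 + half)
    if (lo > hi) next
    tt <- t_ms[lo:hi]
    x[lo:hi] <- x[lo:hi] + amps[k] * exp(-(tt - centers_ms[k])^2 / (2 * sigma_ms^2))
  }
  x
}

#' Simulate EEG for one participant
#'
#' O1/O2 carry 1/f-plus-white background and an alpha-2 sinusoid whose
#' amplitude is multiplicatively modulated by event-locked Gaussians:
#' dips (depth `erd_depth`) at the tap times of proactive trials (FH, FA),
#' gains (`ers_gain`) at reactive tap times (CH) and at the onset of
#' avoided omissions (CR). Cz carries the background plus per-trial ERP
#' templates: the late-auditory component set on every presented real
#' pulse, oN1 + oP2 on false-alarm omissions, oP2 only on correct
#' rejections. The omission components sit at the latencies of the
#' real-pulse P2 and N2 with opposite polarity, so the false-alarm trace
#' approximates a polarity reversal of the real-pulse trace. Artifact
#' bursts (200-ms Hann-windowed broadband noise, EMG-like, scaled by
#' `artifact_amp`) are
#' injected on all channels at `artifact_rate` per minute.
#'
#' @param seq an annotated `pulse_sequence`
#' @param truth ground-truth trial table from [simulate_behavior()]
#' @param profile a `participant_profile`
#' @param seed RNG seed
#' @param fs sample rate (default 256)
#' @param margin_ms recording margin before the first and after the last
#'   slot (default 2000)
#' @return list(rec = `eeg_recording`, markers = list(onsets_ms, taps_ms),
#'   artifact_times_ms)
#' @export
simulate_eeg <- function(seq, truth, profile, seed = NULL, fs = 256,
                         margin_ms = 2000) {
  if (!is.null(seed)) set.seed(seed)
  isi <- attr(seq, "isi")
  t0 <- -margin_ms
  t_end <- max(seq$onset_ms) + isi + margin_ms
  n <- round((t_end - t0) / 1000 * fs)
  t_ms <- t0 + (seq_len(n) - 1) * 1000 / fs
  tapped <- !is.na(truth$rt_ms)
  tap_time <- seq$onset_ms + truth$rt_ms

  # amplitude modulation envelope, shared by O1 and O2
  m <- rep(1, n)
  pro <- tapped & truth$mode == "proactive"
  rea <- tapped & truth$mode == "reactive"
  avoid <- truth$category == "CR"
  if (any(pro)) m <- add_gaussian_events(m, t_ms, tap_time[pro],
                                         rep(-profile$erd_depth, sum(pro)),
                                         profile$mod_sigma_ms)
  if (any(rea)) m <- add_gaussian_events(m, t_ms, tap_time[rea],
                                         rep(profile$ers_gain, sum(rea)),
                                         profile$mod_sigma_ms)
  if (any(avoid)) m <- add_gaussian_events(m, t_ms, seq$onset_ms[avoid],
                                           rep(profile$ers_gain, sum(avoid)),
                                           profile$mod_sigma_ms)
  m <- pmax(m, 0.05)
  # carrier with phase diffusion: real alpha has a finite coherence time,
  # so the rectification ripple decorrelates across epochs
  drift <- cumsum(stats::rnorm(n, 0, profile$phase_noise / sqrt(fs)))
  carrier1 <- sin(2 * pi * profile$alpha_freq * t_ms / 1000 + drift +
                  stats::runif(1, 0, 2 * pi))
  carrier2 <- sin(2 * pi * profile$alpha_freq * t_ms / 1000 + drift +
                  stats::runif(1, 0, 2 * pi))
  A <- profile$alpha_base_amp * m
  o1 <- one_over_f_noise(n, fs, profile$noise_sd) + A * carrier1
  o2 <- one_over_f_noise(n, fs, profile$noise_sd) + A * carrier2

  # Cz: ERP templates
  cz <- one_over_f_noise(n, fs, profile$noise_sd)
  amp <- profile$erp_amplitudes; lat <- profile$erp_latencies
  widths <- c(P1 = 15, N1 = 20, P2 = 30, N2 = 50, LPC = 80,
              oN1 = 20, oP2 = 30)
  presented <- seq$kind == "real" & truth$category != "miss"
  heard <- seq$kind == "real"   # LAEP follows the stimulus, tap or no tap
  for (comp in c("P1", "N1", "P2", "N2", "LPC")) {
    cz <- add_gaussian_events(cz, t_ms, seq$onset_ms[heard] + lat[comp],
                              rep(amp[comp], sum(heard)), widths[comp])
  }
  fa <- truth$category == "FA"
  for (comp in c("oN1", "oP2")) {
    cz <- add_gaussian_events(cz, t_ms, seq$onset_ms[fa] + lat[comp],
                              rep(amp[comp], sum(fa)), widths[comp])
  }
  cz <- add_gaussian_events(cz, t_ms, seq$onset_ms[avoid] + lat["oP2"],
                            rep(amp["oP2"], sum(avoid)), widths["oP2"])

  # artifact bursts on all channels
  dur_min <- (t_end - t0) / 60000
  n_art <- stats::rpois(1, profile$artifact_rate * dur_min)
  art_times <- sort(stats::runif(n_art, t0 + 500, t_end - 500))
  if (n_art > 0) {
    for (at in art_times) {
      i0 <- round((at - t0) / 1000 * fs) + 1
      w <- round(0.2 * fs)             # 200-ms Hann-windowed broadband burst
      idx <- i0:min(i0 + w - 1, n)
      hann <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / w)
      burst <- profile$artifact_amp * hann * stats::rnorm(length(idx))
      o1[idx] <- o1[idx] + burst
      o2[idx] <- o2[idx] + burst
      cz[idx] <- cz[idx] + burst
    }
  }
  rec <- eeg_recording(cbind(O1 = o1, O2 = o2, Cz = cz),
                       c("O1", "O2", "Cz"), fs, start_ms = t0)
  list(rec = rec,
       markers = list(onsets_ms = seq$onset_ms,
                      taps_ms = sort(tap_time[tapped])),
       artifact_times_ms = art_times)
}

#' Cohort configuration defaults
#'
#' Study conditions: 33 participants; Task 1 regular sequence of 120 pulses
#' at 1000 ms; Task 2 missing-pulse sequence of 300 slots with 45 omissions
#' (no adjacent omissions); per-participant false-alarm probability uniform
#' on \[0.1, 0.6\]; alpha frequency uniform on \[10, 13\] Hz.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    n_participants = 33,
    task1 = list(n_pulses = 120, isi = 1000),
    task2 = list(n_total = 300, n_missing = 45, isi = 1000,
                 min_separation = 2),
    profile = list(far_range = c(0.1, 0.6),
                   alpha_freq_range = c(10, 13),
                   w_proactive = 0.5,
                   overrides = list()),
    pipeline = list(epoch_window = c(-1000, 8000),
                    dba_baseline = c(-500, 0),
                    erp_baseline = c(-200, 0),
                    rt_window = c(-500, 500),
                    reject_k = 3,
                    alpha = 0.05)
  )
}

validate_config <- function(config) {
  req <- c("n_participants", "task1", "task2", "profile", "pipeline")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f)) {
    stop("config missing required field(s): ", paste(missing_f, collapse = ", "))
  }
  fr <- config$profile$far_range
  if (!is.null(fr) && (length(fr) != 2 || any(fr < 0 | fr > 1) || fr[1] > fr[2])) {
    stop("profile$far_range must be an increasing pair inside [0, 1]")
  }
  invisible(config)
}

#' Generate a full synthetic cohort
#'
#' Draws one Task-2 sequence shared by the cohort (as in the experiment),
#' a per-participant profile (false-alarm probability and alpha frequency
#' from the configured ranges), and per-participant behavior and EEG for
#' both tasks. Deterministic given `seed`.
#'
#' @param config configuration list (see [default_config()])
#' @param seed integer seed
#' @param eeg generate EEG (TRUE) or behavior only (FALSE)
#' @param tasks which tasks to simulate (default c(1, 2))
#' @return a `synthetic_cohort` list: config, seed, per-task sequence and
#'   participant list (profile, taps_ms, truth, rec, markers)
#' @export
generate_cohort <- function(config = default_config(), seed = 1, eeg = TRUE,
                            tasks = c(1, 2)) {
  validate_config(config)
  set.seed(seed)
  seq1 <- generate_regular_sequence(config$task1$n_pulses, config$task1$isi)
  seq1 <- annotate_lags(seq1)
  seq2 <- generate_missing_sequence(config$task2$n_total,
                                    config$task2$n_missing,
                                    min_separation = config$task2$min_separation,
                                    isi = config$task2$isi)
  out <- list(config = config, seed = seed)
  profiles <- lapply(seq_len(config$n_participants), function(i) {
    args <- list(
      far = stats::runif(1, config$profile$far_range[1],
                         config$profile$far_range[2]),
      alpha_freq = stats::runif(1, config$profile$alpha_freq_range[1],
                                config$profile$alpha_freq_range[2]),
      w_proactive = config$profile$w_proactive
    )
    do.call(participant_profile, utils::modifyList(args, config$profile$overrides))
  })
  for (task in tasks) {
    sq <- if (task == 1) seq1 else seq2
    participants <- lapply(seq_len(config$n_participants), function(i) {
      beh <- simulate_behavior(sq, profiles[[i]])
      p <- list(id = sprintf("P%02d", i), profile = profiles[[i]],
                taps_ms = beh$taps_ms, truth = beh$truth)
      if (eeg) {
        sim <- simulate_eeg(sq, beh$truth, profiles[[i]])
        p$rec <- sim$rec
        p$markers <- sim$markers
        p$artifact_times_ms <- sim$artifact_times_ms
      }
      p
    })
    out[[paste0("task", task)]] <- list(seq = sq, participants = participants)
  }
  class(out) <- "synthetic_cohort"
  out
}
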