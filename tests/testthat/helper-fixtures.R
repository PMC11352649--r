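# Shared fixtures: small recordings and cohorts built in code.

# single- or multi-channel sinusoid recording
sine_recording <- function(freq_hz, amp = 1, dur_s = 20, fs = 256,
                           channels = "O1", start_ms = 0, phase = 0) {
  t <- (seq_len(fs * dur_s) - 1) / fs
  x <- amp * sin(2 * pi * freq_hz * t + phase)
  eeg_recording(matrix(rep(x, length(channels)), ncol = length(channels)),
                channels, fs, start_ms)
}

# steady-state gain of a filtered sinusoid (middle section, edge transients cut)
steady_gain <- function(rec_out, amp_in) {
  n <- nrow(rec_out$data)
  mid <- rec_out$data[floor(n / 4):floor(3 * n / 4), 1]
  max(abs(mid)) / amp_in
}

# high-resolution oracle of the rectify + 8-block-average recipe applied to
# a pure sinusoid (no filter): returns the stream values on the 32-Hz grid
rectified_sine_stream_oracle <- function(freq_hz, amp, dur_s = 20, fs = 256,
                                         ma = 8, oversample = 64) {
  fs_hi <- fs * oversample
  t <- (seq_len(fs_hi * dur_s) - 1) / fs_hi
  x <- abs(amp * sin(2 * pi * freq_hz * t))
  # average over each 8-sample (at fs) block == ma*oversample hi-res samples
  blk <- ma * oversample
  nblk <- length(x) %/% blk
  as.numeric(tapply(x[seq_len(nblk * blk)], rep(seq_len(nblk), each = blk), mean))
}

# a small behavior-only cohort configuration
small_config <- function(n_participants = 3, n_total = 60, n_missing = 9) {
  cfg <- default_config()
  cfg$n_participants <- n_participants
  cfg$task1 <- list(n_pulses = 20, isi = 1000)
  cfg$task2 <- list(n_total = n_total, n_missing = n_missing, isi = 1000,
                    min_separation = 2)
  cfg
}
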