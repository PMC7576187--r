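# Shared fixtures, built lazily once per test run and cached across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small, fast dataset for unit-level pipeline checks.
small_trials <- function() {
  fixture("small_trials", function() {
    gen_dataset(synth_config(n_trials = 2, trial_duration_s = 12,
                             n_channels = 8, snr_db = c(3, -3),
                             noise_sd = 150, seed = 11))
  })
}

# The standard study conditions: 5 SNR x 4 trials, 60 s, 64 channels,
# attended/ignored response gains 1.0/0.3, calibrated noise.
std_trials <- function() {
  fixture("std_trials", function() gen_dataset(synth_config(seed = 2024)))
}

std_loo <- function() {
  fixture("std_loo", function() {
    loo_decode(std_trials(), lambda = 2^8,
               variants = c("intact", "high_rms"))
  })
}

# Null conditions: the ignored stream drives the EEG as strongly as the
# attended one; 8 trials per SNR give 200 ten-second windows.
null_trials <- function() {
  fixture("null_trials", function() {
    gen_dataset(synth_config(n_trials = 8, ignored_gain = 1.0,
                             variants = "intact", seed = 2025))
  })
}

# Hand-built noise-free trials whose EEG is generated with the same
# zero-padded edge convention the lagged design uses, so model fits can be
# exact (gen_dataset trims the onset, which breaks exactness at the edges).
clean_trials <- function(m = 3, nsamp = 800, nch = 3) {
  k <- make_trf_kernel()
  smooth_env <- function() {
    normalize_envelope(envelope(
      as.numeric(stats::filter(rnorm(nsamp), rep(1 / 6, 6),
                               circular = TRUE)), fs = 100))
  }
  tl <- lapply(seq_len(m), function(i) {
    att <- smooth_env(); ign <- smooth_env()
    eeg <- simulate_eeg(att, ign, k, attention_gain = 1, ignored_gain = 0,
                        noise_sd = 0,
                        topography = seq(0.5, 1, length.out = nch))
    eeg$trial_id <- sprintf("clean%02d", i)
    list(trial_id = eeg$trial_id, snr_db = 0, attended_id = "a",
         ignored_scale = 1, eeg = eeg,
         env = list(intact = list(attended = att, ignored = ign)))
  })
  structure(list(trials = tl, fs = 100,
                 channel_names = tl[[1]]$eeg$channel_names, kernel = k,
                 config = NULL),
            class = "trial_set")
}

# Independent per-sample reference for the high-RMS mask: a sample is high
# iff at least one block covering it has RMS at/above the utterance
# threshold. Deliberately brute force (per-sample scan over all blocks).
ref_high_rms_mask <- function(x, fs, block_ms = 16, overlap = 0.5,
                              threshold_db = 0) {
  blen <- round(block_ms / 1000 * fs)
  hop <- max(1L, round(blen * (1 - overlap)))
  starts <- seq.int(1L, length(x) - blen + 1L, by = hop)
  thr <- sqrt(mean(x^2)) * 10^(threshold_db / 20)
  flags <- logical(length(x))
  for (i in seq_along(x)) {
    for (s in starts) {
      if (i >= s && i <= s + blen - 1L) {
        if (sqrt(mean(x[s:(s + blen - 1L)]^2)) >= thr) {
          flags[i] <- TRUE
          break
        }
      }
    }
  }
  flags
}

# Amplitude of a sinusoid after passing through a filter function, measured
# away from the edges.
probe_gain <- function(filter_fun, freq, fs, dur = 8) {
  t <- seq(0, dur, by = 1 / fs)
  y <- filter_fun(sin(2 * pi * freq * t))
  core <- y[round(length(y) * 0.3):round(length(y) * 0.7)]
  max(abs(core))
}

# Peak-shift of a symmetric pulse through a filter function, in samples.
pulse_shift <- function(filter_fun, fs, dur = 6, width = 0.05) {
  t <- seq(0, dur, by = 1 / fs)
  k <- round(length(t) / 2)
  x <- exp(-0.5 * ((seq_along(t) - k) / (width * fs))^2)
  y <- filter_fun(x)
  which.max(abs(y)) - k
}
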