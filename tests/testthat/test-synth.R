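# Synthetic-data generator: kernels, speech-like waveforms, EEG simulation,
# and full datasets with ground truth.

test_that("kernel construction places bumps where the spec says", {
  one <- kernel_spec(data.frame(polarity = 1, latency_ms = 100,
                                width_ms = 20, gain = 1),
                     lag_range_ms = c(0, 400), fs = 100)
  k <- make_trf_kernel(one)
  expect_equal(k$lags_ms[which.max(k$weights)], 100)

  k3 <- make_trf_kernel(kernel_spec())  # +95, -165, +265 ms
  w <- k3$weights
  # count interior sign-consistent local extrema numerically
  ext <- which(diff(sign(diff(w))) != 0) + 1L
  ext <- ext[abs(w[ext]) > 1e-3]
  expect_length(ext, 3L)
  expect_equal(sign(w[ext]), c(1, -1, 1))
  expect_equal(k3$lags_ms[ext], c(95, 165, 265), tolerance = 10)
})

test_that("kernel specs are validated", {
  expect_error(kernel_spec(data.frame()), "non-empty")
  expect_error(kernel_spec(data.frame(polarity = 1, latency_ms = 500,
                                      width_ms = 10, gain = 1)),
               "inside")
  expect_error(kernel_spec(data.frame(polarity = 1, latency_ms = 100,
                                      width_ms = -1, gain = 1)),
               "width")
})

test_that("speech waveforms are reproducible, silence-calibrated, unit RMS", {
  w1 <- gen_speech_waveform(60, silence_fraction = 0.3, seed = 5)
  w2 <- gen_speech_waveform(60, silence_fraction = 0.3, seed = 5)
  expect_identical(w1$samples, w2$samples)

  low <- mean(abs(w1$samples) < 0.01 * max(abs(w1$samples)))
  expect_gt(low, 0.25)
  expect_lt(low, 0.35)

  silent <- attr(w1, "silent")
  expect_equal(sqrt(mean(w1$samples[!silent]^2)), 1, tolerance = 1e-6)

  expect_error(gen_speech_waveform(-1), "positive")
  expect_error(gen_speech_waveform(10, silence_fraction = 1), "silence_fraction")
})

test_that("speech modulation energy concentrates in the syllabic band", {
  w <- gen_speech_waveform(60, seed = 9)
  env <- resample_to_eeg_rate(hilbert_envelope(w))$values
  sp <- Mod(stats::fft(env - mean(env)))^2
  f <- (seq_along(sp) - 1) * 100 / length(sp)
  dens_band <- sum(sp[f >= 2 & f <= 8]) / 6
  dens_rest <- sum(sp[f > 8 & f <= 50]) / 42
  expect_gt(dens_band / dens_rest, 2)
})

test_that("simulated EEG follows the generative model exactly when noise-free", {
  k <- make_trf_kernel()
  env <- envelope(sin(2 * pi * 4 * seq(0, 10, by = 0.01)) + 2, fs = 100)
  ign <- envelope(cos(2 * pi * 3 * seq(0, 10, by = 0.01)) + 2, fs = 100)

  eeg <- simulate_eeg(env, ign, k, attention_gain = 0.7, ignored_gain = 0,
                      noise_sd = 0, topography = rep(1, 4))
  expect_equal(nrow(eeg$data), 4L)
  expect_equal(eeg$data[1, ], eeg$data[3, ])
  # direct convolution oracle for the first channel
  tau <- round(k$lags_ms * k$fs / 1000)
  n <- length(env$values)
  y <- numeric(n)
  for (j in seq_along(tau)) {
    tj <- tau[j]
    if (tj < n) y[(tj + 1):n] <- y[(tj + 1):n] + k$weights[j] * env$values[seq_len(n - tj)]
  }
  expect_equal(eeg$data[1, ], 0.7 * y, tolerance = 1e-12)
})

test_that("simulated EEG is linear in the response gains", {
  k <- make_trf_kernel()
  a <- envelope(runif(500), fs = 100)
  b <- envelope(runif(500), fs = 100)
  f <- function(ga, gi) simulate_eeg(a, b, k, attention_gain = ga,
                                     ignored_gain = gi, noise_sd = 0,
                                     topography = c(1, 0.5))$data
  expect_equal(f(1, 0.3) + f(0.5, 0.2), f(1.5, 0.5), tolerance = 1e-10)
  expect_equal(2 * f(1, 0), f(2, 0), tolerance = 1e-10)
})

test_that("simulated EEG noise is seeded and mismatched lengths error", {
  k <- make_trf_kernel()
  a <- envelope(runif(300), fs = 100)
  e1 <- simulate_eeg(a, a, k, noise_sd = 1, n_channels = 2, seed = 4)
  e2 <- simulate_eeg(a, a, k, noise_sd = 1, n_channels = 2, seed = 4)
  expect_identical(e1$data, e2$data)
  expect_error(simulate_eeg(a, envelope(runif(299), fs = 100), k),
               "equal length")
})

test_that("datasets have the right shape, labels, and epoch lengths", {
  tr <- small_trials()
  expect_s3_class(tr, "trial_set")
  expect_length(tr, 4L)  # 2 SNR x 2 trials
  expect_equal(sort(unique(vapply(tr$trials, `[[`, numeric(1), "snr_db"))),
               c(-3, 3))
  # epoching contract: (duration - 1 s) * 100 Hz
  for (t in tr$trials) {
    expect_equal(ncol(t$eeg$data), (12 - 1) * 100)
    expect_equal(length(t$env$intact$attended$values), 1100)
    expect_true(t$env$intact$attended$normalized)
  }
})

test_that("datasets are bit-identical under a seed and differ across seeds", {
  cfg <- synth_config(n_trials = 1, trial_duration_s = 8, n_channels = 2,
                      snr_db = 0, noise_sd = 10, seed = 21)
  d1 <- gen_dataset(cfg)
  d2 <- gen_dataset(cfg)
  expect_identical(d1$trials[[1]]$eeg$data, d2$trials[[1]]$eeg$data)
  expect_identical(d1$trials[[1]]$env, d2$trials[[1]]$env)

  cfg2 <- synth_config(n_trials = 1, trial_duration_s = 8, n_channels = 2,
                       snr_db = 0, noise_sd = 10, seed = 22)
  d3 <- gen_dataset(cfg2)
  expect_false(identical(d1$trials[[1]]$eeg$data, d3$trials[[1]]$eeg$data))
  expect_identical(dim(d1$trials[[1]]$eeg$data), dim(d3$trials[[1]]$eeg$data))
  expect_identical(d1$trials[[1]]$snr_db, d3$trials[[1]]$snr_db)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(trial_duration_s = 1), "exceed 2")
  expect_error(synth_config(attention_gain = -1), ">= 0")
  expect_error(synth_config(n_channels = 0), ">= 1")
  expect_error(synth_config(topography = c(1, 2), n_channels = 3),
               "per channel")
})
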