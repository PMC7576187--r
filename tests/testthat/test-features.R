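# Stimulus features: block RMS, relative-RMS masking, gating, envelopes,
# resampling, band-pass, normalization, SNR mixing.

test_that("block RMS matches direct computation on toy inputs", {
  fs <- 16000
  const <- audio_stimulus(rep(0.5, fs), fs = fs)
  br <- block_rms(const)
  expect_equal(br$block_len, 256L)   # 0.016 * 16000
  expect_equal(br$hop, 128L)
  expect_true(all(abs(br$rms - 0.5) < 1e-12))

  # loud half then silent half
  wave <- c(rep(2, 8 * 256), rep(0, 8 * 256))
  br2 <- block_rms(wave, fs = fs)
  full_loud <- br2$starts + br2$block_len - 1L <= 8 * 256
  full_quiet <- br2$starts > 8 * 256
  expect_true(all(abs(br2$rms[full_loud] - 2) < 1e-12))
  expect_true(all(br2$rms[full_quiet] == 0))
  mixed <- !full_loud & !full_quiet
  expect_true(all(br2$rms[mixed] > 0 & br2$rms[mixed] < 2))

  expect_error(block_rms(rep(1, 10), fs = fs), "shorter")
})

test_that("high-RMS mask flags the loud half and respects the tie rule", {
  fs <- 16000
  # constant wave, length an exact block tiling so every sample is covered
  n <- 255 * 128 + 256
  expect_true(all(high_rms_mask(rep(0.3, n), fs = fs)$flags))

  wave <- c(rep(2, 16 * 256), rep(0, 16 * 256))
  m <- high_rms_mask(wave, fs = fs)
  expect_true(all(m$flags[1:(16 * 256)]))
  expect_true(mean(m$flags[(16 * 256 + 129):(32 * 256)]) < 0.05)

  expect_error(high_rms_mask(rep(0, 1000), fs = fs), "all-zero")
})

test_that("the mask is scale-invariant", {
  set.seed(8)
  wave <- rnorm(5000) * rep(c(2, 0.2), each = 2500)
  m1 <- high_rms_mask(wave, fs = 16000)
  for (c in c(0.01, 3, 1000))
    expect_identical(high_rms_mask(c * wave, fs = 16000)$flags, m1$flags)
})

test_that("mask agrees with an independent per-sample reference", {
  set.seed(123)
  fs <- 1000  # 16 ms blocks of 16 samples keep the brute force affordable
  for (i in 1:20) {
    n <- sample(300:800, 1)
    x <- rnorm(n) * stats::filter(abs(rnorm(n, sd = 2)), rep(1 / 50, 50),
                                  circular = TRUE)
    x <- as.numeric(x)
    expect_identical(high_rms_mask(x, fs = fs)$flags,
                     ref_high_rms_mask(x, fs = fs))
  }
})

test_that("gating zeroes exactly the off-mask samples and is idempotent", {
  fs <- 16000
  wave <- audio_stimulus(c(rep(2, 8 * 256), rep(0.01, 8 * 256)), fs = fs)
  m <- high_rms_mask(wave)
  g <- gate_to_high_rms(wave, m)
  expect_equal(g$samples[!m$flags], rep(0, sum(!m$flags)))
  expect_equal(g$samples[m$flags], wave$samples[m$flags])
  expect_identical(gate_to_high_rms(g, m)$samples, g$samples)

  all_true <- rep(TRUE, length(wave$samples))
  expect_equal(gate_to_high_rms(wave, all_true)$samples, wave$samples)
  expect_equal(gate_to_high_rms(wave, !all_true)$samples,
               rep(0, length(wave$samples)))
  expect_error(gate_to_high_rms(wave, c(TRUE, FALSE)), "length")
})

test_that("Hilbert envelope recovers amplitude and dominates the waveform", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  tone <- 3 * sin(2 * pi * 50 * t)
  env <- hilbert_envelope(tone, fs = fs)
  core <- env$values[200:1800]
  expect_true(all(abs(core - 3) < 0.03))

  expect_equal(hilbert_envelope(numeric(100) , fs = fs)$values, numeric(100))

  m <- 1 + 0.8 * sin(2 * pi * 2 * t)          # slow nonnegative modulator
  am <- m * cos(2 * pi * 100 * t)
  env2 <- hilbert_envelope(am, fs = fs)$values
  expect_true(all(abs(env2[300:1700] - m[300:1700]) / m[300:1700] < 0.02))

  set.seed(1)
  x <- rnorm(2048)
  expect_true(all(hilbert_envelope(x, fs = fs)$values >= abs(x) - 1e-9))
})

test_that("resampling preserves duration, constants, and slow modulations", {
  fs <- 16000
  n <- 60 * fs
  env <- envelope(rep(2.5, n), fs = fs)
  out <- resample_to_eeg_rate(env)
  expect_equal(length(out$values), 6000)
  expect_true(all(abs(out$values[100:5900] - 2.5) < 1e-6))

  t <- seq_len(n) / fs
  s <- 1 + 0.5 * sin(2 * pi * 3 * t)
  out2 <- resample_to_eeg_rate(envelope(s, fs = fs))$values
  amp <- (max(out2[500:5500]) - min(out2[500:5500])) / 2
  expect_equal(amp, 0.5, tolerance = 0.02)

  expect_error(resample_to_eeg_rate(envelope(1:10, fs = 100), fs_out = 200),
               "below")
})

test_that("envelope band-pass has the stated pass/stop behaviour, zero phase", {
  in_band <- probe_gain(function(x) bandpass_envelope(x, "2-8", fs = 100)$values,
                        5, 100)
  expect_equal(in_band, 1, tolerance = 0.05)
  out_band <- probe_gain(function(x) bandpass_envelope(x, "15-30", fs = 100)$values,
                         5, 100)
  expect_lt(out_band, 10^(-20 / 20))

  # impulse stays put (zero phase)
  x <- numeric(600); x[300] <- 1
  y <- bandpass_envelope(x, "2-8", fs = 100)$values
  expect_lte(abs(which.max(abs(y)) - 300), 1)

  # DC rejection
  yc <- bandpass_envelope(rep(1, 600), "2-8", fs = 100)$values
  expect_lt(mean(abs(yc)), 1e-3)

  expect_error(bandpass_envelope(rnorm(100), "1-4", fs = 100), "unknown band")
  expect_error(bandpass_envelope(rnorm(100), "2-8", fs = 200), "100 Hz")
})

test_that("normalization is a z-score: idempotent and scale-invariant", {
  set.seed(2)
  env <- envelope(runif(500, 1, 4), fs = 100)
  z <- normalize_envelope(env)
  expect_equal(mean(z$values), 0, tolerance = 1e-10)
  expect_equal(stats::var(z$values), 1, tolerance = 1e-10)
  expect_true(z$normalized)
  expect_equal(normalize_envelope(z)$values, z$values, tolerance = 1e-10)
  env5 <- envelope(5 * env$values, fs = 100)
  expect_equal(normalize_envelope(env5)$values, z$values, tolerance = 1e-10)
  expect_error(normalize_envelope(envelope(rep(1, 100), fs = 100)), "constant")
})

test_that("SNR mixing fixes the attended stream and scales the ignored one", {
  set.seed(3)
  att <- audio_stimulus(rnorm(4000), fs = 16000)
  ign <- audio_stimulus(rnorm(4000, sd = 2), fs = 16000)
  for (snr in c(6, 3, 0, -3, -6)) {
    mix <- mix_at_snr(att, ign, snr)
    scaled_ign <- mix$samples - att$samples
    expect_equal(rms(att$samples) / rms(scaled_ign), 10^(snr / 20),
                 tolerance = 1e-9)
    expect_equal(scaled_ign, attr(mix, "ignored_scale") * ign$samples,
                 tolerance = 1e-12)
  }
  expect_error(mix_at_snr(att$samples, rep(0, 4000), 0, fs = 16000), "zero-RMS")
})

test_that("the envelope pipeline is closed under an all-high mask", {
  # square wave: |x| is constant, so every block RMS equals the utterance
  # RMS exactly and all covered samples are flagged high; gating is then the
  # identity and the high-RMS envelope equals the intact one exactly
  fs <- 16000
  n <- 749 * 128 + 256
  t <- seq_len(n) / fs
  wave <- audio_stimulus(sign(sin(2 * pi * 440 * t)), fs = fs)
  expect_true(all(high_rms_mask(wave)$flags))
  e_int <- speech_envelope(wave, variant = "intact")
  e_hi <- speech_envelope(wave, variant = "high_rms")
  expect_identical(e_hi$values, e_int$values)
  expect_identical(e_hi$variant, "high_rms")
})

test_that("synthetic speech lands in the plausible mask-fraction band", {
  for (seed in c(1, 77)) {
    w <- gen_speech_waveform(60, silence_fraction = 0.3, seed = seed)
    frac <- high_rms_mask(w)$fraction
    expect_gt(frac, 0.15)
    expect_lt(frac, 0.50)
  }
})
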