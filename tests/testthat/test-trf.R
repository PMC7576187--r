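# Lagged designs, ridge solutions, forward/backward TRF models, model
# averaging, cross-validation, and component extraction.

test_that("lagged designs have the documented shape and content", {
  d <- lagged_design(rnorm(500), -200, 800, fs = 100)
  expect_equal(ncol(d$X), 101 + 1)           # (800+200)/10 + 1 lags + bias
  expect_equal(length(d$lags_ms), 101)

  d64 <- lagged_design(matrix(rnorm(200 * 64), 200), 0, 400, fs = 100)
  expect_equal(ncol(d64$X), 64 * 41 + 1)

  x <- rnorm(50)
  d0 <- lagged_design(x, 0, 0, fs = 100)     # lag 0 only: identity + bias
  expect_equal(d0$X[, 1], x)
  expect_equal(d0$X[, 2], rep(1, 50))

  # lag content: column for lag tau holds x[t - tau]
  d1 <- lagged_design(x, 0, 20, fs = 100, bias = FALSE)
  expect_equal(d1$X[, 2], c(0, x[1:49]))
  expect_equal(d1$X[, 3], c(0, 0, x[1:48]))

  expect_error(lagged_design(x, 0, 15, fs = 100), "multiple")
})

test_that("ridge matches the brute-force normal-equations oracle", {
  set.seed(42)
  for (i in 1:25) {
    x <- matrix(rnorm(50 * 5), 50)
    d <- lagged_design(x, 0, 10, fs = 1000)  # 2 lags x 5 inputs + bias
    y <- rnorm(50)
    for (lam in c(0.1, 1, 10)) {
      w <- ridge_solve(d, y, lam)
      pen <- diag(c(rep(lam, ncol(d$X) - 1), 0))
      w_oracle <- solve(crossprod(d$X) + pen, crossprod(d$X, y))
      expect_lt(max(abs(w - w_oracle)) / max(abs(w_oracle)), 1e-8)
    }
  }
})

test_that("unpenalized least squares recovers planted weights exactly", {
  set.seed(7)
  x <- matrix(rnorm(200 * 3), 200)
  d <- lagged_design(x, 0, 0, fs = 100)
  w_true <- c(2, -1, 0.5, 0.25)              # includes bias
  y <- d$X %*% w_true
  expect_equal(as.numeric(ridge_solve(d, y, 0)), w_true, tolerance = 1e-8)
})

test_that("shrinkage sends non-bias weights to zero and is monotone", {
  set.seed(13)
  x <- rnorm(400)
  d <- lagged_design(x, 0, 50, fs = 100)
  y <- rnorm(400) + 2
  norms <- vapply(c(0, 1, 1e3, 1e6, 1e12), function(lam) {
    w <- ridge_solve(d, y, lam)
    sqrt(sum(w[-length(w)]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[5], 1e-6 * norms[1])
})

test_that("singular systems at lambda zero advise regularization", {
  x <- rep(1, 30)                            # collinear with the bias column
  d <- lagged_design(x, 0, 0, fs = 100)
  expect_error(ridge_solve(d, rnorm(30), 0), "lambda > 0")
})

test_that("a forward fit on noise-free data recovers the kernel", {
  k <- make_trf_kernel()
  set.seed(31)
  w <- gen_speech_waveform(60, seed = 31)
  env <- normalize_envelope(resample_to_eeg_rate(hilbert_envelope(w)))
  eeg <- simulate_eeg(env, env, k, attention_gain = 1, ignored_gain = 0,
                      noise_sd = 0, n_channels = 1)
  # no onset trim here: generation and design then share the same zero-padded
  # edges, so the fit is exact
  fit <- trf(env, eeg, direction = "forward", lambda = 0.01)
  prof <- coef(fit)[, 1]
  sel <- fit$lags_ms %in% k$lags_ms
  expect_gte(stats::cor(prof[sel], k$weights), 0.999)

  # training-data prediction is essentially perfect
  pr <- predict_eeg(fit, env, eeg)
  expect_equal(unname(pr$r[1]), 1, tolerance = 1e-6)

  # a zero envelope predicts the bias only
  p0 <- predict(fit, envelope(numeric(500), fs = 100))
  expect_true(all(abs(p0 - fit$bias[1]) < 1e-12))
})

test_that("EEG unrelated to the stimulus yields near-zero correlations", {
  set.seed(99)
  env <- envelope(rnorm(5900), fs = 100)
  eeg <- eeg_epoch(matrix(rnorm(5900), 1), fs = 100)
  fit <- trf(env, eeg, direction = "forward", lambda = 2^8, keep_data = FALSE)
  held_env <- envelope(rnorm(5900), fs = 100)
  held_eeg <- matrix(rnorm(5900), 1)
  pr <- predict_eeg(fit, held_env, held_eeg)
  expect_lt(abs(pr$r_mean), 0.05)
})

test_that("a backward decoder inverts a delayed single-channel copy", {
  set.seed(17)
  w <- gen_speech_waveform(60, seed = 17)
  env <- normalize_envelope(resample_to_eeg_rate(hilbert_envelope(w)))
  s <- env$values
  delay <- 10                                 # 100 ms at 100 Hz
  r_del <- c(numeric(delay), s[1:(length(s) - delay)])
  dec <- trf(s, matrix(r_del, 1), direction = "backward", lambda = 1e-6,
             fs = 100)
  g <- coef(dec)[1, ]
  expect_equal(dec$lags_ms[which.max(abs(g))], 100)
  expect_gt(abs(g[dec$lags_ms == 100]) / sqrt(sum(g^2)), 0.9)
  shat <- reconstruct_envelope(dec, matrix(r_del, 1))
  expect_gte(stats::cor(shat, s), 0.999)

  # 64-channel decoder parameter count: 64 * 41 + bias
  eeg64 <- eeg_epoch(matrix(rnorm(64 * 700), 64), fs = 100)
  dec64 <- trf(rnorm(700), eeg64, direction = "backward", lambda = 10)
  expect_equal(length(dec64$weights) + length(dec64$bias), 64 * 41 + 1)
})

test_that("decoder quality degrades monotonically toward the shrinkage limit", {
  set.seed(23)
  s <- as.numeric(stats::filter(rnorm(2000), rep(0.2, 5), circular = TRUE))
  eeg <- eeg_epoch(rbind(c(numeric(5), s[1:1995]), rnorm(2000)), fs = 100)
  rs <- vapply(c(1, 1e4, 1e8), function(lam) {
    dec <- trf(s, eeg, direction = "backward", lambda = lam)
    stats::cor(reconstruct_envelope(dec, eeg), s)
  }, numeric(1))
  expect_true(all(diff(rs) <= 1e-8))
})

test_that("model averaging is elementwise and validates shapes", {
  set.seed(5)
  mk <- function() trf(rnorm(300), matrix(rnorm(600), 2),
                       direction = "forward", lambda = 1, tmin_ms = 0,
                       tmax_ms = 100, fs = 100, keep_data = FALSE)
  m1 <- mk(); m2 <- mk(); m3 <- mk()
  avg <- average_models(list(m1, m2, m3))
  expect_equal(avg$weights, (m1$weights + m2$weights + m3$weights) / 3)
  expect_equal(avg$bias, (m1$bias + m2$bias + m3$bias) / 3)
  expect_equal(average_models(list(m1, m1))$weights, m1$weights)

  neg <- m1; neg$weights <- -neg$weights; neg$bias <- -neg$bias
  zero <- average_models(list(m1, neg))
  expect_true(all(zero$weights == 0) && all(zero$bias == 0))

  short <- trf(rnorm(300), matrix(rnorm(600), 2), direction = "forward",
               lambda = 1, tmin_ms = 0, tmax_ms = 50, fs = 100)
  expect_error(average_models(list(m1, short)), "differ")
})

test_that("component extraction finds P1/N1/P2 and honours tie rules", {
  k <- make_trf_kernel()
  set.seed(41)
  env <- envelope(as.numeric(stats::filter(rnorm(4000), rep(1/6, 6),
                                           circular = TRUE)), fs = 100)
  eeg <- simulate_eeg(env, env, k, attention_gain = 1, ignored_gain = 0,
                      noise_sd = 0, n_channels = 3)
  fit <- trf(normalize_envelope(env), eeg, direction = "forward", lambda = 1)
  comp <- trf_components(fit)
  expect_equal(comp$component, c("P1", "N1", "P2"))
  expect_lte(abs(comp$latency_ms[1] - 95), 10)
  expect_lte(abs(comp$latency_ms[2] - 165), 10)
  expect_lte(abs(comp$latency_ms[3] - 265), 10)
  expect_lte(comp$amplitude[2], 0)           # N1 is negative
  expect_gt(comp$amplitude[1], 0)

  # flat model: zero amplitudes, latency at the window start
  zeeg <- eeg_epoch(matrix(0, 2, 1000), fs = 100)
  zfit <- suppressWarnings(trf(envelope(rnorm(1000), fs = 100), zeeg,
                               direction = "forward", lambda = 1))
  zcomp <- trf_components(zfit)
  expect_equal(zcomp$amplitude, c(0, 0, 0))
  expect_equal(zcomp$latency_ms, c(80, 150, 230))

  # lag grid must cover the component windows
  narrow <- trf(envelope(rnorm(1000), fs = 100),
                eeg_epoch(matrix(rnorm(2000), 2), fs = 100),
                direction = "forward", lambda = 1, tmin_ms = 0, tmax_ms = 200)
  expect_error(trf_components(narrow), "cover")
})

test_that("edge zero-padding has negligible effect on 59 s training fits", {
  tr <- std_trials()$trials[[1]]
  env <- tr$env$intact$attended
  fit <- trf(env, tr$eeg, direction = "forward", lambda = 2^8)
  pred <- predict(fit, env)
  j <- match("Cz", fit$channel_names)
  r_full <- stats::cor(pred[, j], tr$eeg$data[j, ])
  i <- 101:(nrow(pred) - 100)
  r_core <- stats::cor(pred[i, j], tr$eeg$data[j, i])
  expect_lt(abs(r_full - r_core), 0.01)
})

test_that("cross-validation selects sensible ridge parameters", {
  # a grid of one returns that element
  sm <- small_trials()
  cv1 <- loo_tune_lambda(sm, grid = 2^8)
  expect_equal(cv1$lambda, 2^8)
  expect_equal(nrow(cv1$table), length(sm))

  # noise-free, edge-consistent data needs no regularization: the smallest
  # grid value wins (shrinkage can only bias an already-exact fit)
  set.seed(901)
  clean <- clean_trials()
  cv0 <- loo_tune_lambda(clean, grid = 2^c(0, 4, 8, 12),
                         direction = "forward")
  expect_equal(cv0$lambda, 1)

  # with overfitting pressure (few samples, many channels, strong noise on a
  # weak response) the optimum moves strictly inside the grid
  noisy <- gen_dataset(synth_config(n_trials = 4, trial_duration_s = 8,
                                    n_channels = 16, snr_db = 0,
                                    attention_gain = 0.05, ignored_gain = 0,
                                    noise_sd = 1, variants = "intact",
                                    seed = 78))
  cvn <- loo_tune_lambda(noisy, grid = 2^seq(0, 12, 2))
  expect_gt(cvn$lambda, 2^0)
  expect_lt(cvn$lambda, 2^12)
  expect_error(loo_tune_lambda(sm, grid = numeric(0)), "empty")
})

test_that("trf objects expose the standard modelling methods", {
  set.seed(55)
  env <- envelope(rnorm(800), fs = 100)
  eeg <- eeg_epoch(matrix(rnorm(2 * 800), 2), fs = 100,
                   channel_names = c("Fz", "Cz"))
  fit <- trf(env, eeg, direction = "forward", lambda = 4)
  expect_output(print(fit), "forward")
  expect_output(print(summary(fit)), "weight range")
  expect_equal(dim(coef(fit, drop = FALSE)), c(1L, 101L, 2L))
  res <- residuals(fit)
  expect_equal(dim(res), c(800L, 2L))
  expect_equal(fitted(fit) + res, t(eeg$data), tolerance = 1e-10)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit, channel_set = "Cz"); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
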