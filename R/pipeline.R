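# Orchestration: a validated run configuration and the simulate / fit /
# evaluate / demo stages, each writing its outputs (with the config echo and
# its checksum) into a run directory.

#' Build and validate a run configuration
#'
#' Collects every tunable of the pipeline, with the standard analysis
#' constants as defaults: 16 ms / 50%-overlap blocks and a 0 dB relative-RMS
#' threshold for segmentation, the 2-8 / 8-15 / 15-30 Hz bands, forward lags
#' -200..800 ms and backward lags 0..400 ms, the ridge grid
#' `2^0, 2^2, ..., 2^12`, decoding windows 60/30/10/2 s, and the
#' fronto-central channel set. Synthesis settings are delegated to
#' [synth_config()].
#'
#' @param synth A [synth_config()] (defaults to the standard conditions with
#'   `seed`).
#' @param seed Integer seed used for the synthesis default.
#' @param variants Envelope variants to analyse.
#' @param band Analysis band for decoding.
#' @param lambda_grid Ridge candidates for [loo_tune_lambda()].
#' @param lambda Fixed ridge parameter used when `tune = FALSE`.
#' @param tune Tune lambda by leave-one-out cross-validation in [aad_fit()].
#' @param forward_lags_ms,backward_lags_ms Lag windows in ms.
#' @param durations_s Decoding-window durations in seconds.
#' @param channel_set Fronto-central channel names for component extraction.
#' @param threshold_db Relative-RMS threshold for the high-RMS mask.
#' @param store_audio Write stimulus WAV files in [aad_simulate()].
#' @return An object of class `aad_config`.
#' @export
aad_config <- function(synth = NULL, seed = 1L,
                       variants = c("intact", "high_rms"), band = "2-8",
                       lambda_grid = 2^seq(0, 12, 2), lambda = 2^8,
                       tune = TRUE,
                       forward_lags_ms = c(-200, 800),
                       backward_lags_ms = c(0, 400),
                       durations_s = c(60, 30, 10, 2),
                       channel_set = frontocentral_channels(),
                       threshold_db = 0, store_audio = FALSE) {
  synth <- synth %||% synth_config(seed = seed, variants = variants)
  stopifnot(inherits(synth, "synth_config"))
  if (forward_lags_ms[1] >= forward_lags_ms[2] ||
      backward_lags_ms[1] >= backward_lags_ms[2])
    stop("lag windows must be increasing pairs", call. = FALSE)
  if (!length(lambda_grid) || any(lambda_grid < 0))
    stop("`lambda_grid` must be nonnegative and non-empty", call. = FALSE)
  if (any(durations_s <= 0)) stop("durations must be positive", call. = FALSE)
  structure(list(synth = synth, seed = as.integer(seed), variants = variants,
                 band = band, lambda_grid = lambda_grid, lambda = lambda,
                 tune = tune, forward_lags_ms = forward_lags_ms,
                 backward_lags_ms = backward_lags_ms,
                 durations_s = durations_s, channel_set = channel_set,
                 threshold_db = threshold_db, store_audio = store_audio),
            class = "aad_config")
}

config_as_list <- function(cfg) {
  s <- cfg$synth
  list(seed = cfg$seed, variants = cfg$variants, band = cfg$band,
       lambda_grid = cfg$lambda_grid, lambda = cfg$lambda, tune = cfg$tune,
       forward_lags_ms = cfg$forward_lags_ms,
       backward_lags_ms = cfg$backward_lags_ms,
       durations_s = cfg$durations_s, channel_set = cfg$channel_set,
       threshold_db = cfg$threshold_db, store_audio = cfg$store_audio,
       synth = list(n_trials = s$n_trials,
                    trial_duration_s = s$trial_duration_s, snr_db = s$snr_db,
                    attention_gain = s$attention_gain,
                    ignored_gain = s$ignored_gain, noise_sd = s$noise_sd,
                    n_channels = s$n_channels, topography = s$topography,
                    channel_names = s$channel_names,
                    silence_fraction = s$silence_fraction,
                    fs_audio = s$fs_audio, fs_eeg = s$fs_eeg, band = s$band,
                    variants = s$variants, seed = s$seed,
                    kernel = s$kernel$spec$components))
}

# Echo the config into outdir and return its md5 hash.
write_config_echo <- function(cfg, outdir) {
  path <- file.path(outdir, "config.json")
  jsonlite::write_json(config_as_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unname(tools::md5sum(path))
}

run_log <- function(outdir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  cat(line, "\n", sep = "", file = file.path(outdir, "run.log"), append = TRUE)
  invisible(line)
}

#' Simulate a dataset and write it to disk
#'
#' Generates the configured `trial_set`, writes every trial's EEG and
#' envelopes as text + JSON sidecars, the ground-truth kernel and labels as
#' JSON, and an echo of the configuration. Deterministic under the config
#' seed: rerunning into a fresh directory reproduces identical files.
#'
#' @param config An [aad_config()].
#' @param outdir Output directory (created if needed).
#' @return The generated `trial_set`, invisibly.
#' @export
aad_simulate <- function(config = aad_config(), outdir) {
  stopifnot(inherits(config, "aad_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory", call. = FALSE)
  hash <- write_config_echo(config, outdir)
  run_log(outdir, "simulate: seed %d, config %s, R %s", config$seed, hash,
          getRversion())
  t0 <- Sys.time()
  trials <- gen_dataset(config$synth, keep_audio = config$store_audio)
  for (tr in trials$trials) {
    write_eeg_text(tr$eeg, file.path(outdir, paste0(tr$trial_id, "_eeg")))
    if (!is.null(tr$audio)) {
      write_wav(tr$audio$attended,
                file.path(outdir, paste0(tr$trial_id, "_attended.wav")))
      write_wav(tr$audio$ignored,
                file.path(outdir, paste0(tr$trial_id, "_ignored.wav")))
      write_wav(tr$audio$mixture,
                file.path(outdir, paste0(tr$trial_id, "_mixture.wav")))
    }
    for (v in names(tr$env)) {
      write_envelope_text(tr$env[[v]]$attended,
                          file.path(outdir, sprintf("%s_env_%s_att", tr$trial_id, v)))
      write_envelope_text(tr$env[[v]]$ignored,
                          file.path(outdir, sprintf("%s_env_%s_ign", tr$trial_id, v)))
    }
  }
  labels <- data.frame(trial_id = vapply(trials$trials, `[[`, character(1), "trial_id"),
                       snr_db = vapply(trials$trials, `[[`, numeric(1), "snr_db"),
                       attended_id = vapply(trials$trials, `[[`, character(1), "attended_id"),
                       ignored_scale = vapply(trials$trials, `[[`, numeric(1), "ignored_scale"))
  utils::write.csv(labels, file.path(outdir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(lags_ms = trials$kernel$lags_ms,
                            weights = trials$kernel$weights,
                            components = trials$kernel$spec$components,
                            config_hash = hash),
                       file.path(outdir, "kernel.json"), digits = NA)
  run_log(outdir, "simulate: %d trials in %.1f s", length(trials$trials),
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(trials)
}

#' Fit decoders and the forward TRF for a dataset
#'
#' Optionally tunes the ridge parameter on the configured grid by
#' leave-one-out cross-validation (report written as `cv_report.csv`, one row
#' per candidate and fold), fits the averaged forward TRF, extracts its
#' P1/N1/P2 components (`trf_components.csv`), and runs the leave-one-out
#' averaged-decoder scheme for every variant.
#'
#' @param config An [aad_config()].
#' @param trials A `trial_set` (as from [aad_simulate()] / [gen_dataset()]).
#' @param outdir Output directory.
#' @return List with `lambda`, `cv` (or NULL), `forward` (a [trf()]), and
#'   `loo` (an `aad_loo`), invisibly.
#' @export
aad_fit <- function(config, trials, outdir) {
  stopifnot(inherits(config, "aad_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- write_config_echo(config, outdir)
  run_log(outdir, "fit: config %s", hash)
  t0 <- Sys.time()
  cv <- NULL
  lambda <- config$lambda
  if (isTRUE(config$tune)) {
    cv <- loo_tune_lambda(trials, grid = config$lambda_grid,
                          direction = "backward",
                          variant = config$variants[1],
                          tmin_ms = config$backward_lags_ms[1],
                          tmax_ms = config$backward_lags_ms[2])
    lambda <- cv$lambda
    utils::write.csv(cv$table, file.path(outdir, "cv_report.csv"),
                     row.names = FALSE)
  }
  fwd <- fit_forward_trf_set(trials, lambda = lambda,
                             variant = config$variants[1],
                             tmin_ms = config$forward_lags_ms[1],
                             tmax_ms = config$forward_lags_ms[2])
  comp <- trf_components(fwd, channel_set = config$channel_set)
  comp$config_hash <- hash
  utils::write.csv(comp, file.path(outdir, "trf_components.csv"),
                   row.names = FALSE)
  loo <- loo_decode(trials, lambda = lambda, variants = config$variants,
                    tmin_ms = config$backward_lags_ms[1],
                    tmax_ms = config$backward_lags_ms[2])
  run_log(outdir, "fit: lambda %g, %.1f s", lambda,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(lambda = lambda, cv = cv, forward = fwd, loo = loo))
}

#' Evaluate decoding accuracy and write result tables
#'
#' Produces the tidy accuracy table (`accuracy.csv`: one row per variant,
#' duration, and SNR with window counts), the per-trial reconstruction
#' correlations (`reconstruction_r.csv`, attended and ignored columns), and
#' a JSON summary.
#'
#' @param config An [aad_config()].
#' @param trials The decoded `trial_set`.
#' @param fit The result of [aad_fit()].
#' @param outdir Output directory.
#' @return The accuracy data frame, invisibly.
#' @export
aad_evaluate <- function(config, trials, fit, outdir) {
  stopifnot(inherits(config, "aad_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- write_config_echo(config, outdir)
  t0 <- Sys.time()
  acc <- evaluate_accuracy(trials, loo = fit$loo,
                           durations_s = config$durations_s,
                           variants = config$variants)
  acc_out <- acc
  acc_out$config_hash <- hash
  utils::write.csv(acc_out, file.path(outdir, "accuracy.csv"),
                   row.names = FALSE)
  recs <- do.call(rbind, lapply(names(fit$loo$variants), function(v) {
    s <- fit$loo$variants[[v]]$scores
    s$variant <- v
    s
  }))
  recs$config_hash <- hash
  utils::write.csv(recs, file.path(outdir, "reconstruction_r.csv"),
                   row.names = FALSE)
  pooled <- pool_accuracy(acc)
  jsonlite::write_json(list(lambda = fit$lambda, config_hash = hash,
                            pooled_accuracy = pooled,
                            mean_r_attended = mean(recs$r_attended),
                            mean_r_ignored = mean(recs$r_ignored)),
                       file.path(outdir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  run_log(outdir, "evaluate: %.1f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(acc)
}

#' Run a reduced end-to-end synthetic experiment
#'
#' Simulates, fits, and evaluates a small configuration (2 trials per SNR,
#' 20 s trials, 16 channels, a 3-point ridge grid) in about a minute, and
#' prints the pooled accuracy table. Useful as a smoke test and as the worked
#' example of the documentation.
#'
#' @param outdir Output directory (default: a fresh temporary directory).
#' @param seed Integer seed.
#' @param quiet Suppress printing.
#' @return List with `config`, `trials`, `fit`, `accuracy`, invisibly.
#' @export
aad_demo <- function(outdir = tempfile("aad_demo_"), seed = 1L,
                     quiet = FALSE) {
  synth <- synth_config(n_trials = 2, trial_duration_s = 20, n_channels = 16,
                        noise_sd = 150, seed = seed)
  config <- aad_config(synth = synth, seed = seed,
                       lambda_grid = 2^c(0, 4, 8), durations_s = c(20, 10, 2))
  trials <- aad_simulate(config, outdir)
  fit <- aad_fit(config, trials, outdir)
  acc <- aad_evaluate(config, trials, fit, outdir)
  if (!quiet) {
    cat(sprintf("demo run in %s\n", outdir))
    cat(sprintf("tuned lambda: %g\n", fit$lambda))
    cat("pooled decoding accuracy:\n")
    print(pool_accuracy(acc), row.names = FALSE)
    cat("forward TRF components:\n")
    print(trf_components(fit$forward), row.names = FALSE)
  }
  invisible(list(config = config, trials = trials, fit = fit, accuracy = acc))
}
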