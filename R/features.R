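# Stimulus-side feature extraction: relative-RMS segmentation of speech,
# high-RMS gating, Hilbert envelopes, resampling, band-pass filtering,
# normalization, and two-talker SNR mixing.

#' Short-block RMS of a waveform
#'
#' Divides the waveform into Hamming-delimited blocks (default 16 ms, 50%
#' overlap) and returns one RMS value per block. By default the RMS is
#' computed on the raw samples within each block — the Hamming window defines
#' block boundaries only — so block values are directly comparable with the
#' unweighted whole-utterance RMS used as the 0 dB reference. Set
#' `weighted = TRUE` to RMS the Hamming-weighted samples instead (normalized
#' by the window's own RMS). The trailing partial block is dropped.
#'
#' @param wave An [audio_stimulus()] or numeric vector.
#' @param block_ms Block size in milliseconds (default 16).
#' @param overlap Fractional overlap between adjacent blocks (default 0.5).
#' @param fs Sampling rate, required when `wave` is a bare vector.
#' @param weighted Apply the Hamming weights inside each block before the RMS.
#' @return A list with `rms` (one value per block), `starts` (1-based sample
#'   index of each block), `block_len` and `hop` in samples, and `fs`.
#' @export
block_rms <- function(wave, block_ms = 16, overlap = 0.5, fs = NULL,
                      weighted = FALSE) {
  w <- as_wave(wave, fs)
  blen <- round(block_ms / 1000 * w$fs)
  if (blen < 1L) stop("block shorter than one sample", call. = FALSE)
  if (length(w$samples) < blen)
    stop("waveform shorter than one block", call. = FALSE)
  hop <- max(1L, round(blen * (1 - overlap)))
  starts <- seq.int(1L, length(w$samples) - blen + 1L, by = hop)
  if (weighted) {
    win <- signal::hamming(blen)
    wnorm <- sqrt(mean(win^2))
    vals <- vapply(starts, function(s) {
      seg <- w$samples[s:(s + blen - 1L)] * win
      sqrt(mean(seg^2)) / wnorm
    }, numeric(1))
  } else {
    cs <- cumsum(c(0, w$samples^2))
    vals <- sqrt((cs[starts + blen] - cs[starts]) / blen)
  }
  list(rms = vals, starts = starts, block_len = blen, hop = hop, fs = w$fs,
       block_ms = block_ms, overlap = overlap)
}

#' High-RMS-level sample mask
#'
#' Flags the samples of an utterance that belong to its high-RMS-level
#' (intelligibility-critical, vowel-dominated) regions: a block is "high" when
#' its short-block RMS is at or above the whole-utterance RMS scaled by
#' `threshold_db` (default 0 dB, i.e. the utterance RMS itself; ties count as
#' high), and a sample is flagged when any overlapping high block covers it.
#' The mask is invariant to rescaling the waveform.
#'
#' @inheritParams block_rms
#' @param threshold_db Relative threshold in dB re the utterance RMS.
#' @return An object of class `sample_mask`: list with logical `flags` (one
#'   per sample), the segmentation parameters, and the flagged `fraction`.
#' @export
high_rms_mask <- function(wave, block_ms = 16, overlap = 0.5,
                          threshold_db = 0, fs = NULL) {
  w <- as_wave(wave, fs)
  utt <- rms(w$samples)
  if (utt == 0) stop("all-zero utterance: relative RMS threshold undefined",
                     call. = FALSE)
  br <- block_rms(w$samples, block_ms = block_ms, overlap = overlap, fs = w$fs)
  # ">= threshold": ties count as high; a hair of relative slack keeps exact
  # ties (e.g. a constant utterance) robust to floating-point summation order
  high <- br$rms >= utt * 10^(threshold_db / 20) * (1 - 1e-9)
  flags <- logical(length(w$samples))
  for (s in br$starts[high]) flags[s:(s + br$block_len - 1L)] <- TRUE
  structure(list(flags = flags, block_ms = block_ms, overlap = overlap,
                 threshold_db = threshold_db, fs = w$fs,
                 fraction = mean(flags)),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> %d samples, %.1f%% high-RMS (block %g ms, overlap %g, threshold %g dB)\n",
              length(x$flags), 100 * x$fraction, x$block_ms, x$overlap,
              x$threshold_db))
  invisible(x)
}

#' Gate a waveform to its high-RMS-level segments
#'
#' Zeroes every sample outside the mask while preserving the timeline (no
#' concatenation), so gated stimuli stay time-aligned with the EEG.
#'
#' @param wave An [audio_stimulus()] or numeric vector.
#' @param mask A `sample_mask` from [high_rms_mask()], or a logical vector.
#' @param fs Sampling rate for bare vectors.
#' @return An `audio_stim` with off-mask samples set to zero.
#' @export
gate_to_high_rms <- function(wave, mask, fs = NULL) {
  w <- as_wave(wave, fs)
  flags <- if (inherits(mask, "sample_mask")) mask$flags else as.logical(mask)
  if (length(flags) != length(w$samples))
    stop("mask length does not match waveform length", call. = FALSE)
  out <- w$samples
  out[!flags] <- 0
  id <- if (inherits(wave, "audio_stim")) paste0(wave$id, "_high_rms") else "high_rms"
  audio_stimulus(out, fs = w$fs, id = id)
}

#' Broadband Hilbert envelope
#'
#' Magnitude of the analytic signal. Satisfies `envelope >= |wave|` pointwise
#' (the real part of the analytic signal is the waveform itself).
#'
#' @param wave An [audio_stimulus()] or numeric vector.
#' @param fs Sampling rate for bare vectors.
#' @param variant Provenance label carried on the result.
#' @return An [envelope()] at the input rate, band `"broadband"`.
#' @export
hilbert_envelope <- function(wave, fs = NULL, variant = "intact") {
  w <- as_wave(wave, fs)
  envelope(Mod(analytic_signal(w$samples)), fs = w$fs, band = "broadband",
           variant = variant)
}

#' Resample an envelope to the EEG rate
#'
#' Anti-aliased rate conversion (Fourier-domain low-pass and decimation) to
#' `fs_out`, duration preserved within one output sample.
#'
#' @param env An [envelope()] or numeric vector.
#' @param fs_out Target rate in Hz (default 100; must be below the input rate).
#' @param fs Input rate for bare vectors.
#' @return An [envelope()] at `fs_out`.
#' @export
resample_to_eeg_rate <- function(env, fs_out = 100, fs = NULL) {
  w <- as_wave(env, fs)
  if (fs_out >= w$fs)
    stop("`fs_out` must be below the input sampling rate", call. = FALSE)
  n_out <- round(length(w$samples) * fs_out / w$fs)
  vals <- fft_resample(w$samples, n_out)
  if (inherits(env, "envelope"))
    envelope(vals, fs = fs_out, band = env$band, variant = env$variant,
             normalized = env$normalized)
  else envelope(vals, fs = fs_out)
}

band_edges <- function(band) {
  switch(band,
         "2-8"   = c(2, 8),
         "8-15"  = c(8, 15),
         "15-30" = c(15, 30),
         stop(sprintf("unknown band '%s'", band), call. = FALSE))
}

#' Band-pass an envelope with a 150th-order zero-phase FIR
#'
#' Applies a 150th-order Hamming-window FIR band-pass filter forward and
#' backward (zero phase: no group delay, a symmetric pulse keeps its peak to
#' within one sample; the magnitude response is applied twice).
#'
#' @param env An [envelope()] at 100 Hz, or numeric vector with `fs = 100`.
#' @param band `"2-8"`, `"8-15"`, or `"15-30"` (Hz).
#' @param order FIR order (default 150).
#' @param fs Input rate for bare vectors.
#' @return A band-labelled [envelope()].
#' @export
bandpass_envelope <- function(env, band = "2-8", order = 150, fs = NULL) {
  w <- as_wave(env, fs)
  if (w$fs != 100)
    stop("envelope band-pass is defined at the 100 Hz EEG rate", call. = FALSE)
  edges <- band_edges(band)
  b <- signal::fir1(order, edges / (w$fs / 2), type = "pass")
  vals <- fir_filtfilt(b, w$samples)
  variant <- if (inherits(env, "envelope")) env$variant else "intact"
  envelope(vals, fs = w$fs, band = band, variant = variant)
}

#' Z-score an envelope
#'
#' Centers and scales to unit variance (per trial). Scale-invariant and
#' idempotent; constant envelopes are rejected.
#'
#' @param env An [envelope()] or numeric vector.
#' @param fs Input rate for bare vectors.
#' @return The normalized [envelope()], `normalized` flag set.
#' @export
normalize_envelope <- function(env, fs = NULL) {
  w <- as_wave(env, if (is.null(fs) && !inherits(env, "envelope")) 1 else fs)
  s <- stats::sd(w$samples)
  if (!is.finite(s) || s == 0)
    stop("constant envelope cannot be normalized", call. = FALSE)
  vals <- (w$samples - mean(w$samples)) / s
  if (inherits(env, "envelope"))
    envelope(vals, fs = env$fs, band = env$band, variant = env$variant,
             normalized = TRUE)
  else envelope(vals, fs = w$fs, normalized = TRUE)
}

#' Mix two speech streams at a target SNR
#'
#' The attended stream is left untouched (its RMS level is the fixed
#' reference); the ignored stream is rescaled so that
#' `RMS(attended) / RMS(ignored) = 10^(snr_db/20)`, and the two are summed.
#'
#' @param att,ign Attended and ignored streams ([audio_stimulus()] or numeric
#'   vectors of equal length).
#' @param snr_db Target SNR in dB (attended re ignored).
#' @param fs Sampling rate for bare vectors.
#' @return An `audio_stim` mixture; the applied scale factor is attached as
#'   attribute `"ignored_scale"`.
#' @export
mix_at_snr <- function(att, ign, snr_db, fs = NULL) {
  wa <- as_wave(att, fs); wi <- as_wave(ign, fs)
  if (length(wa$samples) != length(wi$samples))
    stop("streams must have equal length", call. = FALSE)
  if (wa$fs != wi$fs) stop("streams must share a sampling rate", call. = FALSE)
  ra <- rms(wa$samples); ri <- rms(wi$samples)
  if (ra == 0 || ri == 0) stop("zero-RMS stream cannot be mixed", call. = FALSE)
  scale <- ra / (ri * 10^(snr_db / 20))
  out <- audio_stimulus(wa$samples + scale * wi$samples, fs = wa$fs,
                        id = sprintf("mix_%+gdB", snr_db))
  attr(out, "ignored_scale") <- scale
  out
}

#' Full envelope pipeline for one waveform
#'
#' Composes the stimulus-feature chain in its canonical order: (optionally)
#' gate to high-RMS segments at the audio rate, Hilbert envelope, anti-aliased
#' resampling to the EEG rate, zero-phase FIR band-pass, and per-trial
#' z-scoring.
#'
#' @param wave An [audio_stimulus()] or numeric vector.
#' @param band Target band (`"2-8"`, `"8-15"`, `"15-30"`) or `"broadband"` to
#'   skip the band-pass.
#' @param variant `"intact"` or `"high_rms"`.
#' @param fs_out EEG rate (default 100 Hz).
#' @param threshold_db Relative-RMS threshold for the high-RMS mask.
#' @param normalize Z-score the result (default TRUE).
#' @param fs Sampling rate for bare vectors.
#' @return An [envelope()] at `fs_out`.
#' @export
speech_envelope <- function(wave, band = "2-8", variant = "intact",
                            fs_out = 100, threshold_db = 0, normalize = TRUE,
                            fs = NULL) {
  w <- as_wave(wave, fs)
  stim <- audio_stimulus(w$samples, fs = w$fs)
  variant <- match.arg(variant, c("intact", "high_rms"))
  if (variant == "high_rms") {
    m <- high_rms_mask(stim, threshold_db = threshold_db)
    stim <- gate_to_high_rms(stim, m)
  }
  env <- hilbert_envelope(stim, variant = variant)
  env <- resample_to_eeg_rate(env, fs_out = fs_out)
  if (band != "broadband") env <- bandpass_envelope(env, band = band)
  if (normalize) env <- normalize_envelope(env)
  env
}
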