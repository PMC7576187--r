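# Deterministic EEG conditioning: re-referencing, zero-phase filtering,
# epoching, downsampling. All filters are applied forward-backward so that
# component latencies are never shifted.

#' Re-reference to the averaged mastoids
#'
#' Subtracts the mean of the left and right mastoid channels from every
#' channel and drops the mastoids from the output.
#'
#' @param eeg An [eeg_epoch()].
#' @param left,right Mastoid channel names (defaults `"M1"`, `"M2"`).
#' @return Re-referenced [eeg_epoch()] without the mastoid rows.
#' @export
rereference_mastoids <- function(eeg, left = "M1", right = "M2") {
  stopifnot(inherits(eeg, "eeg_epoch"))
  miss <- setdiff(c(left, right), eeg$channel_names)
  if (length(miss))
    stop(sprintf("mastoid channel(s) missing: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  ref <- colMeans(eeg$data[c(left, right), , drop = FALSE])
  keep <- setdiff(eeg$channel_names, c(left, right))
  out <- sweep(eeg$data[keep, , drop = FALSE], 2L, ref, "-")
  eeg_epoch(out, fs = eeg$fs, channel_names = keep, trial_id = eeg$trial_id,
            snr_db = eeg$snr_db, attended_id = eeg$attended_id)
}

filt_channels <- function(eeg, fun) {
  out <- t(apply(eeg$data, 1L, fun))
  eeg_epoch(out, fs = eeg$fs, channel_names = eeg$channel_names,
            trial_id = eeg$trial_id, snr_db = eeg$snr_db,
            attended_id = eeg$attended_id)
}

#' Broadband zero-phase Butterworth filter
#'
#' Fourth-order Butterworth band-pass (default 1-50 Hz) applied in both the
#' forward and backward directions (zero phase; effective order 8). Intended
#' for data at the acquisition rate, before downsampling.
#'
#' @param eeg An [eeg_epoch()] with `fs > 2 * high`.
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order of the one-way filter (default 4).
#' @return Filtered [eeg_epoch()].
#' @export
broadband_filter <- function(eeg, low = 1, high = 50, order = 4) {
  stopifnot(inherits(eeg, "eeg_epoch"))
  if (eeg$fs <= 2 * high)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 eeg$fs, high), call. = FALSE)
  bt <- signal::butter(order, c(low, high) / (eeg$fs / 2), type = "pass")
  filt_channels(eeg, function(x) as.numeric(signal::filtfilt(bt, x)))
}

#' Cut trials out of a continuous recording
#'
#' Extracts one epoch per trial, discarding the first `drop_first_s` seconds
#' after each mixture onset (onset responses are not stimulus-tracking): epoch
#' `i` spans `[onset_i + drop_first_s, onset_i + duration_i)`.
#'
#' @param eeg Continuous recording as an [eeg_epoch()].
#' @param onsets_s Numeric vector of trial onsets (seconds from recording start).
#' @param durations_s Trial durations in seconds (recycled to the number of
#'   onsets).
#' @param drop_first_s Seconds discarded after each onset (default 1).
#' @param trial_ids Optional ids for the epochs.
#' @return List of [eeg_epoch()] objects.
#' @export
epoch_trials <- function(eeg, onsets_s, durations_s, drop_first_s = 1,
                         trial_ids = NULL) {
  stopifnot(inherits(eeg, "eeg_epoch"))
  durations_s <- rep_len(durations_s, length(onsets_s))
  n <- ncol(eeg$data)
  out <- vector("list", length(onsets_s))
  for (i in seq_along(onsets_s)) {
    a <- round((onsets_s[i] + drop_first_s) * eeg$fs) + 1L
    b <- round((onsets_s[i] + durations_s[i]) * eeg$fs)
    if (a < 1L || b > n || a > b)
      stop(sprintf("trial %d spans [%d, %d] outside the recording (1..%d)",
                   i, a, b, n), call. = FALSE)
    out[[i]] <- eeg_epoch(eeg$data[, a:b, drop = FALSE], fs = eeg$fs,
                          channel_names = eeg$channel_names,
                          trial_id = if (is.null(trial_ids)) i else trial_ids[i])
  }
  out
}

#' Downsample EEG with anti-aliasing
#'
#' Fourier-domain rate conversion of every channel to `fs_out` (default
#' 100 Hz); duration preserved within one output sample.
#'
#' @param eeg An [eeg_epoch()].
#' @param fs_out Target rate, must be below `eeg$fs`.
#' @return Downsampled [eeg_epoch()].
#' @export
downsample_eeg <- function(eeg, fs_out = 100) {
  stopifnot(inherits(eeg, "eeg_epoch"))
  if (fs_out >= eeg$fs)
    stop("`fs_out` must be below the current sampling rate", call. = FALSE)
  n_out <- round(ncol(eeg$data) * fs_out / eeg$fs)
  out <- t(apply(eeg$data, 1L, fft_resample, n_out = n_out))
  eeg_epoch(out, fs = fs_out, channel_names = eeg$channel_names,
            trial_id = eeg$trial_id, snr_db = eeg$snr_db,
            attended_id = eeg$attended_id)
}

#' FIR order rule for narrowband EEG filters
#'
#' Order = three times the ratio of the sampling frequency to the lower
#' cutoff, rounded to the nearest even integer (symmetric FIR): 150 for the
#' 2-8 Hz band at 100 Hz, 38 for 8-15 Hz, 20 for 15-30 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param f_low Lower band edge in Hz.
#' @return Even integer FIR order.
#' @export
fir_order_rule <- function(fs, f_low) {
  2L * as.integer(round(3 * fs / f_low / 2))
}

#' Narrowband zero-phase FIR filter for EEG
#'
#' Band-pass FIR with the order set by [fir_order_rule()], applied forward and
#' backward (zero phase).
#'
#' @param eeg An [eeg_epoch()] at 100 Hz.
#' @param band `"2-8"`, `"8-15"`, or `"15-30"` (Hz).
#' @return Filtered [eeg_epoch()].
#' @export
narrowband_filter <- function(eeg, band = "2-8") {
  stopifnot(inherits(eeg, "eeg_epoch"))
  if (eeg$fs != 100)
    stop("narrowband EEG filtering is defined at the 100 Hz rate", call. = FALSE)
  edges <- band_edges(band)
  ord <- fir_order_rule(eeg$fs, edges[1])
  b <- signal::fir1(ord, edges / (eeg$fs / 2), type = "pass")
  filt_channels(eeg, function(x) fir_filtfilt(b, x))
}

#' Artifact-rejection hook
#'
#' Placeholder for users preprocessing real recordings with their own
#' component-based artifact removal; returns the input unchanged.
#'
#' @param eeg An [eeg_epoch()].
#' @param fun Optional function `eeg -> eeg` to apply.
#' @return The (possibly transformed) epoch.
#' @export
artifact_hook <- function(eeg, fun = NULL) {
  if (is.null(fun)) eeg else fun(eeg)
}
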