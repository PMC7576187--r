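#' Audio stimulus container
#'
#' Wraps a mono waveform with its sampling rate. All stimulus-side operations
#' (segmentation, gating, envelope extraction, mixing) accept either an
#' `audio_stim` or a bare numeric vector plus `fs`.
#'
#' @param samples Numeric vector of amplitudes (unitless).
#' @param fs Sampling rate in Hz (default 16000, the rate speech stimuli are
#'   stored at).
#' @param id Optional identifier string.
#' @return An object of class `audio_stim`.
#' @export
audio_stimulus <- function(samples, fs = 16000, id = "stim") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || !all(is.finite(samples)))
    stop("`samples` must be a non-empty finite numeric vector", call. = FALSE)
  stop_if_not_scalar_num(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  structure(list(samples = samples, fs = fs, id = as.character(id)),
            class = "audio_stim")
}

#' @export
print.audio_stim <- function(x, ...) {
  cat(sprintf("<audio_stim '%s'> %d samples @ %g Hz (%.2f s), RMS %.4g\n",
              x$id, length(x$samples), x$fs,
              length(x$samples) / x$fs, rms(x$samples)))
  invisible(x)
}

# Coerce an audio_stim / envelope / numeric vector to samples + fs.
as_wave <- function(x, fs = NULL) {
  if (inherits(x, "audio_stim")) return(list(samples = x$samples, fs = x$fs))
  if (inherits(x, "envelope")) return(list(samples = x$values, fs = x$fs))
  if (is.numeric(x)) {
    if (is.null(fs)) stop("`fs` must be given for a bare numeric vector",
                          call. = FALSE)
    return(list(samples = as.numeric(x), fs = fs))
  }
  stop("expected an audio_stim, envelope, or numeric vector", call. = FALSE)
}

#' Temporal envelope container
#'
#' An amplitude-envelope time series with its provenance: sampling rate,
#' frequency band, and whether it came from the intact waveform or from the
#' high-RMS-gated one, and whether it has been z-scored.
#'
#' @param values Numeric envelope series.
#' @param fs Sampling rate in Hz.
#' @param band One of `"broadband"`, `"2-8"`, `"8-15"`, `"15-30"`.
#' @param variant `"intact"` or `"high_rms"`.
#' @param normalized Logical; `TRUE` after [normalize_envelope()].
#' @return An object of class `envelope`.
#' @export
envelope <- function(values, fs, band = "broadband", variant = "intact",
                     normalized = FALSE) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("envelope values must be finite", call. = FALSE)
  stop_if_not_scalar_num(fs, "fs")
  band <- match.arg(band, c("broadband", "2-8", "8-15", "15-30"))
  variant <- match.arg(variant, c("intact", "high_rms"))
  structure(list(values = values, fs = fs, band = band, variant = variant,
                 normalized = isTRUE(normalized)),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz, band %s, %s%s\n",
              length(x$values), x$fs, x$band, x$variant,
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

env_values <- function(x) if (inherits(x, "envelope")) x$values else as.numeric(x)

#' EEG epoch container
#'
#' A channels-by-samples matrix with channel names and trial metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row. Defaults to
#'   `Ch01`, `Ch02`, ...
#' @param trial_id,snr_db,attended_id Optional trial metadata.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, channel_names = NULL, trial_id = NA,
                      snr_db = NA, attended_id = NA) {
  data <- as.matrix(data)
  if (anyNA(data) || !all(is.finite(data)))
    stop("EEG data must be finite with no NA", call. = FALSE)
  stop_if_not_scalar_num(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per data row", call. = FALSE)
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 trial_id = trial_id, snr_db = snr_db, attended_id = attended_id),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch%s> %d channels x %d samples @ %g Hz (%.2f s)\n",
              if (is.na(x$trial_id)) "" else paste0(" ", x$trial_id),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$snr_db)) cat(sprintf("  SNR %+g dB, attended '%s'\n",
                                    x$snr_db, x$attended_id))
  invisible(x)
}

as_eeg_matrix <- function(x) {
  if (inherits(x, "eeg_epoch")) return(x$data)
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, nrow = 1L))
  stop("expected an eeg_epoch or numeric matrix", call. = FALSE)
}

#' Drop the onset portion of a time series or EEG epoch
#'
#' Shared trimming used to discard the first second after mixture onset from
#' both the EEG and its aligned envelopes, so that stimulus and response are
#' always cut by the same rule and cannot drift by a sample.
#'
#' @param x An `eeg_epoch`, `envelope`, or numeric vector.
#' @param fs Sampling rate (taken from the object when it carries one).
#' @param t_drop Seconds to drop from the start (default 1).
#' @return Object of the same class, shortened.
#' @export
drop_onset <- function(x, fs = NULL, t_drop = 1) {
  if (inherits(x, "eeg_epoch")) {
    nd <- round(t_drop * x$fs)
    if (nd >= ncol(x$data)) stop("epoch shorter than the dropped onset", call. = FALSE)
    out <- x
    out$data <- x$data[, (nd + 1L):ncol(x$data), drop = FALSE]
    return(out)
  }
  if (inherits(x, "envelope")) {
    nd <- round(t_drop * x$fs)
    if (nd >= length(x$values)) stop("series shorter than the dropped onset", call. = FALSE)
    out <- x
    out$values <- x$values[(nd + 1L):length(x$values)]
    return(out)
  }
  w <- as_wave(x, fs)
  nd <- round(t_drop * w$fs)
  if (nd >= length(w$samples)) stop("series shorter than the dropped onset", call. = FALSE)
  w$samples[(nd + 1L):length(w$samples)]
}
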