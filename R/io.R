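# File I/O: a minimal mono RIFF/WAV reader-writer (PCM 16-bit and IEEE
# float32), and delimited-text + JSON-sidecar round-trips for EEG epochs and
# envelopes.

#' Write a mono WAV file
#'
#' @param wave An [audio_stimulus()] or numeric vector.
#' @param path Output path.
#' @param format `"float32"` (default; amplitudes stored as-is) or `"pcm16"`
#'   (amplitudes clipped to \[-1, 1\] and scaled to 16-bit integers).
#' @param fs Sampling rate for bare vectors.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, format = c("float32", "pcm16"), fs = NULL) {
  format <- match.arg(format)
  w <- as_wave(wave, fs)
  n <- length(w$samples)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_bytes <- n * bytes_per
  fmt_code <- if (format == "pcm16") 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(w$fs), con, size = 4, endian = "little")
  writeBin(as.integer(w$fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmax(-1, pmin(1, w$samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the PCM 16-bit and IEEE float32 encodings written by
#' [write_wav()].
#'
#' @param path Path to a WAV file.
#' @param id Identifier for the returned stimulus.
#' @return An [audio_stimulus()].
#' @export
read_wav <- function(path, id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt_code <- NULL; fs <- NULL; bits <- NULL; nch <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0L || nchar(tag) < 4L) stop("no data chunk", call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16L) readBin(con, raw(), n = sz - 16L)
    } else if (tag == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk", call. = FALSE)
      if (nch != 1L) stop("only mono WAV is supported", call. = FALSE)
      n <- sz %/% (bits %/% 8L)
      samples <- if (fmt_code == 1L && bits == 16L)
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32767
      else if (fmt_code == 3L && bits == 32L)
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      else stop("unsupported WAV encoding", call. = FALSE)
      return(audio_stimulus(samples, fs = fs, id = id))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}

#' Write an EEG epoch as delimited text plus a JSON sidecar
#'
#' Samples-by-channels TSV (`<prefix>.tsv`) plus `<prefix>.json` holding the
#' sampling rate, channel names, and trial labels.
#'
#' @param eeg An [eeg_epoch()].
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_eeg_text <- function(eeg, prefix) {
  stopifnot(inherits(eeg, "eeg_epoch"))
  utils::write.table(t(eeg$data), paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = eeg$channel_names,
                     quote = FALSE)
  meta <- list(fs = eeg$fs, channel_names = eeg$channel_names,
               trial_id = eeg$trial_id, snr_db = eeg$snr_db,
               attended_id = eeg$attended_id)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an EEG epoch written by [write_eeg_text()]
#'
#' @param prefix Path prefix used at write time.
#' @return An [eeg_epoch()].
#' @export
read_eeg_text <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE)
  eeg_epoch(t(as.matrix(tab)), fs = meta$fs, channel_names = meta$channel_names,
            trial_id = meta$trial_id %||% NA, snr_db = meta$snr_db %||% NA,
            attended_id = meta$attended_id %||% NA)
}

#' Write an envelope as delimited text plus a JSON sidecar
#'
#' @param env An [envelope()].
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_envelope_text <- function(env, prefix) {
  stopifnot(inherits(env, "envelope"))
  utils::write.table(data.frame(value = env$values), paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = env$fs, band = env$band,
                            variant = env$variant,
                            normalized = env$normalized),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an envelope written by [write_envelope_text()]
#'
#' @param prefix Path prefix used at write time.
#' @return An [envelope()].
#' @export
read_envelope_text <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE)
  envelope(tab$value, fs = meta$fs, band = meta$band, variant = meta$variant,
           normalized = meta$normalized)
}
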