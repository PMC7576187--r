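# Attended-speaker classification from reconstruction correlations, and
# accuracy aggregation over SNR conditions and decoding-window durations.

#' Pearson correlation with defensive checks
#'
#' Standard product-moment correlation; errors on unequal lengths, fewer than
#' three samples, or a constant input (where the correlation is undefined).
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("inputs differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  stats::cor(a, b)
}

#' Classify one decoding window
#'
#' The attended speaker is identified correctly when the reconstruction
#' correlates more strongly with the attended than with the ignored envelope;
#' an exact tie counts as incorrect (conservative).
#'
#' @param recon Reconstructed envelope segment.
#' @param att_env,ign_env Actual attended / ignored envelope segments
#'   (matching the decoder's training variant and band).
#' @return List with `r_attended`, `r_ignored`, `correct`.
#' @export
classify_window <- function(recon, att_env, ign_env) {
  recon <- as.numeric(recon)
  ra <- pearson_r(recon, env_values(att_env))
  ri <- pearson_r(recon, env_values(ign_env))
  list(r_attended = ra, r_ignored = ri, correct = ra > ri)
}

#' Chance level for an n-way classification
#'
#' @param n_classes Number of alternatives (default 2).
#' @return Expected accuracy under uniform guessing, `1 / n_classes`.
#' @export
chance_level <- function(n_classes = 2) {
  if (n_classes < 1) stop("`n_classes` must be >= 1", call. = FALSE)
  1 / n_classes
}

#' Decoding accuracy by SNR and window duration
#'
#' Splits every trial's leave-one-out reconstruction into consecutive
#' non-overlapping windows of each requested duration (remainder dropped),
#' classifies each window against the attended and ignored envelopes, and
#' pools window-level accuracy per SNR condition. A nominal duration at least
#' as long as the epoch (for example the "60 s" label on 59 s epochs after
#' onset exclusion) maps to the whole epoch as a single window.
#'
#' @param trials The `trial_set` that was decoded.
#' @param loo An `aad_loo` result from [loo_decode()]; computed at
#'   `lambda` when omitted.
#' @param durations_s Window durations in seconds (default `c(60, 30, 10, 2)`).
#' @param variants Variants to evaluate (default: those present in `loo`).
#' @param lambda Ridge parameter when `loo` is omitted.
#' @return Data frame with one row per (variant, duration, SNR):
#'   `variant`, `duration_s`, `snr_db`, `n_windows`, `n_correct`, `accuracy`,
#'   `mean_r_attended`, `mean_r_ignored`. Window-level detail is attached as
#'   attribute `"windows"`.
#' @export
evaluate_accuracy <- function(trials, loo = NULL,
                              durations_s = c(60, 30, 10, 2),
                              variants = NULL, lambda = 2^8) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  fs <- if (inherits(trials, "trial_set")) trials$fs else tl[[1]]$eeg$fs
  if (is.null(loo))
    loo <- loo_decode(trials, lambda = lambda,
                      variants = variants %||% "intact")
  variants <- variants %||% names(loo$variants)
  rows <- list(); wrows <- list()
  for (v in variants) {
    res <- loo$variants[[v]]
    if (is.null(res))
      stop(sprintf("variant '%s' was not decoded", v), call. = FALSE)
    for (d in durations_s) {
      for (i in seq_along(tl)) {
        shat <- res$reconstructions[[i]]
        n <- length(shat)
        att <- trial_env(tl[[i]], v, "attended")$values
        ign <- trial_env(tl[[i]], v, "ignored")$values
        win <- min(n, round(d * fs))
        nwin <- n %/% win
        for (k in seq_len(nwin)) {
          idx <- ((k - 1L) * win + 1L):(k * win)
          cl <- classify_window(shat[idx], att[idx], ign[idx])
          wrows[[length(wrows) + 1L]] <-
            data.frame(variant = v, duration_s = d, trial_id = tl[[i]]$trial_id,
                       snr_db = tl[[i]]$snr_db, window_index = k,
                       r_attended = cl$r_attended, r_ignored = cl$r_ignored,
                       correct = cl$correct, stringsAsFactors = FALSE)
        }
      }
    }
  }
  wins <- do.call(rbind, wrows)
  agg <- stats::aggregate(cbind(correct, r_attended, r_ignored) ~
                            variant + duration_s + snr_db,
                          data = wins, FUN = mean)
  cnt <- stats::aggregate(correct ~ variant + duration_s + snr_db,
                          data = wins, FUN = length)
  out <- data.frame(variant = agg$variant, duration_s = agg$duration_s,
                    snr_db = agg$snr_db, n_windows = cnt$correct,
                    n_correct = round(agg$correct * cnt$correct),
                    accuracy = agg$correct,
                    mean_r_attended = agg$r_attended,
                    mean_r_ignored = agg$r_ignored,
                    stringsAsFactors = FALSE)
  out <- out[order(out$variant, -out$duration_s, -out$snr_db), ]
  rownames(out) <- NULL
  attr(out, "windows") <- wins
  out
}

#' Pool an accuracy table over SNR conditions
#'
#' @param acc A table from [evaluate_accuracy()].
#' @return Data frame with one row per (variant, duration).
#' @export
pool_accuracy <- function(acc) {
  wins <- attr(acc, "windows")
  if (is.null(wins)) stop("accuracy table lacks window detail", call. = FALSE)
  agg <- stats::aggregate(correct ~ variant + duration_s, data = wins,
                          FUN = mean)
  cnt <- stats::aggregate(correct ~ variant + duration_s, data = wins,
                          FUN = length)
  data.frame(variant = agg$variant, duration_s = agg$duration_s,
             n_windows = cnt$correct,
             n_correct = round(agg$correct * cnt$correct),
             accuracy = agg$correct, stringsAsFactors = FALSE)
}
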