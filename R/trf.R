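# The temporal response function model: a lag-indexed linear mapping between
# a stimulus envelope and multichannel EEG, fit by ridge regression.
#
# Forward (encoding):  r(t, n) = sum_tau w(tau, n) s(t - tau) + eps(t, n)
# Backward (decoding): s_hat(t) = sum_n sum_tau r(t + tau, n) g(tau, n)
#
# Lags are expressed on the stimulus-relative axis in both directions: a
# positive lag means the EEG follows the stimulus. The backward design is
# therefore built with negated lags internally, while the stored lag grid
# stays on the conventional 0..400 ms decoder axis.

#' Fit a temporal response function by ridge regression
#'
#' The central model fit. `direction = "forward"` learns the encoding kernel
#' `w(tau, n)` predicting each EEG channel from the lagged stimulus envelope
#' (default lag window -200..800 ms). `direction = "backward"` learns the
#' decoder `g(tau, n)` reconstructing the envelope from all lagged EEG
#' channels (default 0..400 ms; the reconstruction at time `t` reads the EEG
#' at `t + tau`). Edges are zero-padded so fitted series keep the trial
#' length.
#'
#' @param stimulus Stimulus envelope: an [envelope()] or numeric vector.
#' @param response EEG: an [eeg_epoch()] or channels-by-samples matrix.
#' @param direction `"forward"` (encode) or `"backward"` (decode).
#' @param lambda Ridge parameter (default `2^8`, a typical cross-validated
#'   optimum for z-scored envelopes; tune with [loo_tune_lambda()]).
#' @param tmin_ms,tmax_ms Lag window; defaults depend on `direction`.
#' @param fs Sampling rate, required when neither input carries one.
#' @param bias Include an unpenalized intercept (default TRUE).
#' @param keep_data Store the training series in the object so that
#'   [fitted()], [residuals()] and training correlations can be recomputed
#'   (default TRUE; cross-validation internals switch it off).
#' @return An object of class `trf`: list with `weights` (inputs x lags x
#'   outputs array), `bias`, `lags_ms`, `lambda`, `direction`, `fs`,
#'   `channel_names`, training correlation `r_train`, and optionally `data`.
#' @seealso [predict.trf()], [reconstruct_envelope()], [trf_components()],
#'   [loo_tune_lambda()], [average_models()]
#' @export
trf <- function(stimulus, response, direction = c("forward", "backward"),
                lambda = 2^8, tmin_ms = NULL, tmax_ms = NULL, fs = NULL,
                bias = TRUE, keep_data = TRUE) {
  direction <- match.arg(direction)
  env_fs <- if (inherits(stimulus, "envelope")) stimulus$fs else NULL
  eeg_fs <- if (inherits(response, "eeg_epoch")) response$fs else NULL
  fs <- fs %||% env_fs %||% eeg_fs
  if (is.null(fs)) stop("`fs` must be supplied", call. = FALSE)
  if (!is.null(env_fs) && !is.null(eeg_fs) && env_fs != eeg_fs)
    stop("stimulus and response sampling rates differ", call. = FALSE)
  s <- env_values(stimulus)
  R <- as_eeg_matrix(response)
  ch_names <- if (inherits(response, "eeg_epoch")) response$channel_names
              else rownames(R) %||% sprintf("Ch%02d", seq_len(nrow(R)))
  if (length(s) != ncol(R))
    stop("stimulus and response must have the same number of samples",
         call. = FALSE)
  if (is.null(tmin_ms)) tmin_ms <- if (direction == "forward") -200 else 0
  if (is.null(tmax_ms)) tmax_ms <- if (direction == "forward") 800 else 400

  if (direction == "forward") {
    design <- lagged_design(s, tmin_ms, tmax_ms, fs, bias = bias)
    y <- t(R)
  } else {
    # s_hat(t) = sum r(t + tau) g(tau): design lag -tau on the EEG
    design <- lagged_design(t(R), -tmax_ms, -tmin_ms, fs, bias = bias)
    y <- matrix(s, ncol = 1L)
  }
  W <- ridge_solve(design, y, lambda)
  obj <- new_trf(W, design, direction, lambda, fs, ch_names,
                 tmin_ms, tmax_ms)
  pred <- design$X %*% W
  obj$r_train <- suppressWarnings(
    vapply(seq_len(ncol(y)), function(j) stats::cor(pred[, j], y[, j]),
           numeric(1)))
  if (direction == "forward") names(obj$r_train) <- ch_names
  if (keep_data) obj$data <- list(stimulus = s, response = R)
  obj
}

# Assemble a trf object from a flat weight matrix and its design metadata.
new_trf <- function(W, design, direction, lambda, fs, ch_names,
                    tmin_ms, tmax_ms) {
  p <- nrow(W)
  nl <- length(design$lags_ms)
  ni <- design$n_inputs
  bias_w <- if (design$bias) W[p, ] else numeric(ncol(W))
  core <- W[seq_len(ni * nl), , drop = FALSE]
  lags_ms <- seq(tmin_ms, tmax_ms, by = 1000 / fs)
  wts <- array(0, dim = c(ni, nl, ncol(W)))
  for (i in seq_len(ni))
    wts[i, , ] <- core[((i - 1L) * nl + 1L):(i * nl), , drop = FALSE]
  if (direction == "backward") {
    # design lags ran -tmax..-tmin; flip onto the 0..400 decoder axis
    wts <- wts[, rev(seq_len(nl)), , drop = FALSE]
  }
  inputs <- if (direction == "forward") "envelope" else ch_names
  outputs <- if (direction == "forward") ch_names else "envelope"
  dimnames(wts) <- list(inputs, sprintf("%g", lags_ms), outputs)
  structure(list(weights = wts, bias = as.numeric(bias_w), lags_ms = lags_ms,
                 lambda = lambda, direction = direction, fs = fs,
                 channel_names = ch_names, bias_included = design$bias,
                 r_train = NULL, data = NULL),
            class = "trf")
}

# Flat (inputs*lags [+bias]) x outputs weight matrix on the design axis.
trf_flat_weights <- function(object) {
  d <- dim(object$weights)
  wts <- object$weights
  if (object$direction == "backward")
    wts <- wts[, rev(seq_len(d[2])), , drop = FALSE]
  W <- matrix(0, d[1] * d[2] + as.integer(object$bias_included), d[3])
  for (i in seq_len(d[1]))
    W[((i - 1L) * d[2] + 1L):(i * d[2]), ] <- wts[i, , ]
  if (object$bias_included) W[nrow(W), ] <- object$bias
  W
}

# Design-axis lag window of a trf (ms), as used when it was fit.
trf_design_window <- function(object) {
  if (object$direction == "forward")
    c(min(object$lags_ms), max(object$lags_ms))
  else c(-max(object$lags_ms), -min(object$lags_ms))
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("Temporal response function (%s), %s\n", x$direction,
              if (x$direction == "forward") "envelope -> EEG" else "EEG -> envelope"))
  cat(sprintf("  lags %g..%g ms (%d), fs %g Hz, lambda %g, %d channel(s)\n",
              min(x$lags_ms), max(x$lags_ms), length(x$lags_ms), x$fs,
              x$lambda, length(x$channel_names)))
  if (!is.null(x$r_train))
    cat(sprintf("  training r: mean %.3f (range %.3f..%.3f)\n",
                mean(x$r_train), min(x$r_train), max(x$r_train)))
  invisible(x)
}

#' @export
summary.trf <- function(object, channel_set = NULL, ...) {
  comp <- NULL
  if (object$direction == "forward" &&
      min(object$lags_ms) <= 0 && max(object$lags_ms) >= 300) {
    comp <- tryCatch(trf_components(object, channel_set = channel_set),
                     error = function(e) NULL)
  }
  structure(list(model = object, components = comp), class = "summary.trf")
}

#' @export
print.summary.trf <- function(x, ...) {
  print(x$model)
  w <- x$model$weights
  cat(sprintf("  weight range [%.4g, %.4g], bias range [%.4g, %.4g]\n",
              min(w), max(w), min(x$model$bias), max(x$model$bias)))
  if (!is.null(x$components)) {
    cat("  TRF components (channel-set average):\n")
    print(x$components, row.names = FALSE)
  }
  invisible(x)
}

#' Model weights as an inputs x lags x outputs array
#'
#' @param object A [trf()] model.
#' @param drop Drop singleton dimensions (default TRUE): a forward model
#'   returns a lags-by-channels matrix, a backward model channels-by-lags.
#' @param ... Unused.
#' @return Numeric array or matrix of weights with lag dimnames in ms.
#' @export
coef.trf <- function(object, drop = TRUE, ...) {
  w <- object$weights
  if (!drop) return(w)
  if (object$direction == "forward") {
    out <- w[1, , , drop = TRUE]
    if (is.null(dim(out))) out <- matrix(out, ncol = 1,
                                         dimnames = list(dimnames(w)[[2]],
                                                         dimnames(w)[[3]]))
    out
  } else {
    out <- w[, , 1, drop = TRUE]
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(dimnames(w)[[1]],
                                                         dimnames(w)[[2]]))
    out
  }
}

#' Predict from a temporal response function
#'
#' Forward models map a stimulus envelope to predicted EEG (samples by
#' channels); backward models map EEG to a reconstructed envelope. Edges are
#' zero-padded, so predictions keep the input length.
#'
#' @param object A [trf()] model.
#' @param newdata Envelope (forward) or EEG epoch / channels-by-samples
#'   matrix (backward). Defaults to the stored training data.
#' @param ... Unused.
#' @return Samples-by-channels matrix (forward) or numeric vector (backward).
#' @export
predict.trf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data))
      stop("no stored training data; supply `newdata`", call. = FALSE)
    newdata <- if (object$direction == "forward") object$data$stimulus
               else object$data$response
  }
  win <- trf_design_window(object)
  if (object$direction == "forward") {
    if (inherits(newdata, "envelope") && newdata$fs != object$fs)
      stop("envelope sampling rate does not match the model", call. = FALSE)
    s <- env_values(newdata)
    design <- lagged_design(s, win[1], win[2], object$fs,
                            bias = object$bias_included)
  } else {
    if (inherits(newdata, "eeg_epoch")) {
      if (newdata$fs != object$fs)
        stop("EEG sampling rate does not match the model", call. = FALSE)
      if (!identical(newdata$channel_names, object$channel_names))
        stop("EEG channels do not match the decoder's channel set", call. = FALSE)
    }
    R <- as_eeg_matrix(newdata)
    if (nrow(R) != length(object$channel_names))
      stop("EEG channel count does not match the decoder", call. = FALSE)
    design <- lagged_design(t(R), win[1], win[2], object$fs,
                            bias = object$bias_included)
  }
  pred <- design$X %*% trf_flat_weights(object)
  if (object$direction == "backward") as.numeric(pred) else pred
}

#' @export
fitted.trf <- function(object, ...) predict(object)

#' @export
residuals.trf <- function(object, ...) {
  if (is.null(object$data))
    stop("model was fit with `keep_data = FALSE`", call. = FALSE)
  pred <- predict(object)
  if (object$direction == "forward") t(object$data$response) - pred
  else object$data$stimulus - pred
}

#' Predict EEG from a forward model and score it against recordings
#'
#' Convenience wrapper around [predict.trf()]: predicts every channel from the
#' envelope and, when the actual EEG is supplied, reports the per-channel
#' Pearson correlation plus its mean over a named channel set.
#'
#' @param model A forward [trf()] model.
#' @param env Stimulus envelope.
#' @param eeg Optional actual EEG ([eeg_epoch()] or matrix) to score against.
#' @param channel_set Channel names to average over (default: all).
#' @return List with `predicted` (samples x channels), and when `eeg` is
#'   given, `r` (per channel) and `r_mean` over `channel_set`.
#' @export
predict_eeg <- function(model, env, eeg = NULL, channel_set = NULL) {
  stopifnot(inherits(model, "trf"))
  if (model$direction != "forward")
    stop("`predict_eeg()` needs a forward model", call. = FALSE)
  pred <- predict(model, env)
  colnames(pred) <- model$channel_names
  out <- list(predicted = pred)
  if (!is.null(eeg)) {
    R <- as_eeg_matrix(eeg)
    if (ncol(R) != nrow(pred))
      stop("EEG length does not match the envelope", call. = FALSE)
    r <- vapply(seq_len(nrow(R)),
                function(i) stats::cor(pred[, i], R[i, ]), numeric(1))
    names(r) <- model$channel_names
    set <- channel_set %||% model$channel_names
    set <- intersect(set, model$channel_names)
    if (!length(set)) stop("empty channel set", call. = FALSE)
    out$r <- r
    out$r_mean <- mean(r[set])
  }
  out
}

#' Reconstruct a stimulus envelope from EEG with a backward decoder
#'
#' @param decoder A backward [trf()] model.
#' @param eeg [eeg_epoch()] or channels-by-samples matrix on the decoder's
#'   channel set.
#' @return Numeric reconstruction, one value per EEG sample.
#' @export
reconstruct_envelope <- function(decoder, eeg) {
  stopifnot(inherits(decoder, "trf"))
  if (decoder$direction != "backward")
    stop("`reconstruct_envelope()` needs a backward model", call. = FALSE)
  predict(decoder, eeg)
}

#' Average temporal response functions
#'
#' Elementwise mean of weights and bias across models with identical shape,
#' lag grid, and direction — the combination rule used by the leave-one-out
#' averaged-decoder scheme.
#'
#' @param models List of [trf()] models.
#' @return A [trf()] model (no stored data).
#' @export
average_models <- function(models) {
  if (!length(models)) stop("no models to average", call. = FALSE)
  ref <- models[[1]]
  for (m in models) {
    stopifnot(inherits(m, "trf"))
    if (!identical(dim(m$weights), dim(ref$weights)) ||
        !isTRUE(all.equal(m$lags_ms, ref$lags_ms)) ||
        !identical(m$direction, ref$direction))
      stop("models differ in shape, lag grid, or direction", call. = FALSE)
  }
  out <- ref
  out$weights <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  out$bias <- Reduce(`+`, lapply(models, `[[`, "bias")) / length(models)
  lam <- unique(vapply(models, `[[`, numeric(1), "lambda"))
  out$lambda <- if (length(lam) == 1L) lam else NA_real_
  out$r_train <- NULL
  out$data <- NULL
  out
}

#' Plot TRF weights against lag
#'
#' Butterfly plot of the lag profiles (one line per channel for forward
#' models, per input channel for backward models).
#'
#' @param x A [trf()] model.
#' @param channel_set Optional subset of channels to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trf <- function(x, channel_set = NULL, ...) {
  w <- if (x$direction == "forward") x$weights[1, , ] else t(x$weights[, , 1])
  if (is.null(dim(w))) w <- matrix(w, ncol = 1)
  colnames(w) <- x$channel_names
  if (!is.null(channel_set))
    w <- w[, intersect(channel_set, colnames(w)), drop = FALSE]
  graphics::matplot(x$lags_ms, w, type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "weight",
                    main = sprintf("%s TRF (lambda = %g)", x$direction,
                                   x$lambda), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Extract P1/N1/P2 TRF components
#'
#' Averages forward-model weights over a fronto-central channel set and reads
#' off the three canonical deflections in their lag windows: P1 and P2 are
#' the maxima in 80-110 ms and 230-300 ms, N1 the minimum in 150-180 ms. On a
#' flat profile the earliest lag of the window wins the tie.
#'
#' @param model A forward [trf()] whose lag grid covers 0-300 ms.
#' @param channel_set Channel names averaged before extraction (default
#'   [frontocentral_channels()] intersected with the model's channels; if the
#'   intersection is empty, all channels).
#' @param windows Named list of `c(lo, hi)` ms windows.
#' @return Data frame with one row per component: `component`, `amplitude`,
#'   `latency_ms`, `win_lo_ms`, `win_hi_ms`.
#' @export
trf_components <- function(model, channel_set = NULL,
                           windows = list(P1 = c(80, 110),
                                          N1 = c(150, 180),
                                          P2 = c(230, 300))) {
  stopifnot(inherits(model, "trf"))
  if (model$direction != "forward")
    stop("components are defined for forward models", call. = FALSE)
  for (wname in names(windows)) {
    wn <- windows[[wname]]
    if (min(model$lags_ms) > wn[1] || max(model$lags_ms) < wn[2])
      stop(sprintf("lag grid does not cover the %s window (%g-%g ms)",
                   wname, wn[1], wn[2]), call. = FALSE)
  }
  set <- channel_set %||% frontocentral_channels()
  set <- intersect(set, model$channel_names)
  if (!length(set)) set <- model$channel_names
  W <- model$weights[1, , , drop = TRUE]
  if (is.null(dim(W))) W <- matrix(W, ncol = 1,
                                   dimnames = list(NULL, model$channel_names))
  colnames(W) <- model$channel_names
  prof <- rowMeans(W[, set, drop = FALSE])
  rows <- lapply(names(windows), function(wname) {
    wn <- windows[[wname]]
    idx <- which(model$lags_ms >= wn[1] & model$lags_ms <= wn[2])
    vals <- prof[idx]
    k <- if (wname == "N1") which.min(vals) else which.max(vals)
    data.frame(component = wname, amplitude = vals[k],
               latency_ms = model$lags_ms[idx[k]],
               win_lo_ms = wn[1], win_hi_ms = wn[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "channel_set") <- set
  out
}
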