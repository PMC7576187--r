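# Leave-one-out machinery. Per-trial models are fit once from each trial's
# own Gram matrix and cross-products; the fold decoder for a held-out trial
# is the average of the other trials' models (sum of all minus the held-out
# one, divided by m - 1), so the whole scheme costs one factorization per
# trial per lambda regardless of the number of folds.

trial_env <- function(trial, variant, which = c("attended", "ignored")) {
  which <- match.arg(which)
  pair <- trial$env[[variant]]
  if (is.null(pair))
    stop(sprintf("trial '%s' has no '%s' envelopes", trial$trial_id, variant),
         call. = FALSE)
  pair[[which]]
}

# Build the backward design for one trial on the decoder lag window.
backward_design <- function(trial, tmin_ms, tmax_ms, fs) {
  lagged_design(t(trial$eeg$data), -tmax_ms, -tmin_ms, fs, bias = TRUE)
}

#' Leave-one-out decoding of a trial set
#'
#' Fits one backward decoder per trial at a fixed ridge parameter; each
#' held-out trial is then reconstructed with the elementwise average of the
#' other trials' decoders, and the reconstruction is correlated with the
#' attended and the ignored envelope. When several variants are requested the
#' expensive EEG Gram matrices are shared between them, so the code path is
#' identical and only the envelope inputs differ.
#'
#' @param trials A `trial_set` from [gen_dataset()] (or a compatible list).
#' @param lambda Ridge parameter.
#' @param variants Envelope variants to decode (default `"intact"`).
#' @param tmin_ms,tmax_ms Decoder lag window (default 0-400 ms).
#' @param verbose Print progress.
#' @return An object of class `aad_loo`: list of per-variant results, each
#'   with a data frame `scores` (`trial_id`, `snr_db`, `r_attended`,
#'   `r_ignored`, `correct`) and `reconstructions` (list of numeric series,
#'   one per trial), plus `lambda`, `fs`, and `durations` metadata.
#' @export
loo_decode <- function(trials, lambda = 2^8, variants = "intact",
                       tmin_ms = 0, tmax_ms = 400, verbose = FALSE) {
  stopifnot(inherits(trials, "trial_set") || is.list(trials))
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  m <- length(tl)
  if (m < 3L) stop("leave-one-out needs at least 3 trials", call. = FALSE)
  fs <- if (inherits(trials, "trial_set")) trials$fs else tl[[1]]$eeg$fs

  # pass 1: per-trial Gram + cross-products, one single-trial model per variant
  models <- lapply(variants, function(v) vector("list", m))
  names(models) <- variants
  grams <- vector("list", m)
  for (i in seq_len(m)) {
    if (verbose) message(sprintf("gram %d/%d", i, m))
    d <- backward_design(tl[[i]], tmin_ms, tmax_ms, fs)
    G <- crossprod(d$X)
    pen <- ridge_penalty(d, lambda)
    A <- G; diag(A) <- diag(A) + pen
    ch <- chol(A)
    for (v in variants) {
      y <- trial_env(tl[[i]], v, "attended")$values
      b <- crossprod(d$X, y)
      W <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
      models[[v]][[i]] <- new_trf(W, d, "backward", lambda, fs,
                                  tl[[i]]$eeg$channel_names, tmin_ms, tmax_ms)
    }
    grams[[i]] <- NULL
  }

  # pass 2: average-others decoder, reconstruct held-out, score
  out <- list()
  for (v in variants) {
    wsum <- Reduce(`+`, lapply(models[[v]], `[[`, "weights"))
    bsum <- Reduce(`+`, lapply(models[[v]], `[[`, "bias"))
    recs <- vector("list", m)
    rows <- vector("list", m)
    for (i in seq_len(m)) {
      dec <- models[[v]][[i]]
      dec$weights <- (wsum - models[[v]][[i]]$weights) / (m - 1)
      dec$bias <- (bsum - models[[v]][[i]]$bias) / (m - 1)
      shat <- reconstruct_envelope(dec, tl[[i]]$eeg)
      ra <- pearson_r(shat, trial_env(tl[[i]], v, "attended")$values)
      ri <- pearson_r(shat, trial_env(tl[[i]], v, "ignored")$values)
      recs[[i]] <- shat
      rows[[i]] <- data.frame(trial_id = tl[[i]]$trial_id,
                              snr_db = tl[[i]]$snr_db,
                              r_attended = ra, r_ignored = ri,
                              correct = ra > ri, stringsAsFactors = FALSE)
    }
    out[[v]] <- list(scores = do.call(rbind, rows), reconstructions = recs,
                     models = models[[v]])
  }
  structure(list(variants = out, lambda = lambda, fs = fs,
                 tmin_ms = tmin_ms, tmax_ms = tmax_ms),
            class = "aad_loo")
}

#' @export
print.aad_loo <- function(x, ...) {
  cat(sprintf("<aad_loo> lambda %g, lags %g..%g ms\n", x$lambda,
              x$tmin_ms, x$tmax_ms))
  for (v in names(x$variants)) {
    s <- x$variants[[v]]$scores
    cat(sprintf("  %s: mean r_att %.3f, mean r_ign %.3f, whole-epoch accuracy %.3f (n = %d)\n",
                v, mean(s$r_attended), mean(s$r_ignored), mean(s$correct),
                nrow(s)))
  }
  invisible(x)
}

#' Leave-one-out ridge-parameter tuning
#'
#' Sweeps a grid of ridge parameters (default `2^0, 2^2, ..., 2^12`). For
#' each candidate, one model is fit per trial; each fold's model is the
#' average of the other trials' models, evaluated on the held-out trial —
#' reconstruction correlation with the attended envelope for backward models,
#' mean predicted-EEG correlation over `channel_set` for forward models. The
#' winner maximizes the mean across folds (mean squared error is logged
#' alongside); one pooled optimum is returned for the whole dataset, and ties
#' go to the smallest candidate.
#'
#' @param trials A `trial_set` (or list of trials).
#' @param grid Candidate ridge parameters (default `2^seq(0, 12, 2)`).
#' @param direction `"backward"` (default) or `"forward"`.
#' @param variant Envelope variant used for fitting and scoring.
#' @param channel_set Channels averaged for the forward metric (default all).
#' @param tmin_ms,tmax_ms Lag window; defaults depend on `direction`.
#' @return An object of class `trf_cv`: list with `lambda` (the optimum),
#'   `table` (one row per candidate and fold: `lambda`, `fold`, `r`, `mse`),
#'   and `summary` (mean metric per candidate).
#' @export
loo_tune_lambda <- function(trials, grid = 2^seq(0, 12, 2),
                            direction = c("backward", "forward"),
                            variant = "intact", channel_set = NULL,
                            tmin_ms = NULL, tmax_ms = NULL) {
  direction <- match.arg(direction)
  if (!length(grid)) stop("empty ridge grid", call. = FALSE)
  grid <- sort(grid)
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  m <- length(tl)
  if (m < 3L) stop("leave-one-out needs at least 3 trials", call. = FALSE)
  fs <- if (inherits(trials, "trial_set")) trials$fs else tl[[1]]$eeg$fs
  if (is.null(tmin_ms)) tmin_ms <- if (direction == "forward") -200 else 0
  if (is.null(tmax_ms)) tmax_ms <- if (direction == "forward") 800 else 400

  # per-trial sufficient statistics, shared across the grid
  stats_i <- vector("list", m)
  for (i in seq_len(m)) {
    env_i <- trial_env(tl[[i]], variant, "attended")$values
    if (direction == "backward") {
      d <- backward_design(tl[[i]], tmin_ms, tmax_ms, fs)
      y <- matrix(env_i, ncol = 1L)
    } else {
      d <- lagged_design(env_i, tmin_ms, tmax_ms, fs, bias = TRUE)
      y <- t(tl[[i]]$eeg$data)
    }
    stats_i[[i]] <- list(G = crossprod(d$X), B = crossprod(d$X, y), design = d)
  }
  pen1 <- ridge_penalty(stats_i[[1]]$design, 1)  # unit pattern; scale by lambda

  rows <- list()
  for (lam in grid) {
    Ws <- lapply(stats_i, function(s)
      ridge_from_gram(s$G, s$B, pen1 * lam))
    Wsum <- Reduce(`+`, Ws)
    for (i in seq_len(m)) {
      Wavg <- (Wsum - Ws[[i]]) / (m - 1)
      pred <- stats_i[[i]]$design$X %*% Wavg
      if (direction == "backward") {
        actual <- trial_env(tl[[i]], variant, "attended")$values
        r <- pearson_r(as.numeric(pred), actual)
        mse <- mean((as.numeric(pred) - actual)^2)
      } else {
        actual <- t(tl[[i]]$eeg$data)
        set <- channel_set %||% tl[[i]]$eeg$channel_names
        ji <- match(intersect(set, tl[[i]]$eeg$channel_names),
                    tl[[i]]$eeg$channel_names)
        if (!length(ji)) stop("empty channel set", call. = FALSE)
        rv <- vapply(ji, function(j) stats::cor(pred[, j], actual[, j]),
                     numeric(1))
        r <- mean(rv)
        mse <- mean((pred[, ji] - actual[, ji])^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(lambda = lam, fold = i,
                                              r = r, mse = mse)
    }
  }
  tab <- do.call(rbind, rows)
  smry <- stats::aggregate(cbind(r, mse) ~ lambda, data = tab, FUN = mean)
  best <- smry$lambda[which.max(smry$r)]
  structure(list(lambda = best, table = tab, summary = smry,
                 direction = direction, variant = variant),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %s, variant %s: optimal lambda = %g\n",
              x$direction, x$variant, x$lambda))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit the fold-averaged forward TRF of a trial set
#'
#' One forward model per trial (attended envelope to EEG), averaged with
#' [average_models()] — the encoding-side analogue of the averaged decoder.
#'
#' @param trials A `trial_set`.
#' @param lambda Ridge parameter.
#' @param variant Envelope variant.
#' @param tmin_ms,tmax_ms Lag window (default -200..800 ms).
#' @return A forward [trf()] model.
#' @export
fit_forward_trf_set <- function(trials, lambda = 2^8, variant = "intact",
                                tmin_ms = -200, tmax_ms = 800) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  models <- lapply(tl, function(tr)
    trf(trial_env(tr, variant, "attended"), tr$eeg, direction = "forward",
        lambda = lambda, tmin_ms = tmin_ms, tmax_ms = tmax_ms,
        keep_data = FALSE))
  average_models(models)
}
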