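# Lagged design matrices and the ridge solver: the algebra underneath both
# the forward (encoding) and backward (decoding) temporal response functions.

#' Time-lagged design matrix
#'
#' Expands one or several input series into a matrix with one column per
#' (input, lag) pair. Using the forward convention, the sample at time `t` of
#' the lag-`tau` column holds the input at `t - tau`; indices falling outside
#' the series are zero-filled, so the row count always equals the sample
#' count. Columns are grouped by input (lags vary fastest); an all-ones bias
#' column is appended last when `bias = TRUE`.
#'
#' @param x Numeric vector, samples-by-inputs matrix, or [eeg_epoch()]
#'   (transposed internally to samples-by-channels).
#' @param tmin_ms,tmax_ms Lag window in milliseconds; both must sit on the
#'   sample grid (multiples of `1000/fs`).
#' @param fs Sampling rate in Hz.
#' @param bias Append an all-ones intercept column (default TRUE).
#' @return An object of class `lagged_design`: list with the matrix `X`,
#'   `lags_ms`, `fs`, `n_inputs`, `input_names`, and `bias`.
#' @export
lagged_design <- function(x, tmin_ms, tmax_ms, fs, bias = TRUE) {
  if (inherits(x, "eeg_epoch")) {
    fs <- x$fs
    input_names <- x$channel_names
    x <- t(x$data)
  } else {
    input_names <- NULL
  }
  if (is.vector(x)) x <- matrix(as.numeric(x), ncol = 1L)
  if (tmin_ms > tmax_ms) stop("`tmin_ms` must not exceed `tmax_ms`", call. = FALSE)
  step <- 1000 / fs
  for (v in c(tmin_ms, tmax_ms))
    if (abs(v / step - round(v / step)) > 1e-8)
      stop(sprintf("lag %g ms is not a multiple of the sample step %g ms",
                   v, step), call. = FALSE)
  lags_ms <- seq(tmin_ms, tmax_ms, by = step)
  lag_smp <- as.integer(round(lags_ms * fs / 1000))
  n <- nrow(x); ni <- ncol(x); nl <- length(lags_ms)
  X <- matrix(0, n, ni * nl + as.integer(bias))
  col <- 0L
  for (i in seq_len(ni)) {
    xi <- x[, i]
    for (l in seq_len(nl)) {
      col <- col + 1L
      tau <- lag_smp[l]
      if (tau >= 0L) {
        if (tau < n) X[(tau + 1L):n, col] <- xi[seq_len(n - tau)]
      } else {
        if (-tau < n) X[seq_len(n + tau), col] <- xi[(1L - tau):n]
      }
    }
  }
  if (bias) X[, ncol(X)] <- 1
  structure(list(X = X, lags_ms = lags_ms, fs = fs, n_inputs = ni,
                 input_names = input_names, bias = bias),
            class = "lagged_design")
}

# Penalty vector for a design: lambda on every weight column, 0 on the bias.
ridge_penalty <- function(design, lambda) {
  p <- ncol(design$X)
  pen <- rep(lambda, p)
  if (design$bias) pen[p] <- 0
  pen
}

# Solve (G + diag(pen)) w = b by Cholesky; G = X'X, b = X'y.
ridge_from_gram <- function(G, b, pen) {
  A <- G
  diag(A) <- diag(A) + pen
  ch <- tryCatch(chol(A), error = function(e) NULL)
  # an unpenalized rank-deficient system can slip through chol() with a tiny
  # trailing pivot; treat that as singular too
  if (is.null(ch) ||
      (all(pen == 0) && min(diag(ch)) < 1e-7 * max(diag(ch))))
    stop("normal equations are singular; use a ridge parameter lambda > 0",
         call. = FALSE)
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

#' Ridge regression on a lagged design
#'
#' Closed-form normal-equations solution of
#' `argmin ||y - X w||^2 + lambda ||w||^2`, with the bias column (when
#' present) left unpenalized.
#'
#' @param design A [lagged_design()].
#' @param y Target vector or samples-by-outputs matrix.
#' @param lambda Ridge parameter, `>= 0`. A singular system at `lambda = 0`
#'   is an error suggesting `lambda > 0`.
#' @return Weight matrix, `ncol(X)` by `n_outputs`.
#' @export
ridge_solve <- function(design, y, lambda) {
  stopifnot(inherits(design, "lagged_design"))
  if (!is.matrix(y)) y <- matrix(as.numeric(y), ncol = 1L)
  if (nrow(y) != nrow(design$X))
    stop("`y` must have one row per design row", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a single number >= 0", call. = FALSE)
  ridge_from_gram(crossprod(design$X), crossprod(design$X, y),
                  ridge_penalty(design, lambda))
}
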