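# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the caller's stream, so seeded generators never perturb user code.
#' With `seed = NULL` the current stream is used (and advanced).
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Root-mean-square of a numeric vector.
rms <- function(x) sqrt(mean(x^2))

# Analytic signal via the frequency-domain construction: double the
# positive-frequency half of the spectrum, zero the negative half.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = numeric(n)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Fourier-domain resampling to n_out samples: truncate (or zero-extend) the
# spectrum and invert at the new length. Exact for signals band-limited below
# the output Nyquist; the truncation is an ideal anti-alias low-pass.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  m <- min(n, n_out)
  kpos <- floor(m / 2) + 1L            # bins 0 .. floor(m/2)
  Y[seq_len(kpos)] <- X[seq_len(kpos)]
  kneg <- m - kpos                     # strictly negative-frequency bins
  if (kneg > 0L)
    Y[(n_out - kneg + 1L):n_out] <- X[(n - kneg + 1L):n]
  if (m %% 2L == 0L) {
    # shared Nyquist bin: keep it real so the output stays real; when
    # upsampling, split it between the two mirrored bins
    if (n_out > n) {
      Y[kpos] <- complex(real = Re(X[kpos]) / 2, imaginary = 0)
      Y[n_out - kpos + 2L] <- Y[kpos]
    } else {
      Y[kpos] <- complex(real = Re(X[kpos]), imaginary = 0)
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Linear convolution by FFT; returns the full length(x) + length(b) - 1 result.
conv_full <- function(x, b) {
  n <- length(x) + length(b) - 1L
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  y <- stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                  stats::fft(c(b, numeric(nf - length(b)))), inverse = TRUE)
  Re(y[seq_len(n)]) / nf
}

# Zero-phase application of a symmetric (linear-phase) FIR: full convolution
# with the group delay removed. Exact zero phase for even-order symmetric taps.
fir_zerophase <- function(x, b) {
  d <- (length(b) - 1L) %/% 2L
  conv_full(x, b)[(d + 1L):(d + length(x))]
}

# Forward-backward FIR filtering with mirror padding (three filter lengths at
# each end) so start-up transients die out inside the padding rather than in
# the data. Zero net phase; the magnitude response is applied twice.
fir_filtfilt <- function(b, x) {
  b <- as.numeric(b)
  n <- length(x)
  np <- min(n - 1L, 3L * length(b))
  pre <- 2 * x[1] - x[(np + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- as.numeric(signal::filter(b, 1, c(pre, x, post)))
  y <- rev(as.numeric(signal::filter(b, 1, rev(y))))
  y[(np + 1L):(np + n)]
}

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
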