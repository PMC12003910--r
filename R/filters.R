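# Zero-phase FIR filtering primitives shared by the synthetic generator and
# the preprocessing chain. Kernels are linear-phase windowed-sinc (Hamming)
# designs; because they are symmetric, a single FFT convolution with
# group-delay compensation is exactly zero-phase. Edge effects are handled
# by reflection padding of one kernel length at each end.

#' Design a windowed-sinc band-pass kernel
#'
#' Hamming-windowed sinc FIR design. Transition bandwidth follows the
#' convention `min(max(0.25 * edge, 2), room)` Hz at each edge (where `room`
#' is the distance to DC or Nyquist), and kernel length is
#' `3.3 * srate / min(transition)` rounded up to odd. Pass `low = NULL` or
#' `high = NULL` for pure low-/high-pass designs.
#'
#' @param low,high Band edges in Hz.
#' @param srate Sampling rate in Hz.
#' @return Numeric kernel (odd length, symmetric, unit DC-band gain).
#' @export
design_fir <- function(low, high, srate) {
  nyq <- srate / 2
  if (!is.null(high) && high >= nyq) stop("`high` must be below Nyquist")
  tbw <- c(
    if (!is.null(low)) min(max(0.25 * low, 2), low),
    if (!is.null(high)) min(max(0.25 * high, 2), nyq - high)
  )
  n_taps <- ceiling(3.3 * srate / min(tbw))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  t_idx <- -m:m
  sinc_lp <- function(fc) {
    # ideal lowpass with cutoff fc (Hz), sampled impulse response
    x <- 2 * fc / srate * sinc_fn(2 * fc / srate * t_idx)
    x
  }
  win <- 0.54 + 0.46 * cos(pi * t_idx / m)  # Hamming
  h <- if (is.null(low)) {
    sinc_lp(high + tbw[1] / 2)
  } else if (is.null(high)) {
    hp <- -sinc_lp(low - tbw[1] / 2)
    hp[m + 1] <- hp[m + 1] + 1
    hp
  } else {
    sinc_lp(high + tbw[2] / 2) - sinc_lp(low - tbw[1] / 2)
  }
  h <- h * win
  # normalize passband gain at the band center (or DC for lowpass)
  f0 <- if (is.null(low)) 0 else if (is.null(high)) nyq
        else sqrt(low * high)
  gain <- abs(sum(h * exp(-2i * pi * f0 / srate * t_idx)))
  h / gain
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase filter the columns of a matrix
#'
#' Applies a symmetric FIR kernel to every column with reflection padding
#' and FFT convolution, compensating the group delay so the output is
#' zero-phase and the same length as the input.
#'
#' @param x Numeric matrix (samples in rows, signals in columns) or vector.
#' @param kernel Symmetric odd-length FIR kernel from [design_fir()].
#' @return Filtered object of the same shape.
#' @export
filter_zero_phase <- function(x, kernel) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  m <- (length(kernel) - 1L) / 2L
  pad <- min(n - 1L, length(kernel))
  # reflection padding (about the end samples)
  top <- x[rev(seq_len(pad) + 1L), , drop = FALSE]
  bot <- x[n - seq_len(pad), , drop = FALSE]
  xp <- rbind(2 * x[rep(1L, pad), , drop = FALSE] - top,
              x,
              2 * x[rep(n, pad), , drop = FALSE] - bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(kernel) - 1L, c(2, 3, 5))
  K <- stats::fft(c(kernel, rep(0, nfft - length(kernel))))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(X * K, inverse = TRUE)) / nfft
  # kernel delay m plus padding offset
  out <- y[pad + m + seq_len(n), , drop = FALSE]
  if (vec_in) drop(out) else out
}

#' Envelope of the analytic signal
#'
#' Magnitude of the FFT-based analytic signal (Hilbert envelope), applied
#' column-wise.
#'
#' @param x Numeric matrix (samples x signals) or vector.
#' @return Envelope, same shape as `x`.
#' @export
analytic_envelope <- function(x) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  env <- Mod(stats::mvfft(X, inverse = TRUE)) / n
  if (vec_in) drop(env) else env
}

#' 1/f-shaped Gaussian noise
#'
#' Generates columns of noise whose power spectrum follows `1/f^gamma`
#' over the positive frequencies, scaled to a target standard deviation.
#' Used as the broadband EEG background.
#'
#' @param n_samples Samples per signal.
#' @param n_signals Number of independent columns.
#' @param srate Sampling rate (Hz).
#' @param gamma Spectral exponent (default 1).
#' @param sd Target overall standard deviation (default 1).
#' @return `n_samples x n_signals` matrix.
#' @export
colored_noise <- function(n_samples, n_signals = 1L, srate = 250,
                          gamma = 1, sd = 1) {
  n <- n_samples
  freqs <- seq(0, srate, length.out = n + 1L)[seq_len(n)]
  freqs[freqs > srate / 2] <- srate - freqs[freqs > srate / 2]
  scale <- c(0, 1 / freqs[-1]^(gamma / 2))
  w <- matrix(stats::rnorm(n * n_signals), n, n_signals)
  X <- stats::mvfft(w) * scale
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  x * (sd / stats::sd(as.vector(x)))
}
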