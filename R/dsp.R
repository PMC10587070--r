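# Low-level signal-processing primitives shared by the acoustic and LFP
# modules: analytic signal, zero-phase band-pass filtering with edge
# padding, 1/f noise, von Mises sampling, and deterministic seed
# substreams.

#' Derive a deterministic substream seed
#'
#' A single master seed spawns independent named substreams so that, e.g.,
#' the spike generator can be re-run without touching the LFP noise draws.
#'
#' @param seed Integer master seed.
#' @param name Character tag of the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

#' Analytic signal via the FFT half-spectrum method
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform; the modulus is
#' the instantaneous amplitude envelope and the argument the instantaneous
#' phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1)
  n <- length(x)
  # pad to a 2-3-5-smooth length: R's mixed-radix FFT degrades to O(N^2)
  # on lengths with large prime factors.  The tail is reflected so the
  # seam is smooth; the pad is discarded.
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- if (m > n) c(x, rev(x[(n - (m - n) + 1):n])) else x
  X <- stats::fft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1, m / 2 + 1)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) so the
#' output has no group delay.  One second of reflected data is prepended and
#' appended before filtering to suppress end transients, then trimmed.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 numeric `(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param order Filter order (default 4).
#' @param pad_s Reflection padding in seconds (default 1).
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, band, order = 4, pad_s = 1) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop("band upper edge ", band[2], " Hz is at or above Nyquist (fs = ",
         fs, " Hz)")
  }
  np <- min(length(x) - 1, round(pad_s * fs))
  xp <- c(rev(x[seq_len(np) + 1]), x, rev(x[length(x) - seq_len(np)]))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(np + length(x))]
}

#' Instantaneous band-limited amplitude envelope
#'
#' @inheritParams bandpass
#' @return Non-negative envelope vector.
#' @export
band_envelope <- function(x, fs, band, order = 4) {
  Mod(analytic_signal(bandpass(x, fs, band, order = order)))
}

#' 1/f (pink) background noise
#'
#' Spectral-shaping method: white Gaussian Fourier coefficients scaled by
#' `1/sqrt(f)`, inverse transformed, and rescaled to a target RMS.  The DC
#' component is zero.
#'
#' @param n Number of samples.
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, rms = 1) {
  stopifnot(n > 8)
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))  # FFT-friendly length; truncate after
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp * stats::rnorm(nf, 1, 0.2), argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
    full[nf + 1] <- complex(real = Re(spec[nf]))
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n_out)] / n
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

#' Wrap angles to [-pi, pi)
#' @param x Numeric vector of angles (radians).
#' @return Wrapped angles.
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.  `kappa = 0` reduces to the
#' circular uniform; very large `kappa` (> 1e6) returns the mean exactly.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `kappa >= 0`.
#' @return Angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  if (kappa > 1e6) return(wrap_phase(rep(mu, n)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    m <- max(16, 2 * (n - i))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- f[ok]
    sgn <- sign(u3[ok] - 0.5)
    take <- min(length(acc), n - i)
    if (take > 0) {
      out[(i + 1):(i + take)] <- sgn[seq_len(take)] * acos(acc[seq_len(take)])
      i <- i + take
    }
  }
  wrap_phase(out + mu)
}

#' Block-mean downsampling
#'
#' Averages non-overlapping blocks of `factor` samples; a trailing partial
#' block is dropped.  Used to take 1 kHz power traces to 200 Hz and 200 Hz
#' profiles to 10 Hz.
#'
#' @param x Numeric vector.
#' @param factor Integer decimation factor.
#' @return Vector of length `floor(length(x) / factor)`.
#' @export
block_mean <- function(x, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  nb <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(nb * factor)], nrow = factor))
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
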