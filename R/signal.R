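# Low-level spectral primitives shared by the simulator, the Welch PSD and the
# AEC connectivity code. All filters are zero-phase FFT masks with
# raised-cosine transition edges; stop-band rejection is effectively complete
# well inside one octave of the passband.

fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Raised-cosine transition mask on |f|: 0 below lo - tw, 1 above lo + tw (and
# symmetrically at the upper edge). `lo = NULL` gives a lowpass, `hi = NULL` a
# highpass. DC is always removed for band/highpass masks.
fft_band_mask <- function(n, fs, lo = NULL, hi = NULL, transition = NULL) {
  f <- abs(fft_freqs(n, fs))
  m <- rep(1, n)
  ramp <- function(x, lo_edge, hi_edge) {
    out <- (x - lo_edge) / (hi_edge - lo_edge)
    0.5 - 0.5 * cos(pi * pmin(pmax(out, 0), 1))
  }
  if (!is.null(lo)) {
    tw <- if (is.null(transition)) max(0.25, 0.15 * lo) else transition
    m <- m * ramp(f, lo - tw, lo + tw)
    m[f == 0] <- 0
  }
  if (!is.null(hi)) {
    tw <- if (is.null(transition)) max(0.25, 0.15 * hi) else transition
    m <- m * (1 - ramp(f, hi - tw, hi + tw))
  }
  m
}

# Zero-phase band-pass of a samples x channels matrix (or vector).
fft_filter <- function(x, fs, lo = NULL, hi = NULL, transition = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  m <- fft_band_mask(n, fs, lo, hi, transition)
  y <- Re(stats::mvfft(stats::mvfft(x) * m, inverse = TRUE)) / n
  if (vec) drop(y) else y
}

#' Zero-phase band-pass filter
#'
#' Filters ROI time series into a frequency band with a zero-phase spectral
#' mask (raised-cosine transitions). Out-of-band components one octave outside
#' the passband are suppressed by far more than 40 dB, and DC is removed.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param band Band name (see [meg_bands()]) or a one-row band tibble.
#' @param fs Sampling rate, Hz.
#' @param bands Band table used to resolve `band` names.
#' @return Filtered series with the shape of `x`.
#' @export
bandpass <- function(x, band, fs, bands = meg_bands()) {
  b <- resolve_band(band, bands)
  if (b$hi >= fs / 2) {
    stopf("band '%s' (hi = %g Hz) is not below the Nyquist frequency %g Hz",
          b$band, b$hi, fs / 2)
  }
  fft_filter(x, fs, lo = b$lo, hi = b$hi)
}

#' Analytic-signal amplitude envelope
#'
#' Returns the magnitude of the analytic (Hilbert) signal of a band-limited
#' series: for a sinusoid of amplitude A the envelope is approximately A away
#' from the record edges.
#'
#' @param x Numeric vector or samples-by-channels matrix (band-limited).
#' @return Non-negative envelope with the shape of `x`.
#' @export
analytic_envelope <- function(x) {
  Mod(analytic_signal(x))
}

# Complex analytic signal via the frequency-domain construction.
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  if (vec) drop(a) else a
}

# Low-pass smooth an envelope (keeping its DC level) and decimate it to about
# four samples per cycle of the cutoff; returns the (possibly shorter) series.
smooth_envelope <- function(env, fs, cutoff = 1, downsample = TRUE) {
  vec <- is.null(dim(env))
  if (vec) env <- matrix(env, ncol = 1)
  n <- nrow(env)
  m <- fft_band_mask(n, fs, lo = NULL, hi = cutoff)
  sm <- Re(stats::mvfft(stats::mvfft(env) * m, inverse = TRUE)) / n
  if (downsample) {
    step <- max(1L, floor(fs / (4 * cutoff)))
    sm <- sm[seq(1L, n, by = step), , drop = FALSE]
  }
  if (vec) drop(sm) else sm
}

# 1/f^exponent "pink" background noise, unit variance.
pink_noise <- function(n, exponent = 1, fs = 1) {
  f <- abs(fft_freqs(n, fs))
  amp <- ifelse(f > 0, f^(-exponent / 2), 0)
  spec <- amp * complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Slow positive random envelope: low-pass-filtered Gaussian noise (unit sd)
# mapped through exp(sigma * z); strictly positive, fluctuations below `cutoff`.
slow_envelope <- function(n, fs, cutoff = 0.5, sigma = 0.4) {
  z <- stats::rnorm(n)
  m <- fft_band_mask(n, fs, lo = NULL, hi = cutoff)
  zs <- Re(stats::fft(stats::fft(z) * m, inverse = TRUE)) / n
  s <- stats::sd(zs)
  if (s > 0) zs <- zs / s
  exp(sigma * zs)
}
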