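#' Welch power spectral density of a recording
#'
#' Computes the one-sided Welch PSD of every ROI channel per epoch (windowed,
#' overlapping segments, periodograms averaged) and then averages across
#' epochs, giving one spectrum per ROI. Defaults: 2-s Hann segments with 50%
#' overlap, demeaned per segment, giving 0.5 Hz resolution so the 1--3 Hz
#' delta band spans several bins.
#'
#' @param recording A `meg_recording` (see [simulate_subject()]).
#' @param nperseg Segment length in samples (default `2 * fs`).
#' @param overlap_frac Fractional overlap between segments, in `[0, 1)`.
#' @param window Taper: `"hann"` or `"rect"`.
#' @return A `meg_psd`: list with `freqs` (Hz), `density` (freqs x regions
#'   matrix, power per Hz), `fs`, `n_epochs_averaged`, `subject_id`.
#' @export
welch_psd <- function(recording, nperseg = NULL, overlap_frac = 0.5,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  fs <- recording$fs
  n <- nrow(recording$epochs[[1]])
  if (is.null(nperseg)) nperseg <- min(n, round(2 * fs))
  nperseg <- as.integer(nperseg)
  if (nperseg > n) stopf("nperseg (%d) exceeds the epoch length (%d samples)", nperseg, n)
  if (overlap_frac < 0 || overlap_frac >= 1) stopf("overlap_frac must be in [0, 1)")
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)  # periodic Hann
  } else {
    rep(1, nperseg)
  }
  step <- max(1L, as.integer(round(nperseg * (1 - overlap_frac))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nfreq <- nperseg %/% 2 + 1L
  scale <- 1 / (fs * sum(w^2))
  acc <- matrix(0, nfreq, ncol(recording$epochs[[1]]))
  nseg <- 0L
  for (ep in recording$epochs) {
    for (s in starts) {
      seg <- ep[s:(s + nperseg - 1L), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg)) * w
      p <- Mod(stats::mvfft(seg))^2 * scale
      p <- p[seq_len(nfreq), , drop = FALSE]
      if (nperseg %% 2 == 0) {
        p[2:(nfreq - 1L), ] <- 2 * p[2:(nfreq - 1L), ]
      } else {
        p[2:nfreq, ] <- 2 * p[2:nfreq, ]
      }
      acc <- acc + p
      nseg <- nseg + 1L
    }
  }
  structure(list(
    freqs = (seq_len(nfreq) - 1) * fs / nperseg,
    density = acc / nseg,
    fs = fs,
    n_epochs_averaged = length(recording$epochs),
    subject_id = recording$subject_id
  ), class = "meg_psd")
}

#' Band-integrated power per ROI
#'
#' Trapezoidal integral of the PSD over `[lo, hi]`, one value per ROI.
#'
#' @param psd A `meg_psd` from [welch_psd()].
#' @param band Band name or one-row band tibble.
#' @param bands Band table for name resolution.
#' @return Tibble with `region` (1-based index) and `power` (non-negative).
#' @export
band_power <- function(psd, band, bands = meg_bands()) {
  b <- resolve_band(band, bands)
  if (b$hi > max(psd$freqs) + 1e-9) {
    stopf("band '%s' extends beyond the PSD frequency range (max %g Hz)",
          b$band, max(psd$freqs))
  }
  keep <- psd$freqs >= b$lo & psd$freqs <= b$hi
  if (sum(keep) < 2) stopf("band '%s' covers fewer than two frequency bins", b$band)
  f <- psd$freqs[keep]
  d <- psd$density[keep, , drop = FALSE]
  df <- diff(f)
  p <- as.numeric(crossprod(c(df / 2, 0) + c(0, df / 2), d))
  tibble::tibble(region = seq_len(ncol(psd$density)), power = p)
}

#' Regional band-power feature matrix
#'
#' For every subject and requested band, the band-integrated Welch power of
#' each ROI. Power features are log10-transformed by default to tame the
#' right-skew of absolute band power.
#'
#' @param cohort A `meg_cohort`, or a list of `meg_recording`s.
#' @param bands Band table (default: the cohort's configured bands).
#' @param log10 Log-transform the band powers?
#' @param ... Passed to [welch_psd()].
#' @return Tibble: `subject_id`, `group`, then one `pow_<band>_<roi>` column
#'   per band and ROI (90 per band at the canonical atlas size).
#' @export
power_features <- function(cohort, bands = NULL, log10 = TRUE, ...) {
  subjects <- if (inherits(cohort, "meg_cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stopf("empty cohort")
  if (is.null(bands)) {
    bands <- if (inherits(cohort, "meg_cohort")) cohort$config$bands else meg_bands()
  }
  dims <- vapply(subjects, function(s) c(s$fs, ncol(s$epochs[[1]])), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all subjects must share the sampling rate and region count")
  }
  rows <- purrr::map(subjects, function(s) {
    psd <- welch_psd(s, ...)
    vals <- purrr::map(seq_len(nrow(bands)), function(bi) {
      bp <- band_power(psd, bands[bi, ])$power
      if (log10) bp <- base::log10(pmax(bp, .Machine$double.xmin))
      stats::setNames(bp, sprintf("pow_%s_%03d", bands$band[bi], seq_along(bp)))
    })
    c(list(subject_id = s$subject_id, group = s$group),
      as.list(unlist(vals)))
  })
  dplyr::bind_rows(rows)
}
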