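#' Residualise one series on another
#'
#' Removes the zero-lag linear component of `x` from `y` (regression with
#' intercept), so the returned series has zero sample correlation with `x`.
#' Used for leakage correction before envelope correlation: source
#' reconstruction mixes signals at zero lag, and orthogonalisation removes the
#' spurious connectivity that mixing induces. A constant `x` leaves `y`
#' unchanged (there is nothing to regress out).
#'
#' @param x,y Equal-length numeric vectors.
#' @return `y` residualised on `x`.
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss <= .Machine$double.eps * length(x)) return(y)
  b <- sum(xc * y) / ss
  y - (mean(y) - b * mean(x)) - b * x   # full OLS residual: y = x gives 0
}

#' Amplitude envelope correlation connectome
#'
#' Computes the band-limited AEC matrix of one recording. Per epoch the
#' channels are band-pass filtered, optionally pairwise-orthogonalised
#' (symmetrically: both directions, averaged), the amplitude envelopes taken
#' as the analytic-signal magnitude, optionally low-pass smoothed and
#' decimated (envelope dynamics at rest are slow), and Pearson-correlated for
#' every ROI pair. Epoch (and direction) averaging is done on the Fisher z
#' scale and back-transformed, so the stored values are correlations.
#'
#' @param recording A `meg_recording`.
#' @param band Band name or one-row band tibble.
#' @param leakage_correction Apply symmetric pairwise orthogonalisation
#'   (default TRUE). With correction a signal's AEC with a copy of itself is
#'   ~0; without, ~1.
#' @param env_smooth Envelope low-pass cutoff in Hz before correlation
#'   (with decimation to ~4 samples per cutoff cycle); `NULL` correlates the
#'   raw envelopes.
#' @param bands Band table for name resolution.
#' @return A `meg_aec`: the regions-by-regions symmetric correlation matrix
#'   (diagonal `NA`) with attributes `band` and `subject_id`.
#' @export
aec_matrix <- function(recording, band, leakage_correction = TRUE,
                       env_smooth = 1, bands = meg_bands()) {
  b <- resolve_band(band, bands)
  fs <- recording$fs
  nreg <- ncol(recording$epochs[[1]])
  if (nrow(recording$epochs[[1]]) < 8) stopf("epochs are too short for envelope correlation")
  zclip <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  prep_env <- function(E) {
    if (is.null(env_smooth)) E else smooth_envelope(E, fs, env_smooth, downsample = TRUE)
  }
  safe_cor <- function(...) {
    r <- suppressWarnings(stats::cor(...))
    r[!is.finite(r)] <- 0
    r
  }
  zacc <- matrix(0, nreg, nreg)
  for (ep in recording$epochs) {
    X <- bandpass(ep, b, fs)
    A <- analytic_signal(X)
    Es <- prep_env(Mod(A))
    if (!leakage_correction) {
      z <- zclip(safe_cor(Es))
    } else {
      G <- crossprod(X)
      D <- matrix(0, nreg, nreg)
      for (i in seq_len(nreg)) {
        bi <- if (G[i, i] > .Machine$double.eps) G[i, ] / G[i, i] else numeric(nreg)
        Ares <- A - A[, i] %*% t(bi)            # residual of every channel on i
        Eres <- prep_env(Mod(Ares))
        D[i, ] <- safe_cor(Eres, Es[, i])       # corr(env(resid j|i), env i)
      }
      z <- (zclip(D) + t(zclip(D))) / 2         # symmetrise the two directions
    }
    zacc <- zacc + z
  }
  out <- tanh(zacc / length(recording$epochs))
  diag(out) <- NA_real_
  structure(out, class = c("meg_aec", class(out)),
            band = b$band, subject_id = recording$subject_id)
}

#' Canonical edge vectorisation of a connectome
#'
#' Unpacks a symmetric regions-by-regions matrix into its upper-triangle edges
#' in canonical row-major order (`i < j`); 90 regions give the canonical
#' 4005-edge vector. `edges_to_matrix()` is the lossless inverse.
#'
#' @param mat Symmetric numeric matrix (class `meg_aec` or plain).
#' @param band Band label used in the edge names (taken from a `meg_aec`
#'   attribute when absent).
#' @param tol Symmetry tolerance.
#' @return Tibble with `feature` (`aec_<band>_<i>_<j>`), `roi_i`, `roi_j`,
#'   `value`, in canonical order.
#' @export
vectorize_edges <- function(mat, band = NULL, tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) stopf("`mat` must be square")
  if (is.null(band)) band <- attr(mat, "band") %||% "band"
  off <- abs(mat - t(mat))
  if (max(off[is.finite(off)], 0) > tol) stopf("matrix is asymmetric beyond tolerance")
  n <- nrow(mat)
  ij <- which(upper.tri(mat), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tibble::tibble(
    feature = sprintf("aec_%s_%03d_%03d", band, ij[, 1], ij[, 2]),
    roi_i = as.integer(ij[, 1]), roi_j = as.integer(ij[, 2]),
    value = mat[ij]
  )
}

#' @rdname vectorize_edges
#' @param edges Tibble from [vectorize_edges()].
#' @param n_regions Matrix dimension; inferred from the largest index if NULL.
#' @export
edges_to_matrix <- function(edges, n_regions = NULL) {
  if (is.null(n_regions)) n_regions <- max(edges$roi_j)
  m <- matrix(NA_real_, n_regions, n_regions)
  m[cbind(edges$roi_i, edges$roi_j)] <- edges$value
  m[cbind(edges$roi_j, edges$roi_i)] <- edges$value
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' AEC edge feature matrix for a cohort
#'
#' One [aec_matrix()] per subject and band, vectorised into canonical edge
#' features (4005 per band at the 90-region atlas size).
#'
#' @inheritParams power_features
#' @param leakage_correction,env_smooth Passed to [aec_matrix()].
#' @return Tibble: `subject_id`, `group`, then `aec_<band>_<i>_<j>` columns.
#' @export
aec_features <- function(cohort, bands = NULL, leakage_correction = TRUE,
                         env_smooth = 1) {
  subjects <- if (inherits(cohort, "meg_cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stopf("empty cohort")
  if (is.null(bands)) {
    bands <- if (inherits(cohort, "meg_cohort")) cohort$config$bands else meg_bands()
  }
  rows <- purrr::map(subjects, function(s) {
    vals <- purrr::map(seq_len(nrow(bands)), function(bi) {
      ed <- vectorize_edges(aec_matrix(s, bands[bi, ], leakage_correction,
                                       env_smooth))
      stats::setNames(ed$value, ed$feature)
    })
    c(list(subject_id = s$subject_id, group = s$group), as.list(unlist(vals)))
  })
  dplyr::bind_rows(rows)
}
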