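#' Canonical MEG frequency bands
#'
#' The seven canonical band definitions used throughout the pipeline:
#' delta 1--3, theta 4--7, alpha 8--14, beta 15--30, low gamma one 30--55,
#' low gamma two 65--80 and high gamma 80--150 Hz.
#'
#' @param bands Optional character vector of band names to keep (in the
#'   canonical order). `NULL` returns all seven.
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' meg_bands()
#' meg_bands(c("alpha", "beta"))
#' @export
meg_bands <- function(bands = NULL) {
  tbl <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "lgamma1", "lgamma2", "hgamma"),
    lo   = c(1, 4, 8, 15, 30, 65, 80),
    hi   = c(3, 7, 14, 30, 55, 80, 150)
  )
  if (is.null(bands)) return(tbl)
  missing <- setdiff(bands, tbl$band)
  if (length(missing)) stopf("unknown band(s): %s", paste(missing, collapse = ", "))
  tbl[match(bands, tbl$band), ]
}

#' Define a frequency band
#'
#' @param band Band name.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return One-row tibble compatible with [meg_bands()].
#' @export
band_definition <- function(band, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo)) {
    stopf("band edges must satisfy 0 < lo < hi (got lo=%s, hi=%s)", lo, hi)
  }
  tibble::tibble(band = as.character(band), lo = as.numeric(lo), hi = as.numeric(hi))
}

# Resolve a band argument (name, or one-row band tibble) against a band table.
resolve_band <- function(band, bands = meg_bands()) {
  if (is.data.frame(band)) {
    stopifnot(nrow(band) == 1L, all(c("band", "lo", "hi") %in% names(band)))
    return(band)
  }
  hit <- bands[bands$band == band, ]
  if (nrow(hit) != 1L) stopf("unknown band '%s'", band)
  hit
}

band_centre <- function(band_row) (band_row$lo + band_row$hi) / 2
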