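#' Configure a synthetic MEG-like cohort
#'
#' Describes the study conditions for the synthetic cohort generator: four
#' groups of subjects, each providing epoch-segmented source-space ("virtual
#' sensor") ROI time series built from 1/f background noise plus band-limited
#' oscillations with slowly varying amplitude envelopes.
#'
#' Defaults mirror the clinical cohort the pipeline was designed for: groups
#' PTSD/TC/mTBI/NTC of 24/27/27/23 subjects, 90 regions, 10-s epochs, and the
#' seven canonical bands of [meg_bands()]. The sampling rate defaults to
#' 600 Hz so the 80--150 Hz band is resolvable.
#'
#' @param n_per_group Named integer vector, subjects per group.
#' @param n_regions Number of ROIs (atlas nodes).
#' @param fs Sampling rate, Hz; must exceed twice the highest band edge.
#' @param epoch_len Epoch length in seconds; `epoch_len * fs` must be integer.
#' @param n_epochs Epochs per subject.
#' @param bands Band table (subset of [meg_bands()] or custom).
#' @param base_amplitudes Named numeric: baseline oscillation amplitude per
#'   band (arbitrary units); must cover every band in `bands`.
#' @param noise_exponent Spectral slope of the 1/f background.
#' @param noise_sd Standard deviation of the background noise (0 disables it).
#' @param env_sigma Log-scale SD of the slow amplitude envelopes.
#' @param env_cutoff Envelope fluctuation cutoff, Hz (< 1 Hz: envelope
#'   dynamics at rest are slow).
#' @param subject_scale_sigma Log-scale SD of the per-subject global amplitude
#'   factor (source amplitude / SNR differs substantially between heads;
#'   0 disables it).
#' @param seed Master seed; all per-subject seeds derive from it.
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config(n_per_group = c(PTSD = 5, TC = 5, mTBI = 5, NTC = 5),
#'                      n_regions = 10, fs = 120, bands = meg_bands("alpha"),
#'                      base_amplitudes = c(alpha = 1))
#' @export
cohort_config <- function(n_per_group = c(PTSD = 24, TC = 27, mTBI = 27, NTC = 23),
                          n_regions = 90,
                          fs = 600,
                          epoch_len = 10,
                          n_epochs = 6,
                          bands = meg_bands(),
                          base_amplitudes = c(delta = 1.2, theta = 1, alpha = 1,
                                              beta = 0.7, lgamma1 = 0.5,
                                              lgamma2 = 0.35, hgamma = 0.3),
                          noise_exponent = 1,
                          noise_sd = 1,
                          env_sigma = 0.4,
                          env_cutoff = 0.5,
                          subject_scale_sigma = 0.3,
                          seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stopf("`n_per_group` must be a named vector of group sizes")
  }
  if (any(n_per_group < 1)) stopf("every group needs at least one subject")
  if (n_regions < 2) stopf("`n_regions` must be >= 2")
  if (fs <= 2 * max(bands$hi)) {
    stopf("fs = %g Hz cannot resolve the %g Hz band edge (need fs > %g)",
          fs, max(bands$hi), 2 * max(bands$hi))
  }
  n_samples <- epoch_len * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stopf("epoch_len * fs must be an integer sample count")
  }
  missing_amp <- setdiff(bands$band, names(base_amplitudes))
  if (length(missing_amp)) {
    stopf("`base_amplitudes` missing band(s): %s", paste(missing_amp, collapse = ", "))
  }
  structure(list(
    n_per_group = n_per_group, n_regions = as.integer(n_regions),
    fs = fs, epoch_len = epoch_len, n_epochs = as.integer(n_epochs),
    n_samples = as.integer(round(n_samples)),
    bands = bands, base_amplitudes = base_amplitudes[bands$band],
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    env_sigma = env_sigma, env_cutoff = env_cutoff,
    subject_scale_sigma = subject_scale_sigma,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Ground-truth effect specifications
#'
#' `power_effect()` multiplies the oscillation amplitude of one ROI in one band
#' for the listed groups (band power scales with the square of the magnitude).
#' `edge_effect()` makes an ROI pair share a common slow envelope modulation in
#' one band for the listed groups, raising their amplitude envelope
#' correlation; `coupling` is the mixing weight in `[0, 1]`.
#'
#' @param band Band name.
#' @param roi,roi_i,roi_j 1-based ROI indices; `roi_i < roi_j`.
#' @param groups Character vector of group labels the effect applies to.
#' @param magnitude Amplitude multiplier (>= 0).
#' @param coupling Envelope mixing weight in `[0, 1]`.
#' @return One-row effect tibble; combine with `rbind()`/[dplyr::bind_rows()].
#' @export
power_effect <- function(band, roi, groups, magnitude) {
  if (magnitude < 0) stopf("`magnitude` must be >= 0")
  tibble::tibble(kind = "power", band = band, roi_i = as.integer(roi),
                 roi_j = NA_integer_, groups = list(groups),
                 magnitude = magnitude)
}

#' @rdname power_effect
#' @export
edge_effect <- function(band, roi_i, roi_j, groups, coupling) {
  if (!(coupling >= 0 && coupling <= 1)) stopf("`coupling` must be in [0, 1]")
  if (!(roi_i < roi_j)) stopf("edge requires roi_i < roi_j")
  tibble::tibble(kind = "edge", band = band, roi_i = as.integer(roi_i),
                 roi_j = as.integer(roi_j), groups = list(groups),
                 magnitude = coupling)
}

validate_effects <- function(effects, config) {
  if (is.null(effects) || nrow(effects) == 0) {
    return(tibble::tibble(kind = character(), band = character(),
                          roi_i = integer(), roi_j = integer(),
                          groups = list(), magnitude = numeric()))
  }
  bad_band <- setdiff(effects$band, config$bands$band)
  if (length(bad_band)) stopf("effect references band(s) not in config: %s",
                              paste(bad_band, collapse = ", "))
  rois <- c(effects$roi_i, effects$roi_j)
  rois <- rois[!is.na(rois)]
  if (any(rois < 1 | rois > config$n_regions)) {
    stopf("effect ROI index outside 1..%d", config$n_regions)
  }
  bad_grp <- setdiff(unlist(effects$groups), names(config$n_per_group))
  if (length(bad_grp)) stopf("effect references unknown group(s): %s",
                             paste(bad_grp, collapse = ", "))
  effects
}

#' Simulate one subject's ROI recording
#'
#' Each ROI channel is 1/f background noise plus, per band, a sinusoid at the
#' band centre whose amplitude follows a slow positive random envelope.
#' Power effects multiply the target band amplitude; edge effects mix a common
#' envelope into both ROIs of the pair with weight equal to the coupling.
#'
#' @param config A [cohort_config()].
#' @param group Group label for this subject.
#' @param effects Effect tibble ([power_effect()]/[edge_effect()] rows), or NULL.
#' @param seed Integer seed; identical inputs give bit-identical recordings.
#' @param subject_id Label for the subject.
#' @return A `meg_recording`: list with `subject_id`, `group`, `fs` and
#'   `epochs` (list of samples-by-regions matrices).
#' @export
simulate_subject <- function(config, group, effects = NULL, seed = 1L,
                             subject_id = "S01") {
  effects <- validate_effects(effects, config)
  if (!group %in% names(config$n_per_group)) stopf("unknown group '%s'", group)
  n <- config$n_samples
  fs <- config$fs
  tt <- (seq_len(n) - 1) / fs
  active <- effects[vapply(effects$groups, function(g) group %in% g, logical(1)), ]
  pow_mult <- function(r, b) {
    hit <- active$kind == "power" & active$band == b & active$roi_i == r
    if (any(hit)) prod(active$magnitude[hit]) else 1
  }
  edge_rows <- which(active$kind == "edge")

  epochs <- with_seed(seed, {
    subj_scale <- exp(config$subject_scale_sigma * stats::rnorm(1))
    lapply(seq_len(config$n_epochs), function(e) {
      shared <- lapply(edge_rows, function(i) {
        slow_envelope(n, fs, config$env_cutoff, config$env_sigma)
      })
      x <- matrix(0, n, config$n_regions)
      for (r in seq_len(config$n_regions)) {
        ch <- if (config$noise_sd > 0) {
          config$noise_sd * pink_noise(n, config$noise_exponent, fs)
        } else {
          numeric(n)
        }
        for (bi in seq_len(nrow(config$bands))) {
          brow <- config$bands[bi, ]
          amp <- config$base_amplitudes[[brow$band]] * pow_mult(r, brow$band)
          env <- slow_envelope(n, fs, config$env_cutoff, config$env_sigma)
          phase <- stats::runif(1, 0, 2 * pi)
          if (amp <= 0) next
          for (k in seq_along(edge_rows)) {
            er <- active[edge_rows[k], ]
            if (er$band == brow$band && r %in% c(er$roi_i, er$roi_j)) {
              env <- (1 - er$magnitude) * env + er$magnitude * shared[[k]]
            }
          }
          ch <- ch + amp * env * sin(2 * pi * band_centre(brow) * tt + phase)
        }
        x[, r] <- ch
      }
      subj_scale * x
    })
  })
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 epochs = epochs),
            class = "meg_recording")
}

#' Simulate a four-group cohort with known ground truth
#'
#' Generates one [simulate_subject()] recording per subject, with per-subject
#' seeds derived deterministically from `config$seed`, and attaches the
#' ground-truth effect map (with the feature names each effect lands on) for
#' recovery testing.
#'
#' @inheritParams simulate_subject
#' @return A `meg_cohort`: list with `subjects` (list of recordings), `config`,
#'   `ground_truth` (tibble with a `feature` column).
#' @examples
#' cfg <- cohort_config(n_per_group = c(A = 3, B = 3, C = 3, D = 3),
#'                      n_regions = 6, fs = 80, n_epochs = 2,
#'                      bands = meg_bands("alpha"),
#'                      base_amplitudes = c(alpha = 1))
#' co <- simulate_cohort(cfg, power_effect("alpha", 2, "A", 2))
#' @export
simulate_cohort <- function(config, effects = NULL) {
  effects <- validate_effects(effects, config)
  groups <- names(config$n_per_group)
  subjects <- list()
  for (g in groups) {
    for (i in seq_len(config$n_per_group[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      subjects[[id]] <- simulate_subject(
        config, g, effects,
        seed = derive_seed(config$seed, "subject", id), subject_id = id
      )
    }
  }
  gt <- effects
  if (nrow(gt)) {
    gt$feature <- ifelse(
      gt$kind == "power",
      sprintf("pow_%s_%03d", gt$band, gt$roi_i),
      sprintf("aec_%s_%03d_%03d", gt$band, gt$roi_i, gt$roi_j)
    )
  } else {
    gt$feature <- character()
  }
  structure(list(subjects = subjects, config = config, ground_truth = gt),
            class = "meg_cohort")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %s (%s): %d epochs x %d regions x %d samples @ %g Hz\n",
              x$subject_id, x$group, length(x$epochs), ncol(x$epochs[[1]]),
              nrow(x$epochs[[1]]), x$fs))
  invisible(x)
}

#' @export
print.meg_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<meg_cohort> %d subjects (%s); %d regions, %d epochs @ %g Hz; %d planted effect(s)\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$n_regions, x$config$n_epochs, x$config$fs,
              nrow(x$ground_truth)))
  invisible(x)
}

#' Cohort subject labels
#' @param cohort A `meg_cohort`.
#' @return Tibble with `subject_id` and `group`.
#' @export
cohort_labels <- function(cohort) {
  tibble::tibble(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = vapply(cohort$subjects, `[[`, "", "group")
  )
}
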