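# Serialisation: cohorts as a directory of per-subject CSVs plus a JSON
# manifest carrying the config and the ground-truth effect map; feature
# matrices as CSV with a JSON sidecar describing bands and parameters.

#' Write / read a synthetic cohort
#'
#' The cohort container is a directory holding `manifest.json` (config,
#' subject table, ground-truth effect map) and one `<subject_id>.csv` per
#' subject (columns `epoch`, then one column per region; rows are samples
#' stacked by epoch). `read_cohort()` restores a bit-identical `meg_cohort`
#' up to CSV numeric printing precision (15 significant digits).
#'
#' @param cohort A `meg_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` the directory path, invisibly; `read_cohort()` a
#'   `meg_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  gt <- cohort$ground_truth
  manifest <- list(
    config = list(
      n_per_group = as.list(cfg$n_per_group), n_regions = cfg$n_regions,
      fs = cfg$fs, epoch_len = cfg$epoch_len, n_epochs = cfg$n_epochs,
      bands = cfg$bands, base_amplitudes = as.list(cfg$base_amplitudes),
      noise_exponent = cfg$noise_exponent, noise_sd = cfg$noise_sd,
      env_sigma = cfg$env_sigma, env_cutoff = cfg$env_cutoff,
      subject_scale_sigma = cfg$subject_scale_sigma, seed = cfg$seed
    ),
    subjects = cohort_labels(cohort),
    ground_truth = gt[setdiff(names(gt), "groups")],
    ground_truth_groups = lapply(gt$groups, identity),
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in cohort$subjects) {
    mat <- do.call(rbind, s$epochs)
    df <- data.frame(epoch = rep(seq_along(s$epochs), each = nrow(s$epochs[[1]])),
                     mat)
    names(df) <- c("epoch", sprintf("region_%03d", seq_len(ncol(mat))))
    utils::write.csv(df, file.path(dir, paste0(s$subject_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mc <- manifest$config
  config <- cohort_config(
    n_per_group = unlist(mc$n_per_group), n_regions = mc$n_regions,
    fs = mc$fs, epoch_len = mc$epoch_len, n_epochs = mc$n_epochs,
    bands = tibble::as_tibble(mc$bands),
    base_amplitudes = unlist(mc$base_amplitudes),
    noise_exponent = mc$noise_exponent, noise_sd = mc$noise_sd,
    env_sigma = mc$env_sigma, env_cutoff = mc$env_cutoff,
    subject_scale_sigma = mc$subject_scale_sigma, seed = mc$seed
  )
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    id <- manifest$subjects$subject_id[i]
    df <- utils::read.csv(file.path(dir, paste0(id, ".csv")))
    epochs <- lapply(split(df[-1], df$epoch),
                     function(e) unname(as.matrix(e)))
    names(epochs) <- NULL
    structure(list(subject_id = id, group = manifest$subjects$group[i],
                   fs = config$fs, epochs = epochs), class = "meg_recording")
  })
  names(subjects) <- manifest$subjects$subject_id
  gt <- tibble::as_tibble(manifest$ground_truth)
  if (nrow(gt) == 0) {
    gt <- tibble::tibble(kind = character(), band = character(),
                         roi_i = integer(), roi_j = integer(),
                         magnitude = numeric(), feature = character())
  }
  # JSON drops all-NA columns (power-only effect maps have no roi_j)
  if (!"roi_j" %in% names(gt)) gt$roi_j <- NA_integer_
  gt$roi_i <- as.integer(gt$roi_i)
  gt$roi_j <- as.integer(gt$roi_j)
  gt$groups <- lapply(manifest$ground_truth_groups, unlist)
  gt <- gt[c("kind", "band", "roi_i", "roi_j", "groups", "magnitude", "feature")]
  structure(list(subjects = subjects, config = config, ground_truth = gt),
            class = "meg_cohort")
}

#' Write / read a feature matrix as CSV with a JSON sidecar
#'
#' @param data Feature tibble.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @param meta Extra metadata recorded in the sidecar (bands, parameters...).
#' @export
write_feature_matrix <- function(data, path, meta = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data, path, row.names = FALSE)
  sidecar <- c(list(n_subjects = nrow(data),
                    features = feature_cols(data),
                    written = "megconn feature matrix"), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Feature metadata parsed from canonical feature names
#'
#' @param features Character vector of `pow_<band>_<roi>` /
#'   `aec_<band>_<i>_<j>` names, or a feature tibble.
#' @return Tibble: `feature`, `type` (`power`/`aec`), `band`, `roi_i`,
#'   `roi_j` (`NA` for power features).
#' @export
feature_info <- function(features) {
  if (is.data.frame(features)) features <- feature_cols(features)
  parts <- strsplit(features, "_", fixed = TRUE)
  tibble::tibble(
    feature = features,
    type = vapply(parts, function(p) if (p[1] == "pow") "power" else "aec", ""),
    band = vapply(parts, `[`, "", 2),
    roi_i = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    roi_j = vapply(parts, function(p) {
      if (length(p) >= 4) as.integer(p[4]) else NA_integer_
    }, integer(1))
  )
}

#' Build a validated run configuration
#'
#' Accepts a YAML file path or a named list, fills defaults, validates, and
#' attaches a config hash that is echoed into every output the run writes.
#'
#' @param config Path to a YAML file, or a named list with any of:
#'   `out_dir`, `seed`, `bands`, `feature_types` (`"power"`, `"aec"`),
#'   `two_step`, `alpha_raw`, `fraction`, `n_folds`, `n_perm`, `cohort`
#'   (arguments to [cohort_config()]), `effects` (records with `kind`,
#'   `band`, `roi_i`, `roi_j`, `groups`, `magnitude`).
#' @return A `run_config` list with a `hash` element.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(out_dir = "megconn_out", seed = 1L, bands = NULL,
                   feature_types = c("power", "aec"), two_step = FALSE,
                   alpha_raw = 0.05, fraction = 0.85, n_folds = 10,
                   n_perm = 0, cohort = list(), effects = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (!all(cfg$feature_types %in% c("power", "aec"))) {
    stopf("feature_types must be a subset of {power, aec}")
  }
  cohort_args <- cfg$cohort
  if (!is.null(cohort_args$n_per_group)) {
    cohort_args$n_per_group <- unlist(cohort_args$n_per_group)
  }
  if (!is.null(cohort_args$base_amplitudes)) {
    cohort_args$base_amplitudes <- unlist(cohort_args$base_amplitudes)
  }
  if (!is.null(cfg$bands)) cohort_args$bands <- meg_bands(cfg$bands)
  if (is.null(cohort_args$seed)) cohort_args$seed <- cfg$seed
  cfg$cohort_config <- do.call(cohort_config, cohort_args)
  if (is.null(cfg$bands)) cfg$bands <- cfg$cohort_config$bands$band
  eff <- cfg$effects
  cfg$effect_table <- if (length(eff)) {
    dplyr::bind_rows(lapply(eff, function(e) {
      if (e$kind == "power") {
        power_effect(e$band, e$roi_i, unlist(e$groups), e$magnitude)
      } else {
        edge_effect(e$band, e$roi_i, e$roi_j, unlist(e$groups), e$magnitude)
      }
    }))
  } else {
    NULL
  }
  cfg$hash <- rlang::hash(cfg[c("seed", "bands", "feature_types", "two_step",
                                "alpha_raw", "fraction", "n_folds", "n_perm",
                                "cohort", "effects")])
  structure(cfg, class = "run_config")
}

#' Run the configured stages end to end
#'
#' `simulate_stage()` writes the cohort container and ground-truth map;
#' `features_stage()` writes one feature-matrix CSV per band and feature
#' type; `model_stage()` runs [run_pipeline()] per band and feature type and
#' writes a JSON report each (selection, consensus, holdout evaluation,
#' permutation p), every file stamped with the config hash.
#' `run_from_config()` chains the three.
#'
#' @param cfg A [run_config()].
#' @param cohort Optionally a pre-simulated `meg_cohort` (otherwise read from
#'   `out_dir/cohort`).
#' @return `run_from_config()` returns a tibble summarising each fitted model.
#' @export
simulate_stage <- function(cfg) {
  cohort <- simulate_cohort(cfg$cohort_config, cfg$effect_table)
  write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
  invisible(cohort)
}

#' @rdname simulate_stage
#' @export
features_stage <- function(cfg, cohort = NULL) {
  if (is.null(cohort)) cohort <- read_cohort(file.path(cfg$out_dir, "cohort"))
  bands <- meg_bands(cfg$bands)
  out <- list()
  for (bi in seq_len(nrow(bands))) {
    b <- bands$band[bi]
    if ("power" %in% cfg$feature_types) {
      fm <- power_features(cohort, bands[bi, ])
      write_feature_matrix(fm, file.path(cfg$out_dir, sprintf("features_power_%s.csv", b)),
                           meta = list(band = bands[bi, ], type = "power",
                                       config_hash = cfg$hash))
      out[[paste0("power_", b)]] <- fm
    }
    if ("aec" %in% cfg$feature_types) {
      fm <- aec_features(cohort, bands[bi, ])
      write_feature_matrix(fm, file.path(cfg$out_dir, sprintf("features_aec_%s.csv", b)),
                           meta = list(band = bands[bi, ], type = "aec",
                                       config_hash = cfg$hash))
      out[[paste0("aec_", b)]] <- fm
    }
  }
  invisible(out)
}

#' @rdname simulate_stage
#' @param features Named list of feature tibbles from [features_stage()].
#' @export
model_stage <- function(cfg, features) {
  rows <- purrr::imap(features, function(fm, nm) {
    run <- run_pipeline(fm, fraction = cfg$fraction, n_folds = cfg$n_folds,
                        two_step = cfg$two_step, alpha_raw = cfg$alpha_raw,
                        n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, "model", nm))
    report <- list(
      model = nm, config_hash = cfg$hash, seed = run$seed,
      consensus = run$selection$consensus,
      cv_accuracy = run$selection$fold_accuracy,
      fourclass_cv = run$selection$fourclass,
      holdout = if (!is.null(run$evaluation)) {
        list(per_group = run$evaluation$per_group,
             overall = run$evaluation$overall_accuracy,
             confusion = as.data.frame(run$evaluation$confusion))
      },
      permutation_p = if (!is.null(run$permutation)) run$permutation$p_value
    )
    jsonlite::write_json(report,
                         file.path(cfg$out_dir, sprintf("report_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tibble::tibble(
      model = nm, n_consensus = length(run$selection$consensus),
      cv_fourclass = mean(run$selection$fourclass$accuracy, na.rm = TRUE),
      holdout_overall = if (!is.null(run$evaluation)) run$evaluation$overall_accuracy else NA_real_,
      permutation_p = if (!is.null(run$permutation)) run$permutation$p_value else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname simulate_stage
#' @export
run_from_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  cohort <- simulate_stage(cfg)
  features <- features_stage(cfg, cohort)
  summary <- model_stage(cfg, features)
  utils::write.csv(summary, file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
  summary
}
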