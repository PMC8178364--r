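#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-fold accuracies of a selection run
#'
#' @param x A `cv_selection` from [cv_svm_rrf_fs()].
#' @param ... Unused.
#' @return Tibble: `fold`, `group`, `accuracy` (percent; four-class rows use
#'   `group = "fourclass"`).
#' @method tidy cv_selection
#' @export
tidy.cv_selection <- function(x, ...) {
  dplyr::bind_rows(
    x$fold_accuracy,
    dplyr::mutate(x$fourclass, group = "fourclass",
                  .before = "accuracy")[c("fold", "group", "accuracy")]
  )
}

#' @rdname tidy.cv_selection
#' @return `glance()`: one row with fold counts, consensus size and the
#'   four-class CV accuracy mean and SD across folds.
#' @method glance cv_selection
#' @export
glance.cv_selection <- function(x, ...) {
  tibble::tibble(
    n_folds = length(x$fold_features),
    two_step = x$two_step,
    n_consensus = length(x$consensus),
    cv_accuracy_mean = mean(x$fourclass$accuracy, na.rm = TRUE),
    cv_accuracy_sd = stats::sd(x$fourclass$accuracy, na.rm = TRUE)
  )
}

#' Tidy a holdout evaluation
#'
#' @param x A `meg_eval` from [evaluate_holdout()].
#' @param ... Unused.
#' @return Per-group tibble: `group`, `accuracy` (percent), `auc`.
#' @method tidy meg_eval
#' @export
tidy.meg_eval <- function(x, ...) x$per_group

#' @rdname tidy.meg_eval
#' @method glance meg_eval
#' @export
glance.meg_eval <- function(x, ...) {
  tibble::tibble(
    n_holdout = x$n_holdout,
    overall_accuracy = x$overall_accuracy,
    mean_ovr_accuracy = mean(x$per_group$accuracy),
    mean_auc = mean(x$per_group$auc, na.rm = TRUE)
  )
}

#' Tidy a fitted SVM bundle
#'
#' @param x An `svm_bundle`.
#' @param ... Unused.
#' @return `tidy()`: one row per feature used; `glance()`: kernel,
#'   hyperparameters and tuning-CV accuracy.
#' @method tidy svm_bundle
#' @export
tidy.svm_bundle <- function(x, ...) {
  if (isTRUE(x$empty)) return(tibble::tibble(feature = character()))
  tibble::tibble(feature = x$features)
}

#' @rdname tidy.svm_bundle
#' @method glance svm_bundle
#' @export
glance.svm_bundle <- function(x, ...) {
  if (isTRUE(x$empty)) {
    return(tibble::tibble(kernel = NA_character_, cost = NA_real_,
                          gamma = NA_real_, n_features = 0L,
                          tune_cv_accuracy = NA_real_))
  }
  tibble::tibble(kernel = x$kernel, cost = x$cost, gamma = x$gamma,
                 n_features = length(x$features),
                 tune_cv_accuracy = 100 * x$cv_accuracy)
}

#' Tidy / summarise a full pipeline run
#'
#' @param x A `meg_run` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: per-group holdout accuracy and AUC; `glance()`: one row
#'   with consensus size, CV accuracy, holdout accuracy and permutation p.
#' @method tidy meg_run
#' @export
tidy.meg_run <- function(x, ...) {
  if (is.null(x$evaluation)) return(tibble::tibble(group = character()))
  tidy(x$evaluation)
}

#' @rdname tidy.meg_run
#' @method glance meg_run
#' @export
glance.meg_run <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$selection),
    tibble::tibble(
      holdout_accuracy = if (!is.null(x$evaluation)) x$evaluation$overall_accuracy else NA_real_,
      permutation_p = if (!is.null(x$permutation)) x$permutation$p_value else NA_real_,
      plsda_p = if (!is.null(x$plsda)) x$plsda$perm_p else NA_real_,
      seed = x$seed
    )
  )
}
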