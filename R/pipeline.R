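#' Run the full classification pipeline on a feature table
#'
#' End-to-end orchestration of the downstream workflow for one feature set
#' (one band and feature type): stratified 85/15 train/holdout split, nested
#' cross-validated recursive RF feature selection with SVM modelling
#' ([cv_svm_rrf_fs()]), final SVM trained on the training data with the
#' consensus features, optional PLS-DA verification and label-permutation
#' test, and a single holdout evaluation.
#'
#' The permutation statistic is the mean four-class CV accuracy of the
#' selection engine re-run from scratch on the permuted labels, at reduced
#' fold/tree counts (`perm_folds`, `perm_trees`) so the test is tractable;
#' screening and selection are repeated per permutation, never reused.
#'
#' @param data Feature tibble (`subject_id`, `group`, features).
#' @param fraction Training fraction for the holdout split.
#' @param n_folds Outer CV folds.
#' @param two_step Univariate raw-p reduction inside each fold?
#' @param alpha_raw Raw-p threshold for the two-step screen.
#' @param n_perm Label permutations for the permutation test (0 skips it).
#' @param perm_folds,perm_trees Reduced fold/tree counts for the permutation
#'   closure.
#' @param verify_plsda Run PLS-DA verification of the consensus features?
#' @param seed Master seed; split, folds, forests and permutations all derive
#'   from it.
#' @param ... Further arguments to [cv_svm_rrf_fs()].
#' @return A `meg_run`: `split`, `selection` (`cv_selection`), `bundle`
#'   (`svm_bundle`), `evaluation` (`meg_eval`, `NULL` if the consensus was
#'   empty), `permutation`, `plsda`, `seed`.
#' @export
run_pipeline <- function(data, fraction = 0.85, n_folds = 10, two_step = FALSE,
                         alpha_raw = 0.05, n_perm = 0, perm_folds = 3,
                         perm_trees = 100, verify_plsda = FALSE, seed = 1L, ...) {
  check_feature_table(data)
  split <- stratified_split(data, fraction, seed = derive_seed(seed, "split"))
  train <- data[data$subject_id %in% split$train_ids, ]
  holdout <- data[data$subject_id %in% split$holdout_ids, ]
  selection <- cv_svm_rrf_fs(train, n_folds = n_folds, two_step = two_step,
                             alpha_raw = alpha_raw,
                             seed = derive_seed(seed, "cv"), ...)
  bundle <- tune_and_train_svm(train, selection$consensus,
                               seed = derive_seed(seed, "final"))
  evaluation <- if (!isTRUE(bundle$empty)) {
    evaluate_holdout(bundle, holdout, split)
  } else {
    NULL
  }
  permutation <- if (n_perm > 0) {
    perm_args <- utils::modifyList(list(...), list(n_trees = perm_trees))
    stat <- function(d) {
      res <- do.call(cv_svm_rrf_fs, c(
        list(d, n_folds = perm_folds, two_step = two_step,
             alpha_raw = alpha_raw, seed = derive_seed(seed, "permstat")),
        perm_args
      ))
      mean(res$fourclass$accuracy, na.rm = TRUE)
    }
    permutation_test(train, stat, n_perm = n_perm,
                     seed = derive_seed(seed, "permtest"))
  } else {
    NULL
  }
  plsda <- if (verify_plsda && length(selection$consensus) >= 2) {
    plsda_verify(train, selection$consensus, seed = derive_seed(seed, "plsda"))
  } else {
    NULL
  }
  structure(list(split = split, selection = selection, bundle = bundle,
                 evaluation = evaluation, permutation = permutation,
                 plsda = plsda, seed = as.integer(seed)),
            class = "meg_run")
}

#' @export
print.meg_run <- function(x, ...) {
  cat(sprintf("<meg_run> seed %d; consensus %d feature(s)\n", x$seed,
              length(x$selection$consensus)))
  if (!is.null(x$evaluation)) print(x$evaluation)
  if (!is.null(x$permutation)) {
    cat(sprintf("permutation p = %.4g (n_perm = %d)\n",
                x$permutation$p_value, x$permutation$n_perm))
  }
  invisible(x)
}
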