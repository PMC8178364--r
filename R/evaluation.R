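#' Stratified train/holdout split
#'
#' Splits subjects into training and holdout sets preserving group
#' proportions (largest-remainder rounding per group, so each group's
#' training count is within one subject of `fraction` times its size). The
#' default 85/15 split of the 101-subject reference cohort gives 86 training
#' and 15 holdout subjects.
#'
#' @param data Feature tibble (or any tibble with `subject_id` and `group`).
#' @param fraction Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @return A `split_spec`: `train_ids`, `holdout_ids`, `fraction`, `seed` and
#'   the training `partition_hash`.
#' @export
stratified_split <- function(data, fraction = 0.85, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stopf("`fraction` must be in (0, 1)")
  if (!all(c("subject_id", "group") %in% names(data))) {
    stopf("`data` needs `subject_id` and `group` columns")
  }
  tab <- table(data$group)
  if (any(tab < 2)) stopf("every group needs >= 2 subjects to split")
  # largest-remainder apportionment of the total training count across groups
  total_train <- round(fraction * nrow(data))
  quota <- fraction * as.numeric(tab)
  base <- floor(quota)
  rem <- total_train - sum(base)
  extra <- order(quota - base, decreasing = TRUE)[seq_len(max(rem, 0))]
  n_train <- base
  n_train[extra] <- n_train[extra] + 1
  n_train <- pmin(pmax(n_train, 1), as.numeric(tab) - 1)  # >=1 holdout per group
  names(n_train) <- names(tab)
  train_ids <- character()
  with_seed(seed, {
    for (g in names(tab)) {
      ids <- data$subject_id[data$group == g]
      train_ids <- c(train_ids, sample(ids, n_train[[g]]))
    }
  })
  holdout_ids <- setdiff(data$subject_id, train_ids)
  structure(list(train_ids = sort(train_ids), holdout_ids = sort(holdout_ids),
                 fraction = fraction, seed = as.integer(seed),
                 partition_hash = partition_hash(train_ids)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d holdout (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$holdout_ids), x$fraction, x$seed))
  invisible(x)
}

#' Per-group one-vs-rest accuracy
#'
#' For each group, the accuracy of the binarised decision "this group vs the
#' remaining groups" over all evaluated subjects, as a percentage.
#'
#' @param truth True group labels.
#' @param pred Predicted labels, aligned with `truth`.
#' @param groups Groups to report (default: those present in `truth`).
#' @return Tibble: `group`, `accuracy` (percent).
#' @export
per_group_accuracy <- function(truth, pred, groups = NULL) {
  if (length(truth) != length(pred)) stopf("`truth` and `pred` must be aligned")
  if (is.null(groups)) groups <- sort(unique(as.character(truth)))
  # predictions outside the group set simply binarise to "rest"; a *requested*
  # group that neither labels nor predictions carry is a caller error (typo)
  unknown <- setdiff(groups, c(as.character(truth), as.character(pred)))
  if (length(unknown)) {
    stopf("unknown group label(s): %s", paste(unknown, collapse = ", "))
  }
  tibble::tibble(
    group = groups,
    accuracy = unname(vapply(groups, function(g) {
      100 * mean((truth == g) == (pred == g))
    }, numeric(1)))
  )
}

#' One-vs-rest ROC AUC per group
#'
#' Mann--Whitney (midrank-tied) area under the one-vs-rest ROC curve for each
#' group, from per-class decision scores. A group absent from the evaluated
#' labels has an undefined AUC and is reported as `NA`.
#'
#' @param truth True group labels.
#' @param scores Subjects-by-groups numeric score matrix (higher = more
#'   "this group"), e.g. from [ovr_scores()].
#' @return Tibble: `group`, `auc` in `[0, 1]`.
#' @export
ovr_auc <- function(truth, scores) {
  if (nrow(scores) != length(truth)) stopf("`scores` rows must align with `truth`")
  tibble::tibble(
    group = colnames(scores),
    auc = unname(vapply(colnames(scores), function(g) {
      resp <- factor(ifelse(truth == g, "pos", "neg"), levels = c("neg", "pos"))
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, g], quiet = TRUE,
                                     direction = "<", levels = c("neg", "pos"))))
    }, numeric(1)))
  )
}

#' Sample-label permutation test
#'
#' Re-runs a pipeline statistic under label permutations and reports the
#' permutation p-value `(1 + #{permuted >= observed}) / (1 + n_perm)`, which
#' is valid (super-uniform under the null) by construction. The statistic
#' closure receives the full data with its `group` column (re)assigned and
#' must recompute everything -- screening, selection, training, CV scoring --
#' from scratch, so no information from the observed run is reused.
#'
#' @param data Feature tibble with a `group` column.
#' @param statistic Function `data -> scalar score` (higher = better).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @return List: `p_value`, `observed`, `permuted` (vector), `n_perm`, `seed`.
#' @export
permutation_test <- function(data, statistic, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  if (!"group" %in% names(data)) stopf("`data` needs a `group` column")
  observed <- statistic(data)
  perms <- with_seed(derive_seed(seed, "permlabels"), {
    replicate(n_perm, sample(data$group))
  })
  permuted <- vapply(seq_len(n_perm), function(b) {
    d <- data
    d$group <- perms[, b]
    statistic(d)
  }, numeric(1))
  list(p_value = (1 + sum(permuted >= observed)) / (1 + n_perm),
       observed = observed, permuted = permuted,
       n_perm = n_perm, seed = as.integer(seed))
}

#' Evaluate a fitted model on the holdout subjects
#'
#' Scores the holdout set once with a fitted [tune_and_train_svm()] bundle:
#' per-group one-vs-rest accuracy, one-vs-rest AUC and the confusion matrix,
#' with full provenance (training partition hash, features, kernel). Any
#' overlap between the holdout subjects and the bundle's training partition
#' is a hard leakage failure, as is a tampered partition hash.
#'
#' @param bundle An `svm_bundle`.
#' @param holdout Holdout feature tibble.
#' @param split Optional `split_spec`; when given, the bundle's partition
#'   hash must match the split's.
#' @return A `meg_eval`: per-group accuracy/AUC tibble, confusion matrix
#'   (rows = true groups), overall accuracy, provenance.
#' @export
evaluate_holdout <- function(bundle, holdout, split = NULL) {
  if (isTRUE(bundle$empty)) stopf("no-model bundle: %s", bundle$reason)
  overlap <- intersect(holdout$subject_id, bundle$train_ids)
  if (length(overlap)) {
    stopf("leakage: holdout overlaps the model's training partition (%s%s)",
          paste(head(overlap, 3), collapse = ", "),
          if (length(overlap) > 3) ", ..." else "")
  }
  if (!is.null(split) && !identical(split$partition_hash, bundle$partition_hash)) {
    stopf("partition hash mismatch: the model was not trained on this split")
  }
  pred <- predict(bundle, holdout)$pred
  scores <- ovr_scores(bundle, holdout)
  acc <- per_group_accuracy(holdout$group, pred, groups = bundle$levels)
  auc <- ovr_auc(holdout$group, scores)
  cm <- table(truth = factor(holdout$group, bundle$levels),
              pred = factor(pred, bundle$levels))
  structure(list(
    per_group = dplyr::left_join(acc, auc, by = "group"),
    confusion = cm,
    overall_accuracy = 100 * mean(pred == holdout$group),
    n_holdout = nrow(holdout),
    predictions = tibble::tibble(subject_id = holdout$subject_id,
                                 truth = holdout$group, pred = pred),
    scores = scores,
    provenance = list(partition_hash = bundle$partition_hash,
                      features = bundle$features, kernel = bundle$kernel,
                      cost = bundle$cost, gamma = bundle$gamma)
  ), class = "meg_eval")
}

#' @export
print.meg_eval <- function(x, ...) {
  cat(sprintf("<meg_eval> %d holdout subjects; overall accuracy %.1f%%\n",
              x$n_holdout, x$overall_accuracy))
  print(as.data.frame(x$per_group), row.names = FALSE)
  invisible(x)
}
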