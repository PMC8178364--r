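#' Random-forest feature importance ranking
#'
#' Fits a classification random forest and returns features in decreasing
#' mean-impurity-decrease importance; ties are broken by the fixed feature
#' column order so the ranking is a deterministic total order.
#'
#' @param data Feature tibble with `subject_id`, `group` and feature columns.
#' @param n_trees Number of trees.
#' @param seed Integer seed (forest growth is seeded and single-threaded).
#' @return Tibble: `feature`, `importance`, `rank`.
#' @export
rf_rank <- function(data, n_trees = 500, seed = 1L) {
  feats <- check_feature_table(data)
  y <- factor(data$group)
  if (nlevels(y) < 2) stopf("`group` must contain at least two classes")
  fit <- ranger::ranger(
    x = data[feats], y = y, num.trees = n_trees,
    importance = "impurity", seed = as.integer(seed), num.threads = 1
  )
  imp <- fit$variable.importance[feats]
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(feature = feats[ord], importance = unname(imp[ord]),
                 rank = seq_along(ord))
}

# Misclassification error of the remaining feature set, either the forest's
# out-of-bag estimate (with binomial SE) or an explicit stratified inner CV.
rrf_error <- function(data, feats, n_trees, error_estimate, inner_folds, seed) {
  y <- factor(data$group)
  if (error_estimate == "oob") {
    fit <- ranger::ranger(x = data[feats], y = y, num.trees = n_trees,
                          importance = "impurity", seed = as.integer(seed),
                          num.threads = 1)
    err <- fit$prediction.error
    list(error = err, se = sqrt(err * (1 - err) / length(y)),
         importance = fit$variable.importance[feats])
  } else {
    fold <- stratified_folds(y, inner_folds, derive_seed(seed, "innercv"))
    errs <- vapply(seq_len(inner_folds), function(f) {
      tr <- data[fold != f, ]; te <- data[fold == f, ]
      fit <- ranger::ranger(x = tr[feats], y = factor(tr$group, levels(y)),
                            num.trees = n_trees,
                            seed = derive_seed(seed, "fold", f), num.threads = 1)
      mean(stats::predict(fit, te[feats])$predictions != te$group)
    }, numeric(1))
    fit <- ranger::ranger(x = data[feats], y = y, num.trees = n_trees,
                          importance = "impurity", seed = as.integer(seed),
                          num.threads = 1)
    list(error = mean(errs), se = stats::sd(errs) / sqrt(inner_folds),
         importance = fit$variable.importance[feats])
  }
}

#' Recursive random-forest feature elimination
#'
#' Iteratively drops the lowest-importance fraction of the remaining features,
#' recording the classification error at each set size, and returns the
#' smallest subset whose error is within `se_mult` standard errors of the
#' minimum (the one-standard-error parsimony rule).
#'
#' @param data Feature tibble with `subject_id`, `group` and feature columns.
#' @param drop_frac Fraction of remaining features dropped per round, in (0,1).
#' @param min_features Smallest subset size visited.
#' @param n_trees Trees per forest.
#' @param error_estimate `"oob"` (out-of-bag, the default) or `"cv"`
#'   (stratified `inner_folds`-fold refitting).
#' @param inner_folds Folds for `error_estimate = "cv"`.
#' @param se_mult Multiplier in the one-SE rule (0 picks the minimum-error size).
#' @param seed Integer seed.
#' @return An `rrf_select` list: `selected` (features in importance order),
#'   `path` (tibble `size`, `error`, `se`), `chosen_size`.
#' @export
rrf_select <- function(data, drop_frac = 0.2, min_features = 2,
                       n_trees = 500, error_estimate = c("oob", "cv"),
                       inner_folds = 5, se_mult = 1, seed = 1L) {
  error_estimate <- match.arg(error_estimate)
  if (!(drop_frac > 0 && drop_frac < 1)) stopf("`drop_frac` must be in (0, 1)")
  feats <- check_feature_table(data)
  if (min_features > length(feats)) {
    stopf("min_features (%d) exceeds the number of features (%d)",
          min_features, length(feats))
  }
  current <- feats
  sizes <- integer(); errs <- numeric(); ses <- numeric(); sets <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    est <- rrf_error(data, current, n_trees, error_estimate, inner_folds,
                     derive_seed(seed, "round", round))
    sizes <- c(sizes, length(current)); errs <- c(errs, est$error)
    ses <- c(ses, est$se); sets[[round]] <- current
    if (length(current) <= min_features) break
    ord <- order(-est$importance, match(names(est$importance), feats))
    ndrop <- max(1L, floor(drop_frac * length(current)))
    keep <- max(min_features, length(current) - ndrop)
    current <- names(est$importance)[ord][seq_len(keep)]
  }
  thr <- min(errs) + se_mult * ses[which.min(errs)]
  ok <- which(errs <= thr)
  pick <- ok[which.min(sizes[ok])]
  structure(list(selected = sets[[pick]],
                 path = tibble::tibble(size = sizes, error = errs, se = ses),
                 chosen_size = sizes[pick], se_mult = se_mult,
                 error_estimate = error_estimate, seed = as.integer(seed)),
            class = "rrf_select")
}

#' @export
print.rrf_select <- function(x, ...) {
  cat(sprintf("<rrf_select> %d features chosen (path %s; %s error, %g-SE rule)\n",
              x$chosen_size, paste(x$path$size, collapse = ">"),
              x$error_estimate, x$se_mult))
  invisible(x)
}

#' Tune and train the final SVM on a feature subset
#'
#' Standardises the features with training statistics, selects the kernel and
#' hyperparameters by stratified inner cross-validation over a grid (linear
#' and RBF kernels, log-spaced cost, RBF bandwidth around the 1/p heuristic),
#' and fits the final SVM on all rows. Classes are weighted inversely to
#' group size. Ties prefer the simpler model: linear before RBF, then the
#' smaller cost, then the smaller gamma.
#'
#' @param data Training feature tibble.
#' @param features Feature ids the model may use (non-empty).
#' @param kernels Kernel menu (subset of `"linear"`, `"radial"`).
#' @param cost Cost grid.
#' @param gamma_mult RBF gamma grid as multiples of `1/length(features)`.
#' @param inner_folds Folds for the tuning CV.
#' @param seed Integer seed.
#' @return An `svm_bundle`: fitted model, preprocessing state (center/scale),
#'   feature ids, chosen kernel/hyperparameters, inner-CV accuracy, training
#'   ids and partition hash.
#' @export
tune_and_train_svm <- function(data, features, kernels = c("linear", "radial"),
                               cost = 10^(-1:2), gamma_mult = c(0.25, 1, 4),
                               inner_folds = 5, seed = 1L) {
  if (length(features) == 0) {
    return(structure(list(empty = TRUE, reason = "empty feature set"),
                     class = c("no_model", "svm_bundle")))
  }
  missing <- setdiff(features, names(data))
  if (length(missing)) stopf("features absent from data: %s",
                             paste(head(missing, 3), collapse = ", "))
  y <- factor(data$group)
  zs <- zscore_fit_transform(data[c("subject_id", "group", features)])
  X <- as_feature_matrix(zs$data)
  wts <- length(y) / (nlevels(y) * table(y))
  wts <- stats::setNames(as.numeric(wts), names(wts))
  grid <- dplyr::bind_rows(
    if ("linear" %in% kernels) tibble::tibble(kernel = "linear", cost = cost, gamma = NA_real_),
    if ("radial" %in% kernels) tidyr::expand_grid(kernel = "radial", cost = cost,
                                                  gamma = gamma_mult / length(features))
  )
  if (nrow(grid) == 0) stopf("empty kernel menu")
  n_inner <- min(inner_folds, min(table(y)))
  if (n_inner < 2) stopf("too few subjects per group for tuning CV")
  fold <- stratified_folds(y, n_inner, derive_seed(seed, "svmtune"))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(n_inner), function(f) {
      tr <- fold != f
      fit <- e1071::svm(
        x = X[tr, , drop = FALSE], y = y[tr], kernel = grid$kernel[i],
        cost = grid$cost[i],
        gamma = if (is.na(grid$gamma[i])) 1 / ncol(X) else grid$gamma[i],
        class.weights = wts, scale = FALSE
      )
      mean(stats::predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  # parsimony tie-break: order = kernel menu order, then cost, then gamma
  best <- order(-acc, match(grid$kernel, c("linear", "radial")),
                grid$cost, grid$gamma)[1]
  fit <- e1071::svm(
    x = X, y = y, kernel = grid$kernel[best], cost = grid$cost[best],
    gamma = if (is.na(grid$gamma[best])) 1 / ncol(X) else grid$gamma[best],
    class.weights = wts, scale = FALSE
  )
  structure(list(
    model = fit, features = features, kernel = grid$kernel[best],
    cost = grid$cost[best],
    gamma = if (is.na(grid$gamma[best])) 1 / ncol(X) else grid$gamma[best],
    cv_accuracy = acc[best], center = zs$center, scale = zs$scale,
    zero_sd = zs$zero_sd, levels = levels(y),
    train_ids = data$subject_id,
    partition_hash = partition_hash(data$subject_id), empty = FALSE
  ), class = "svm_bundle")
}

bundle_matrix <- function(object, newdata) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stopf("subjects lack consensus feature(s): %s",
          paste(head(missing, 3), collapse = ", "))
  }
  X <- as.matrix(newdata[object$features])
  rownames(X) <- newdata$subject_id
  for (j in object$features) {
    X[, j] <- if (j %in% object$zero_sd) 0 else
      (X[, j] - object$center[[j]]) / object$scale[[j]]
  }
  X
}

#' Predict group labels from a fitted SVM bundle
#'
#' @param object An `svm_bundle` from [tune_and_train_svm()].
#' @param newdata Feature tibble containing every feature the bundle declares
#'   (missing features are an error, not silently imputed).
#' @param ... Unused.
#' @return Tibble: `subject_id`, `pred` (factor with the training levels).
#' @export
predict.svm_bundle <- function(object, newdata, ...) {
  if (isTRUE(object$empty)) stopf("no-model bundle: %s", object$reason)
  X <- bundle_matrix(object, newdata)
  tibble::tibble(subject_id = newdata$subject_id,
                 pred = stats::predict(object$model, X))
}

#' One-vs-rest decision scores from a fitted SVM bundle
#'
#' Aggregates the pairwise decision values of the multiclass SVM into one
#' score per class (signed votes in favour of the class), suitable for
#' one-vs-rest ROC analysis.
#'
#' @inheritParams predict.svm_bundle
#' @return Numeric matrix, subjects by classes.
#' @export
ovr_scores <- function(object, newdata) {
  if (isTRUE(object$empty)) stopf("no-model bundle: %s", object$reason)
  X <- bundle_matrix(object, newdata)
  dv <- attr(stats::predict(object$model, X, decision.values = TRUE),
             "decision.values")
  out <- matrix(0, nrow(X), length(object$levels),
                dimnames = list(newdata$subject_id, object$levels))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    out[, pair[1]] <- out[, pair[1]] + dv[, cn]
    out[, pair[2]] <- out[, pair[2]] - dv[, cn]
  }
  out
}

#' Nested cross-validated SVM with recursive RF feature selection
#'
#' The selection engine: for each outer fold of the training data, optionally
#' reduce the fold-training features by a raw-p univariate screen (two-step
#' mode), run [rrf_select()] on the fold-training part, tune and fit an SVM
#' on the selected features, and score the held-out fold (per-group
#' one-vs-rest and four-class accuracy). Consensus features are those
#' selected in at least `consensus_threshold` of the outer folds; the final
#' model is then trained on all training data with the consensus set (see
#' [tune_and_train_svm()]).
#'
#' @param data Training feature tibble (must exclude the holdout subjects).
#' @param n_folds Outer folds (default 10, stratified by group).
#' @param repeats Repetitions of the outer CV with fresh fold assignments.
#' @param two_step Apply the training-only raw-p screen inside each fold?
#' @param alpha_raw Raw-p threshold for the two-step screen.
#' @param consensus_threshold Minimum fraction of folds a feature must be
#'   selected in (default 0.5).
#' @param kernels,inner_folds Passed to [tune_and_train_svm()].
#' @param drop_frac,min_features,n_trees,error_estimate,se_mult Passed to
#'   [rrf_select()].
#' @param seed Integer seed; the full run is reproducible bit-for-bit.
#' @return A `cv_selection`: per-fold feature sets, per-fold per-group and
#'   four-class accuracies, consensus features, parameters, and the training
#'   partition hash.
#' @export
cv_svm_rrf_fs <- function(data, n_folds = 10, repeats = 1, two_step = FALSE,
                          alpha_raw = 0.05, consensus_threshold = 0.5,
                          drop_frac = 0.2, min_features = 2, n_trees = 500,
                          error_estimate = c("oob", "cv"), se_mult = 1,
                          kernels = c("linear", "radial"), inner_folds = 5,
                          seed = 1L) {
  error_estimate <- match.arg(error_estimate)
  check_feature_table(data)
  groups <- sort(unique(data$group))
  fold_features <- list(); accs <- list(); four <- numeric(); fold_id <- 0L
  for (rep in seq_len(repeats)) {
    fold <- stratified_folds(data$group, n_folds,
                             derive_seed(seed, "outer", rep))
    for (f in seq_len(n_folds)) {
      fold_id <- fold_id + 1L
      tr <- data[fold != f, ]; te <- data[fold == f, ]
      fseed <- derive_seed(seed, "fold", rep, f)
      feats <- feature_cols(tr)
      if (two_step) {
        ss <- screen_features(tr, alpha_raw, holdout_ids = te$subject_id)
        feats <- ss$features
      }
      if (length(feats) == 0) {
        fold_features[[fold_id]] <- character()
        accs[[fold_id]] <- tibble::tibble(fold = fold_id, group = groups,
                                          accuracy = NA_real_)
        four <- c(four, NA_real_)
        next
      }
      sel <- rrf_select(tr[c("subject_id", "group", feats)],
                        drop_frac = drop_frac, min_features = min(min_features, length(feats)),
                        n_trees = n_trees, error_estimate = error_estimate,
                        inner_folds = inner_folds, se_mult = se_mult,
                        seed = derive_seed(fseed, "rrf"))
      bundle <- tune_and_train_svm(tr, sel$selected, kernels = kernels,
                                   inner_folds = inner_folds,
                                   seed = derive_seed(fseed, "svm"))
      pred <- predict(bundle, te)$pred
      fold_features[[fold_id]] <- sel$selected
      pg <- per_group_accuracy(te$group, pred, groups = groups)
      pg$fold <- fold_id
      accs[[fold_id]] <- pg[c("fold", "group", "accuracy")]
      four <- c(four, 100 * mean(pred == te$group))
    }
  }
  all_feats <- feature_cols(data)
  counts <- table(factor(unlist(fold_features), levels = all_feats))
  consensus <- names(counts)[counts / fold_id >= consensus_threshold]
  structure(list(
    fold_features = fold_features,
    fold_accuracy = dplyr::bind_rows(accs),
    fourclass = tibble::tibble(fold = seq_along(four), accuracy = four),
    consensus = consensus, consensus_threshold = consensus_threshold,
    n_folds = n_folds, repeats = repeats, two_step = two_step,
    alpha_raw = alpha_raw, seed = as.integer(seed),
    partition_hash = partition_hash(data$subject_id)
  ), class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection> %d folds%s; consensus %d feature(s) at >= %.0f%% of folds; mean four-class CV accuracy %.1f%%\n",
              length(x$fold_features),
              if (x$two_step) " (two-step)" else "",
              length(x$consensus), 100 * x$consensus_threshold,
              mean(x$fourclass$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' PLS-DA verification of a selected feature set
#'
#' Fits partial least squares discriminant analysis on the selected features
#' as an independent classifier, reporting its stratified-CV accuracy and a
#' label-permutation p-value. When the permutation p is not significant the
#' feature set is flagged as suited to SVM modelling only (features that do
#' not generalise to an independent linear classifier).
#'
#' @param data Feature tibble.
#' @param features Feature ids to verify (consensus set).
#' @param n_components PLS components (default 3).
#' @param folds CV folds.
#' @param n_perm Label permutations.
#' @param alpha Significance level for the SVM-only flag.
#' @param seed Integer seed.
#' @return List: `cv_accuracy` (%), `perm_p`, `n_perm`, `svm_only` flag.
#' @export
plsda_verify <- function(data, features, n_components = 3, folds = 5,
                         n_perm = 199, alpha = 0.05, seed = 1L) {
  if (n_components < 1) stopf("`n_components` must be >= 1")
  if (length(features) < 2) stopf("PLS-DA verification needs >= 2 features")
  missing <- setdiff(features, names(data))
  if (length(missing)) stopf("features absent from data: %s",
                             paste(head(missing, 3), collapse = ", "))
  X <- as.matrix(data[features])
  y <- factor(data$group)
  if (n_components > min(dim(X))) stopf("`n_components` exceeds the data rank bound")
  cvacc <- function(yy, fseed) {
    fold <- stratified_folds(yy, folds, fseed)
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- mixOmics::plsda(X[tr, , drop = FALSE], yy[tr], ncomp = n_components)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE])
      cls <- pr$class$max.dist[, n_components]
      mean(cls == as.character(yy[!tr]))
    }, numeric(1)))
  }
  obs <- cvacc(y, derive_seed(seed, "obs"))
  perm <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) {
      cvacc(sample(y), derive_seed(seed, "permcv", b))
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(cv_accuracy = 100 * obs, perm_p = p, n_perm = n_perm,
       svm_only = p >= alpha)
}
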