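shifted4 <- function(n = 12, n_features = 30, delta = 3, seed = 1) {
  # four groups, four disjoint single-feature markers + noise
  toy_features(
    n_per_group = c(A = n, B = n, C = n, D = n), n_features = n_features,
    shifts = list(f001 = c(A = delta), f002 = c(B = delta),
                  f003 = c(C = delta), f004 = c(D = delta)),
    seed = seed
  )
}

test_that("random-forest ranking puts a label-determined feature first", {
  hits <- vapply(1:10, function(s) {
    d <- toy_features(n_features = 15, seed = 200 + s)
    d$f008 <- as.numeric(factor(d$group))          # label-determined
    rf_rank(d, n_trees = 200, seed = s)$feature[1] == "f008"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  d1 <- toy_features(seed = 1); d1$group <- "A"
  expect_error(rf_rank(d1), "two classes")
})

test_that("all-noise importance rankings are exchangeable across data redraws", {
  r1 <- rf_rank(toy_features(n_features = 40, seed = 31), n_trees = 300, seed = 1)
  r2 <- rf_rank(toy_features(n_features = 40, seed = 32), n_trees = 300, seed = 1)
  rho <- stats::cor(match(r1$feature, r2$feature), seq_len(40), method = "spearman")
  expect_lt(abs(rho), 0.5)
})

test_that("duplicated top features share the top ranks", {
  d <- shifted4(delta = 6, n_features = 10, seed = 5)
  d$f011 <- d$f001 + stats::rnorm(nrow(d), sd = 1e-3)
  rk <- rf_rank(d, n_trees = 500, seed = 3)
  expect_true(all(match(c("f001", "f011"), rk$feature) <= 6))
})

test_that("recursive elimination visits the documented size ladder", {
  d <- toy_features(n_features = 8, seed = 41)
  sel <- rrf_select(d, drop_frac = 0.5, min_features = 2, n_trees = 50, seed = 1)
  expect_equal(sel$path$size, c(8, 4, 2))
  expect_error(rrf_select(d, min_features = 100), "exceeds")
  expect_error(rrf_select(d, drop_frac = 1.2), "\\(0, 1\\)")
})

test_that("rRF-FS recovers planted informative features from noise", {
  d <- toy_features(
    n_per_group = c(A = 15, B = 15, C = 15, D = 15), n_features = 205,
    shifts = list(f001 = c(A = 4), f002 = c(B = 4), f003 = c(C = 4),
                  f004 = c(D = 4), f005 = c(A = 4, B = 4)),
    seed = 43
  )
  sel <- rrf_select(d, n_trees = 300, seed = 7)
  planted <- sprintf("f%03d", 1:5)
  expect_gte(sum(planted %in% sel$selected), 4)
  expect_lt(length(sel$selected), 50)
})

test_that("all-noise elimination ends near chance error", {
  d <- toy_features(n_features = 30, seed = 47)
  sel <- rrf_select(d, n_trees = 200, seed = 9)
  final_err <- sel$path$error[sel$path$size == sel$chosen_size]
  expect_gt(final_err, 0.5)   # four balanced classes: chance error 0.75
})

test_that("SVM tuning selects sensible kernels and enforces its contract", {
  # linearly separable: linear kernel, perfect tuning CV, parsimony tie-break
  d <- shifted4(delta = 8, n_features = 6, seed = 51)
  b <- tune_and_train_svm(d, sprintf("f%03d", 1:4), seed = 1)
  expect_equal(b$kernel, "linear")
  expect_equal(b$cv_accuracy, 1)
  # XOR structure: RBF beats linear
  xor <- withr::with_seed(53, {
    n <- 30
    x1 <- c(stats::rnorm(n, -2), stats::rnorm(n, 2), stats::rnorm(n, -2), stats::rnorm(n, 2))
    x2 <- c(stats::rnorm(n, -2), stats::rnorm(n, 2), stats::rnorm(n, 2), stats::rnorm(n, -2))
    tibble::tibble(subject_id = sprintf("S%03d", 1:(4 * n)),
                   group = rep(c("A", "A", "B", "B"), each = n),
                   f001 = x1, f002 = x2)
  })
  bx <- tune_and_train_svm(xor, c("f001", "f002"), seed = 2)
  expect_equal(bx$kernel, "radial")
  expect_gt(bx$cv_accuracy, 0.9)
  # contract: missing feature at prediction time errors; empty set -> no-model
  expect_error(predict(b, d[, c("subject_id", "group", "f001")]),
               "lack consensus feature")
  nm <- tune_and_train_svm(d, character(0))
  expect_s3_class(nm, "no_model")
  expect_error(predict(nm, d), "no-model")
})

test_that("nested CV selection recovers planted structure with high accuracy", {
  d <- shifted4(n = 15, delta = 4, n_features = 40, seed = 61)
  res <- cv_svm_rrf_fs(d, n_folds = 5, n_trees = 200, seed = 3)
  expect_gte(sum(sprintf("f%03d", 1:4) %in% res$consensus), 3)
  acc <- res$fold_accuracy
  expect_true(all(tapply(acc$accuracy, acc$group, mean) > 80))
  expect_true(all(res$fold_accuracy$accuracy >= 0 & res$fold_accuracy$accuracy <= 100))
  # repeat with the same seed: bit-identical result
  res2 <- cv_svm_rrf_fs(d, n_folds = 5, n_trees = 200, seed = 3)
  expect_identical(res, res2)
})

test_that("shuffled labels bring four-class CV accuracy to chance", {
  d <- shifted4(n = 12, delta = 4, n_features = 20, seed = 67)
  d$group <- withr::with_seed(1, sample(d$group))
  res <- cv_svm_rrf_fs(d, n_folds = 4, n_trees = 100, seed = 5)
  expect_lt(mean(res$fourclass$accuracy), 50)   # chance is 25%
})

test_that("two-step mode screens inside each fold and tolerates empty screens", {
  d <- shifted4(n = 12, delta = 5, n_features = 30, seed = 71)
  res <- cv_svm_rrf_fs(d, n_folds = 4, two_step = TRUE, alpha_raw = 0.05,
                       n_trees = 100, seed = 7)
  expect_gte(sum(sprintf("f%03d", 1:4) %in% res$consensus), 3)
  # alpha_raw = 0 empties every fold screen: reported, not an error
  res0 <- cv_svm_rrf_fs(d, n_folds = 4, two_step = TRUE, alpha_raw = 0,
                        n_trees = 100, seed = 7)
  expect_length(res0$consensus, 0)
  expect_true(all(is.na(res0$fourclass$accuracy)))
})

test_that("PLS-DA verification separates structure from noise deterministically", {
  d <- shifted4(n = 12, delta = 5, n_features = 8, seed = 73)
  v <- plsda_verify(d, sprintf("f%03d", 1:4), n_perm = 49, seed = 1)
  expect_lt(v$perm_p, 0.05)
  expect_false(v$svm_only)
  expect_gt(v$cv_accuracy, 80)
  v2 <- plsda_verify(d, sprintf("f%03d", 1:4), n_perm = 49, seed = 1)
  expect_identical(v, v2)
  noise <- toy_features(n_features = 8, seed = 79)
  vn <- plsda_verify(noise, sprintf("f%03d", 1:4), n_perm = 49, seed = 2)
  expect_gt(vn$perm_p, 0.05)
  expect_true(vn$svm_only)
  expect_error(plsda_verify(d, sprintf("f%03d", 1:4), n_components = 0), ">= 1")
})
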