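ref_labels <- function() {
  tibble::tibble(
    subject_id = sprintf("S%03d", 1:101),
    group = rep(c("PTSD", "TC", "mTBI", "NTC"), c(24, 27, 27, 23)),
    f001 = stats::rnorm(101)
  )
}

test_that("the 85/15 split reproduces the reference cohort arithmetic", {
  d <- withr::with_seed(1, ref_labels())
  sp <- stratified_split(d, 0.85, seed = 4)
  expect_length(sp$train_ids, 86)
  expect_length(sp$holdout_ids, 15)
  expect_length(intersect(sp$train_ids, sp$holdout_ids), 0)
  expect_setequal(c(sp$train_ids, sp$holdout_ids), d$subject_id)
  # per-group training counts within one subject of fraction * n_g
  tr <- table(d$group[d$subject_id %in% sp$train_ids])
  expect_true(all(abs(tr - 0.85 * table(d$group)) <= 1))
  ho <- table(d$group[d$subject_id %in% sp$holdout_ids])
  expect_true(all(ho >= 1))
  expect_identical(sp, stratified_split(d, 0.85, seed = 4))
  expect_false(identical(sp$train_ids, stratified_split(d, 0.85, seed = 5)$train_ids))
  expect_error(stratified_split(d, 1.2), "\\(0, 1\\)")
  d1 <- d[c(1, 25:101), ]  # PTSD reduced to one subject
  expect_error(stratified_split(d1), ">= 2 subjects")
})

test_that("per-group one-vs-rest accuracy matches closed forms", {
  truth <- rep(c("A", "B", "C", "D"), c(4, 4, 4, 2))
  expect_true(all(per_group_accuracy(truth, truth)$accuracy == 100))
  # an always-"rest" predictor: accuracy = 100 * (1 - group fraction)
  rest <- rep("Z", length(truth))
  acc <- per_group_accuracy(truth, rest, groups = c("A", "B", "C", "D"))
  expect_equal(acc$accuracy, 100 * (1 - c(4, 4, 4, 2) / 14))
  # one wrong of 14 binarised decisions
  pred <- truth; pred[1] <- "B"
  acc2 <- per_group_accuracy(truth, pred)
  expect_equal(acc2$accuracy[acc2$group == "C"], 100)
  expect_equal(acc2$accuracy[acc2$group == "A"], 100 * 13 / 14, tolerance = 1e-10)
  expect_error(per_group_accuracy(truth, truth[1:3]), "aligned")
  expect_error(per_group_accuracy(truth, truth, groups = "E"), "unknown group")
})

test_that("one-vs-rest AUC agrees with brute-force pair counting", {
  truth <- c("A", "A", "A", "B", "B", "B")
  scores <- cbind(A = c(3, 2.5, 2, 1, 0.5, 0), B = c(0, 1, 1, 1, 2, 3))
  res <- ovr_auc(truth, scores)
  expect_equal(res$auc[res$group == "A"], 1)
  expect_equal(res$auc[res$group == "B"],
               auc_bruteforce(scores[truth == "B", "B"],
                              scores[truth != "B", "B"]))
  # tied toy with midranks
  s2 <- cbind(A = c(1, 1, 2, 1, 2, 0), B = rep(0, 6))
  res2 <- ovr_auc(truth, s2)
  expect_equal(res2$auc[res2$group == "A"],
               auc_bruteforce(s2[truth == "A", "A"], s2[truth != "A", "A"]))
  # label-independent scores hover at 0.5
  big <- withr::with_seed(8, {
    tr <- sample(c("A", "B"), 2000, replace = TRUE)
    list(truth = tr, scores = cbind(A = stats::rnorm(2000), B = stats::rnorm(2000)))
  })
  resr <- ovr_auc(big$truth, big$scores)
  expect_equal(resr$auc, c(0.5, 0.5), tolerance = 0.05, ignore_attr = TRUE)
  # absent class is undefined
  resa <- ovr_auc(rep("A", 6), scores)
  expect_true(is.na(resa$auc[resa$group == "B"]))
})

test_that("permutation p-values follow the +1 formula and are calibrated", {
  d <- toy_features(n_per_group = c(A = 5, B = 5, C = 5, D = 5),
                    n_features = 2, seed = 1)
  orig <- d$group
  # statistic that only the unpermuted labels maximise -> 0 exceedances
  stat <- function(x) as.numeric(identical(x$group, orig))
  expect_equal(permutation_test(d, stat, n_perm = 999, seed = 1)$p_value, 0.001)
  # constant statistic: every permutation ties the observed value -> p = 1
  expect_equal(permutation_test(d, function(x) 1, n_perm = 99, seed = 1)$p_value, 1)
  expect_error(permutation_test(d, stat, n_perm = 0), ">= 1")
  # null calibration of a location statistic
  ps <- vapply(1:120, function(r) {
    dn <- toy_features(n_per_group = c(A = 8, B = 8, C = 8, D = 8),
                       n_features = 1, seed = 500 + r)
    permutation_test(dn, function(x) mean(x$f001[x$group == "A"]),
                     n_perm = 39, seed = r)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.1)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.12)
})

test_that("holdout evaluation enforces partition integrity and provenance", {
  d <- toy_features(n_per_group = c(A = 14, B = 14, C = 14, D = 14),
                    n_features = 8,
                    shifts = list(f001 = c(A = 5), f002 = c(B = 5),
                                  f003 = c(C = 5), f004 = c(D = 5)),
                    seed = 91)
  sp <- stratified_split(d, 0.8, seed = 2)
  train <- d[d$subject_id %in% sp$train_ids, ]
  hold <- d[d$subject_id %in% sp$holdout_ids, ]
  b <- tune_and_train_svm(train, sprintf("f%03d", 1:4), seed = 3)
  ev <- evaluate_holdout(b, hold, sp)
  expect_true(all(ev$per_group$accuracy >= 0 & ev$per_group$accuracy <= 100))
  expect_true(all(ev$per_group$auc >= 0 & ev$per_group$auc <= 1, na.rm = TRUE))
  # confusion marginals equal the true holdout group counts
  expect_equal(as.integer(rowSums(ev$confusion)),
               as.integer(table(hold$group)))
  expect_equal(sum(ev$confusion), nrow(hold))
  # evaluating twice gives an identical report
  expect_identical(ev, evaluate_holdout(b, hold, sp))
  # leakage: training subject in the holdout set
  expect_error(evaluate_holdout(b, rbind(hold, train[1, ]), sp), "leakage")
  # tampered partition hash
  sp_bad <- sp; sp_bad$partition_hash <- "deadbeef"
  expect_error(evaluate_holdout(b, hold, sp_bad), "hash mismatch")
})

test_that("strong planted structure yields high holdout performance", {
  d <- toy_features(n_per_group = c(A = 14, B = 14, C = 14, D = 14),
                    n_features = 8,
                    shifts = list(f001 = c(A = 6), f002 = c(B = 6),
                                  f003 = c(C = 6), f004 = c(D = 6)),
                    seed = 97)
  run <- run_pipeline(d, fraction = 0.8, n_folds = 5, n_trees = 200, seed = 11)
  expect_true(all(tidy(run)$accuracy > 70))
  g <- glance(run)
  expect_gt(g$cv_accuracy_mean, 70)
  expect_equal(g$n_folds, 5)
})
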