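test_that("vectorised ANOVA agrees with stats::oneway.test", {
  d <- toy_features(n_features = 6, seed = 3)
  res <- screen_univariate(d)
  for (f in c("f001", "f004", "f006")) {
    ref <- stats::oneway.test(d[[f]] ~ d$group, var.equal = TRUE)
    row <- res[res$feature == f, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p_raw, ref$p.value, tolerance = 1e-10)
  }
  # Kruskal-Wallis option matches the base implementation
  resk <- screen_univariate(d, test = "kruskal")
  refk <- stats::kruskal.test(d$f002, factor(d$group))
  rowk <- resk[resk$feature == "f002", ]
  expect_equal(rowk$statistic, unname(refk$statistic), tolerance = 1e-10)
  expect_equal(rowk$p_raw, refk$p.value, tolerance = 1e-10)
})

test_that("screening has power against a planted shift and handles degeneracy", {
  d <- toy_features(n_per_group = c(A = 20, B = 20, C = 20, D = 20),
                    n_features = 5, shifts = list(f002 = c(A = 5)), seed = 7)
  res <- screen_univariate(d)
  expect_lt(res$p_raw[res$feature == "f002"], 1e-6)
  d$f005 <- 1
  expect_warning(res2 <- screen_univariate(d), "zero-variance")
  expect_equal(res2$p_raw[res2$feature == "f005"], 1)
  d2 <- d[d$group %in% c("A", "B"), ][1:21, ]  # one group with 1 subject
  d2$group <- c(rep("A", 20), "B")
  expect_error(screen_univariate(d2), "at least two subjects")
})

test_that("null p-values are approximately uniform", {
  d <- toy_features(n_per_group = c(A = 15, B = 15, C = 15, D = 15),
                    n_features = 400, seed = 11)
  res <- screen_univariate(d)
  expect_gt(stats::ks.test(res$p_raw, "punif")$p.value, 0.01)
  expect_lt(abs(mean(res$p_raw < 0.05) - 0.05), 0.035)
})

test_that("BH adjustment matches hand-computed and degenerate cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, NA)), "finite")
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in p-value rank
  p <- withr::with_seed(1, stats::runif(30))
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("raw-p reduction keeps ~alpha*m null features and all strong ones", {
  d <- toy_features(n_per_group = c(A = 15, B = 15, C = 15, D = 15),
                    n_features = 500, seed = 13)
  ss <- screen_features(d, alpha_raw = 0.05)
  expect_true(abs(length(ss$features) - 25) < 20)  # Binomial(500, 0.05)
  expect_length(screen_features(d, alpha_raw = 0)$features, 0)
  for (sd_ in 1:3) {
    d2 <- toy_features(n_per_group = c(A = 15, B = 15, C = 15, D = 15),
                       n_features = 50, shifts = list(f010 = c(B = 4)),
                       seed = 100 + sd_)
    expect_true("f010" %in% screen_features(d2, 0.05)$features)
  }
})

test_that("screening refuses data containing holdout subjects", {
  d <- toy_features(seed = 1)
  expect_error(screen_features(d, holdout_ids = c("S001", "S020")), "leakage")
  ok <- screen_features(d[-(1:2), ], holdout_ids = c("S001", "S002"))
  expect_s3_class(ok, "screen_set")
  expect_identical(ok$partition_hash,
                   rlang::hash(sort(d$subject_id[-(1:2)])))
})

test_that("z-scoring uses training statistics only", {
  d <- toy_features(n_features = 4, seed = 5)
  fit_ids <- d$subject_id[1:30]
  zs <- zscore_fit_transform(d, fit_ids)
  fit_rows <- zs$data$subject_id %in% fit_ids
  X <- as.matrix(zs$data[fit_rows, -(1:2)])
  expect_equal(unname(colMeans(X)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, stats::sd)), rep(1, 4), tolerance = 1e-12)
  # holdout rows standardised with training stats differ from their own z-scores
  hold <- !fit_rows
  own <- scale(as.matrix(d[hold, -(1:2)]))
  expect_false(isTRUE(all.equal(as.matrix(zs$data[hold, -(1:2)]), own,
                                check.attributes = FALSE)))
  d$f001 <- 2
  zs2 <- zscore_fit_transform(d, fit_ids)
  expect_equal(zs2$zero_sd, "f001")
  expect_true(all(zs2$data$f001 == 0))
})

test_that("hierarchical clustering separates blobs and not noise", {
  blob <- toy_features(n_per_group = c(A = 10, B = 10, C = 10, D = 10),
                       n_features = 8,
                       shifts = sapply(sprintf("f%03d", 1:8), function(f)
                         c(A = 6, B = -6, C = 12, D = -12)[],
                         simplify = FALSE),
                       seed = 17)
  hc <- hierarchical_cluster(zscore_fit_transform(blob)$data)
  expect_equal(hc$ari, 1)
  noise <- toy_features(n_features = 8, seed = 19)
  hcn <- hierarchical_cluster(zscore_fit_transform(noise)$data)
  expect_lt(abs(hcn$ari), 0.2)
  expect_error(hierarchical_cluster(noise[1, ]), "at least two")
})

test_that("PCA scores expose rank structure and ordered variance fractions", {
  d <- toy_features(n_features = 6, seed = 23)
  # rank-1 data: a single component explains everything
  v <- withr::with_seed(2, stats::rnorm(nrow(d)))
  rank1 <- d
  for (j in 1:6) rank1[[sprintf("f%03d", j)]] <- v * j
  p1 <- pca_scores(rank1, k = 2)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)
  pc <- pca_scores(d, k = 5)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  # reconstruction error decreases with k (SVD oracle)
  X <- scale(as.matrix(d[-(1:2)]), scale = FALSE)
  sv <- svd(X)
  recon_err <- vapply(1:4, function(k) {
    Xk <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sum((X - Xk)^2)
  }, numeric(1))
  expect_true(all(diff(recon_err) < 0))
  expect_error(pca_scores(d, k = 0), ">= 1")
  expect_error(pca_scores(d, k = 100), "exceeds")
})
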