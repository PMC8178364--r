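#' Univariate group screening of a feature table
#'
#' Tests every feature for a four-group location difference (one-way ANOVA F
#' by default; Kruskal--Wallis as the nonparametric option) and attaches
#' Benjamini--Hochberg adjusted p-values. Zero-variance features are
#' degenerate and reported with `p_raw = 1` (with a warning).
#'
#' The ANOVA F statistics are computed vectorised across all features
#' (several thousand edges per band) and agree with [stats::oneway.test()]
#' with equal variances assumed.
#'
#' @param data Feature tibble with `subject_id`, `group` and numeric feature
#'   columns.
#' @param test `"anova"` or `"kruskal"`.
#' @return Tibble: `feature`, `statistic`, `p_raw`, `p_fdr`, ordered as the
#'   input columns.
#' @export
screen_univariate <- function(data, test = c("anova", "kruskal")) {
  test <- match.arg(test)
  feats <- check_feature_table(data)
  g <- as.factor(data$group)
  if (nlevels(g) < 2) stopf("need at least two groups")
  if (min(table(g)) < 2) stopf("every group needs at least two subjects")
  X <- as_feature_matrix(data)
  n <- nrow(X); k <- nlevels(g)
  if (test == "anova") {
    gm <- colMeans(X)
    ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
    for (lev in levels(g)) {
      idx <- which(g == lev)
      mu <- colMeans(X[idx, , drop = FALSE])
      ssb <- ssb + length(idx) * (mu - gm)^2
      ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, mu)^2)
    }
    stat <- (ssb / (k - 1)) / (ssw / (n - k))
    p <- stats::pf(stat, k - 1, n - k, lower.tail = FALSE)
  } else {
    res <- apply(X, 2, function(v) {
      if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
      kt <- stats::kruskal.test(v, g)
      c(unname(kt$statistic), kt$p.value)
    })
    stat <- res[1, ]; p <- res[2, ]
  }
  # 0/0 (zero variance overall) is degenerate; Inf (within-group variance 0,
  # groups distinct) is a real, maximal effect with p = 0.
  const <- is.nan(stat) | is.na(stat)
  if (any(const)) {
    rlang::warn(sprintf("%d zero-variance feature(s); their p set to 1", sum(const)))
    stat[const] <- 0
    p[const] <- 1
  }
  tibble::tibble(feature = feats, statistic = unname(stat),
                 p_raw = unname(p), p_fdr = fdr_adjust(unname(p)))
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone in p-value rank.
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw))) stopf("p-values must be finite (no NA/NaN)")
  if (any(p_raw < 0 | p_raw > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Training-only raw-p feature reduction
#'
#' The first step of the two-step pipeline: keep the features whose raw
#' univariate p-value falls below `alpha_raw`, computed on training subjects
#' only. Passing the holdout ids lets the function enforce the no-leakage
#' contract: if any holdout subject appears in `data` the call errors.
#'
#' @param data Training-subject feature tibble.
#' @param alpha_raw Raw p-value threshold (default 0.05). An empty selection
#'   is permitted and reported.
#' @param test Univariate test, see [screen_univariate()].
#' @param holdout_ids Optional subject ids that must not be present.
#' @return A `screen_set`: list with `features`, `alpha_raw`, `test`,
#'   `n_tested` and the training `partition_hash`.
#' @export
screen_features <- function(data, alpha_raw = 0.05,
                            test = c("anova", "kruskal"),
                            holdout_ids = NULL) {
  test <- match.arg(test)
  if (!is.null(holdout_ids)) {
    leak <- intersect(data$subject_id, holdout_ids)
    if (length(leak)) {
      stopf("leakage: holdout subject(s) present in screening data (%s%s)",
            paste(head(leak, 3), collapse = ", "),
            if (length(leak) > 3) ", ..." else "")
    }
  }
  res <- screen_univariate(data, test)
  keep <- res$feature[res$p_raw < alpha_raw]
  structure(list(features = keep, alpha_raw = alpha_raw, test = test,
                 n_tested = nrow(res),
                 partition_hash = partition_hash(data$subject_id)),
            class = "screen_set")
}

#' @export
print.screen_set <- function(x, ...) {
  cat(sprintf("<screen_set> %d / %d features at raw p < %g (%s)\n",
              length(x$features), x$n_tested, x$alpha_raw, x$test))
  invisible(x)
}

#' Z-score features using training statistics only
#'
#' Fits per-feature means and SDs on the `fit_ids` rows and applies them to
#' every row, so holdout subjects are standardised with training statistics.
#' Zero-SD features are flagged and mapped to 0.
#'
#' @param data Feature tibble.
#' @param fit_ids Subject ids the statistics are computed from (default: all).
#' @return List: `data` (standardised tibble), `center`, `scale`, `fit_ids`,
#'   `zero_sd` (flagged feature names).
#' @export
zscore_fit_transform <- function(data, fit_ids = data$subject_id) {
  feats <- check_feature_table(data, require_group = FALSE)
  if (!all(fit_ids %in% data$subject_id)) stopf("fit_ids must be a subset of data$subject_id")
  fit <- data[data$subject_id %in% fit_ids, feats, drop = FALSE]
  ctr <- vapply(fit, mean, numeric(1))
  scl <- vapply(fit, stats::sd, numeric(1))
  zero <- names(scl)[scl == 0 | !is.finite(scl)]
  out <- data
  for (f in feats) {
    out[[f]] <- if (f %in% zero) 0 else (data[[f]] - ctr[[f]]) / scl[[f]]
  }
  list(data = out, center = ctr, scale = scl, fit_ids = fit_ids, zero_sd = zero)
}

#' Two-way hierarchical clustering of a standardised feature table
#'
#' Agglomerative clustering of subjects (Euclidean distance, Ward linkage)
#' and of features (correlation distance, average linkage), as used to ask
#' whether univariate-reduced features separate the groups. When `group`
#' labels are available the agreement between the top-level subject clusters
#' and the true groups is reported as the adjusted Rand index.
#'
#' @param data Standardised feature tibble (see [zscore_fit_transform()]).
#' @param k Number of top-level subject clusters to cut (default: number of
#'   groups, or 2).
#' @return List: `hc_subjects`, `hc_features` (hclust objects), `clusters`
#'   (tibble subject_id/cluster), `ari` (NA without labels).
#' @export
hierarchical_cluster <- function(data, k = NULL) {
  feats <- check_feature_table(data, require_group = FALSE)
  X <- as_feature_matrix(data)
  if (nrow(X) < 2) stopf("need at least two subjects to cluster")
  if (any(!is.finite(X))) stopf("non-finite entries in the feature matrix")
  hs <- stats::hclust(stats::dist(X), method = "ward.D2")
  hf <- if (ncol(X) >= 2) {
    cs <- suppressWarnings(stats::cor(X))
    cs[!is.finite(cs)] <- 0
    stats::hclust(stats::as.dist(1 - cs), method = "average")
  } else {
    NULL
  }
  has_groups <- "group" %in% names(data)
  if (is.null(k)) k <- if (has_groups) length(unique(data$group)) else 2L
  cl <- stats::cutree(hs, k = min(k, nrow(X)))
  ari <- if (has_groups) mclust::adjustedRandIndex(cl, data$group) else NA_real_
  list(hc_subjects = hs, hc_features = hf,
       clusters = tibble::tibble(subject_id = data$subject_id, cluster = unname(cl)),
       ari = ari)
}

#' PCA scores of a standardised feature table
#'
#' @param data Standardised feature tibble.
#' @param k Number of components (1 <= k <= min(subjects, features)).
#' @return List: `scores` (tibble with `subject_id`, `group` if present, and
#'   `PC1..PCk`), `var_explained` (fractions, non-increasing, summing to <= 1).
#' @export
pca_scores <- function(data, k = 3) {
  feats <- check_feature_table(data, require_group = FALSE)
  X <- as_feature_matrix(data)
  if (k < 1) stopf("`k` must be >= 1")
  if (k > min(dim(X))) stopf("`k` exceeds min(subjects, features) = %d", min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  sc <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  sc <- dplyr::bind_cols(
    tibble::tibble(subject_id = data$subject_id),
    if ("group" %in% names(data)) tibble::tibble(group = data$group),
    sc
  )
  list(scores = sc, var_explained = ve[seq_len(k)])
}
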