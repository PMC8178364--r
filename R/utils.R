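#' @importFrom rlang abort warn hash .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Deterministic integer seed derived from a master seed and any tags.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  h <- rlang::hash(list(as.integer(seed), ...))
  strtoi(substr(h, 1, 7), base = 16L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Hash of a subject-id partition, order-insensitive.
partition_hash <- function(ids) rlang::hash(sort(as.character(ids)))

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

# Columns of a feature table that hold features (everything except metadata).
feature_cols <- function(data) {
  setdiff(names(data), c("subject_id", "group"))
}

# Validate a subjects-by-features tibble: subject_id + group + numeric columns.
check_feature_table <- function(data, require_group = TRUE) {
  if (!is.data.frame(data)) stopf("`data` must be a data frame of features")
  if (!"subject_id" %in% names(data)) stopf("`data` must have a `subject_id` column")
  if (require_group && !"group" %in% names(data)) {
    stopf("`data` must have a `group` column")
  }
  feats <- feature_cols(data)
  if (length(feats) == 0L) stopf("`data` contains no feature columns")
  bad <- feats[!vapply(data[feats], is.numeric, logical(1))]
  if (length(bad)) stopf("non-numeric feature columns: %s", paste(head(bad, 3), collapse = ", "))
  invisible(feats)
}

as_feature_matrix <- function(data) {
  feats <- feature_cols(data)
  m <- as.matrix(data[feats])
  rownames(m) <- data$subject_id
  m
}

# Stratified fold assignment: every group is spread as evenly as possible
# across folds. Errors if a fold would miss a group entirely.
stratified_folds <- function(groups, n_folds, seed) {
  groups <- as.factor(groups)
  if (min(table(groups)) < n_folds) {
    stopf("stratified %d-fold CV needs >= %d subjects per group (smallest group has %d)",
          n_folds, n_folds, min(table(groups)))
  }
  fold <- integer(length(groups))
  with_seed(seed, {
    for (g in levels(groups)) {
      idx <- sample(which(groups == g))
      fold[idx] <- rep_len(sample(n_folds), length(idx))
    }
  })
  fold
}
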