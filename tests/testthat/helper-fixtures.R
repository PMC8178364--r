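# Shared fixtures: everything is generated in code at test time.

# A bare recording from a list of samples x regions epoch matrices.
mk_recording <- function(epochs, fs, subject_id = "T01", group = "X") {
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 epochs = epochs), class = "meg_recording")
}

# Small alpha-band cohort config for signal-level tests.
tiny_config <- function(n = c(PTSD = 4, TC = 4, mTBI = 4, NTC = 4),
                        n_regions = 4, fs = 80, n_epochs = 2, seed = 1L, ...) {
  cohort_config(n_per_group = n, n_regions = n_regions, fs = fs,
                n_epochs = n_epochs, bands = meg_bands("alpha"),
                base_amplitudes = c(alpha = 1), seed = seed, ...)
}

# Gaussian feature table with optional group-specific mean shifts: fast
# stand-in for the signal pipeline in selection/evaluation tests.
# `shifts` is a named list feature -> c(group = delta).
toy_features <- function(n_per_group = c(A = 12, B = 12, C = 12, D = 12),
                         n_features = 10, shifts = list(), seed = 1L,
                         prefix = "f") {
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    colnames(X) <- sprintf("%s%03d", prefix, seq_len(n_features))
    for (f in names(shifts)) {
      for (g in names(shifts[[f]])) {
        X[groups == g, f] <- X[groups == g, f] + shifts[[f]][[g]]
      }
    }
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), group = groups),
      tibble::as_tibble(X)
    )
  })
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# p_(k) * m / k, cumulative minimum from the largest rank down, clipped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[ord[k]] * m / k)
    adj[ord[k]] <- running
  }
  pmin(adj, 1)
}

# Brute-force ROC AUC by pair counting with midrank ties.
auc_bruteforce <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos_scores) * length(neg_scores))
}
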