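#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_boxplot
#'   geom_point geom_col geom_abline labs scale_y_log10 scale_fill_gradient2
#'   facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a Welch PSD
#'
#' One line per ROI on a log power axis, with the canonical band edges
#' implied by the x-range.
#'
#' @param object A `meg_psd` from [welch_psd()].
#' @param regions ROI indices to draw (default: up to 8).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meg_psd
#' @export
autoplot.meg_psd <- function(object, regions = NULL, ...) {
  if (is.null(regions)) regions <- seq_len(min(8, ncol(object$density)))
  df <- purrr::map_dfr(regions, function(r) {
    tibble::tibble(freq = object$freqs, density = object$density[, r],
                   region = factor(r))
  })
  ggplot(df, aes(x = .data$freq, y = .data$density, colour = .data$region)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "Frequency (Hz)", y = "PSD (power/Hz)",
         title = sprintf("Welch PSD — %s", object$subject_id)) +
    theme_minimal()
}

#' Plot an AEC connectome matrix
#'
#' @param object A `meg_aec` from [aec_matrix()].
#' @param ... Unused.
#' @return A ggplot heatmap of the symmetric edge matrix.
#' @method autoplot meg_aec
#' @export
autoplot.meg_aec <- function(object, ...) {
  n <- nrow(object)
  df <- tibble::tibble(roi_i = rep(seq_len(n), times = n),
                       roi_j = rep(seq_len(n), each = n),
                       aec = as.numeric(unclass(object)))
  ggplot(df, aes(x = .data$roi_j, y = .data$roi_i, fill = .data$aec)) +
    geom_raster() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "ROI", y = "ROI",
         title = sprintf("AEC (%s) — %s", attr(object, "band"),
                         attr(object, "subject_id"))) +
    theme_minimal()
}

#' Plot per-group CV accuracies of a selection run
#'
#' Boxplots of the per-fold one-vs-rest accuracy for each group.
#'
#' @param object A `cv_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_selection
#' @export
autoplot.cv_selection <- function(object, ...) {
  ggplot(object$fold_accuracy,
         aes(x = .data$group, y = .data$accuracy)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.15, seed = 1),
               alpha = 0.6) +
    labs(x = NULL, y = "Per-group CV accuracy (%)",
         title = sprintf("CV-SVM-rRF-FS: %d consensus feature(s)",
                         length(object$consensus))) +
    theme_minimal()
}

#' Plot holdout one-vs-rest ROC curves
#'
#' @param object A `meg_eval` from [evaluate_holdout()].
#' @param ... Unused.
#' @return A ggplot with one ROC curve per group (AUC in the strip label).
#' @method autoplot meg_eval
#' @export
autoplot.meg_eval <- function(object, ...) {
  df <- purrr::map_dfr(colnames(object$scores), function(g) {
    resp <- factor(ifelse(object$predictions$truth == g, "pos", "neg"),
                   levels = c("neg", "pos"))
    if (length(unique(resp)) < 2) return(NULL)
    rc <- pROC::roc(resp, object$scores[, g], quiet = TRUE, direction = "<",
                    levels = c("neg", "pos"))
    auc <- object$per_group$auc[object$per_group$group == g]
    tibble::tibble(group = sprintf("%s (AUC %.2f)", g, auc),
                   fpr = 1 - rc$specificities, tpr = rc$sensitivities)
  })
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(linetype = "dashed", colour = "grey60") +
    facet_wrap(~group) +
    labs(x = "False positive rate", y = "True positive rate",
         title = "Holdout one-vs-rest ROC") +
    theme_minimal()
}

#' Plot the recursive-elimination error path
#'
#' @param object An `rrf_select`.
#' @param ... Unused.
#' @return A ggplot of error (with SE ribbon) against feature-set size.
#' @method autoplot rrf_select
#' @export
autoplot.rrf_select <- function(object, ...) {
  ggplot(object$path, aes(x = .data$size, y = .data$error)) +
    ggplot2::geom_ribbon(aes(ymin = .data$error - .data$se,
                             ymax = .data$error + .data$se), alpha = 0.2) +
    geom_line() +
    geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_size, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "Features remaining", y = "Classification error",
         title = sprintf("rRF-FS path (chosen size %d)", object$chosen_size)) +
    theme_minimal()
}
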