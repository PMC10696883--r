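#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_abline geom_tile geom_errorbar labs theme_bw scale_fill_gradient2
#'   geom_hline facet_wrap
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey50") +
    geom_line() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    theme_bw()
}

#' Plot training history of a fitted model
#'
#' @param object A trained `crnn_model`.
#' @param ... Unused.
#' @return A ggplot object with loss curves and validation AUC.
#' @export
autoplot.crnn_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss", "val_auc"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    labs(x = "Epoch", y = NULL, title = "Training history") +
    theme_bw()
}

#' Plot binned AUC against ChIP-Seq signal strength
#'
#' Mean AUC per ChIP-score bin with a +/- 1 sd ribbon over the negative
#' redraws, bins ordered from strongest to weakest signal.
#'
#' @param object A `binned_auc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_auc_result <- function(object, ...) {
  b <- object$bins
  ggplot(b, aes(x = .data$bin, y = .data$mean_auc)) +
    geom_ribbon(aes(ymin = .data$mean_auc - .data$sd_auc,
                    ymax = .data$mean_auc + .data$sd_auc),
                fill = "grey80") +
    geom_line() + geom_point() +
    geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey50") +
    labs(x = "Bin (decreasing ChIP-Seq score)", y = "Mean ROC-AUC",
         title = sprintf("Binned AUC (%d repeats of %d negatives)",
                         object$repeats, object$n_neg_per_repeat)) +
    theme_bw()
}

#' Heatmap of saturation-mutagenesis effects
#'
#' Per-position, per-alternative-base score deltas of every single
#' nucleotide variant; blue marks variants predicted to weaken binding,
#' red variants predicted to strengthen it.
#'
#' @param effects Variant tibble from [saturation_mutagenesis()].
#' @return A ggplot object.
#' @export
plot_saturation_mutagenesis <- function(effects) {
  ggplot(effects, aes(x = .data$position, y = .data$alt_base,
                      fill = .data$delta)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "Position (1-based)", y = "Alternative base",
         fill = "Δ score",
         title = unique(effects$parent_id)) +
    theme_bw()
}

#' Score versus dissociation constant scatter plot
#'
#' Censored (NBD) records are drawn at the imputed value with an open
#' symbol; the dotted line marks the detection threshold.
#'
#' @param scores Tibble with `ligand_id` and `score`.
#' @param affinities Affinity tibble (`ligand_id`, `kd`, `censored`).
#' @param censored_value Imputed Kd for censored records (uM).
#' @param detection_threshold Detection threshold (uM).
#' @return A ggplot object.
#' @export
plot_affinity_correlation <- function(scores, affinities,
                                      censored_value = 10,
                                      detection_threshold = 9) {
  d <- left_join(affinities, scores, by = "ligand_id") |>
    mutate(kd_plot = ifelse(.data$censored, censored_value, .data$kd))
  ggplot(d, aes(x = .data$score, y = .data$kd_plot,
                shape = .data$censored)) +
    geom_hline(yintercept = detection_threshold, linetype = "dotted",
               colour = "grey50") +
    geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    labs(x = "Predicted binding score", y = "Kd (µM)",
         shape = "Censored (NBD)") +
    theme_bw()
}
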