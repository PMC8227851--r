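#' Plot a variable-importance ranking
#'
#' Bar chart of mean variable importance in rank order, with the selection
#' cutoff drawn as a dashed line.
#'
#' @param object An `ec_importance`.
#' @param cutoff Selection cutoff to draw (default 0.003).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ec_importance
#' @export
autoplot.ec_importance <- function(object, cutoff = 0.003, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, -.data$mean_importance),
    y = .data$mean_importance
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = NULL, y = "mean variable importance",
      title = "Resampled multi-model variable importance"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot LOOCV predictions
#'
#' Quantitative system: predicted vs observed PIE-score.  Categorical
#' systems: predicted probability of the observed category by truth.
#'
#' @param object An `ec_loocv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ec_loocv
#' @export
autoplot.ec_loocv <- function(object, ...) {
  pred <- object$predictions
  if (object$system == "quantitative") {
    return(
      ggplot2::ggplot(pred, ggplot2::aes(.data$pie_obs, .data$pie_pred)) +
        ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
        ggplot2::labs(
          x = "observed PIE-score", y = "LOOCV predicted PIE-score",
          title = paste0("Quantitative LOOCV, panel ", object$panel_name)
        ) +
        ggplot2::theme_minimal()
    )
  }
  cats <- levels(pred$truth)
  P <- as.matrix(pred[paste0("p_", cats)])
  pred$p_truth <- P[cbind(seq_len(nrow(P)), as.integer(pred$truth))]
  ggplot2::ggplot(pred, ggplot2::aes(.data$truth, .data$p_truth)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::labs(
      x = "observed eye colour",
      y = "LOOCV probability of observed colour",
      title = paste0(object$system, " LOOCV, panel ", object$panel_name)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an outcome report
#'
#' Stacked bar of correct / incorrect / inconclusive percentages, the usual
#' presentation of threshold-based forensic prediction performance.
#'
#' @param object An `ec_report`, or a list of them (e.g. one per policy).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ec_report
#' @export
autoplot.ec_report <- function(object, ...) {
  reports <- if (inherits(object, "ec_report")) list(object) else object
  df <- purrr::map_dfr(reports, function(r) {
    thr <- if (identical(r$policy$threshold, "pmax")) "pmax" else paste0("p ≥ ", r$policy$threshold)
    dplyr::mutate(r$outcome, policy = thr, panel = r$panel_name)
  })
  df$outcome <- factor(df$outcome, levels = c("inconclusive", "incorrect", "correct"))
  ggplot2::ggplot(df, ggplot2::aes(.data$policy, .data$percent, fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_manual(values = c(
      correct = "#4d9954", incorrect = "#b84a3c", inconclusive = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = "% of predictions", fill = NULL) +
    ggplot2::theme_minimal()
}
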