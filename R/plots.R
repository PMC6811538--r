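# ggplot2 views of the result objects.

#' Plot an evaluation's per-permutation performance
#'
#' Distribution of the predicted/observed ln IC50 correlation across
#' permutations, one panel row of boxes per drug.
#'
#' @param object An `inforx_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot inforx_eval
#' @export
autoplot.inforx_eval <- function(object, ...) {
  dat <- tidy(object) |> filter(!is.na(.data$r_pred_obs))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$drug_id, y = .data$r_pred_obs)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "r (predicted vs observed ln IC50)",
                  title = object$method) +
    ggplot2::theme_minimal()
}

#' Compare method summaries across drugs
#'
#' Mean predicted/observed correlation per drug and method, the usual view
#' for judging which feature-selection strategy wins where.
#'
#' @param summaries A tibble of [glance.inforx_eval()] rows (possibly
#'   several methods bound together).
#' @return A ggplot.
#' @export
plot_method_comparison <- function(summaries) {
  stopifnot(all(c("method", "drug_id", "mean_r") %in% names(summaries)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$drug_id, y = .data$mean_r,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "mean r (predicted vs observed ln IC50)",
                  fill = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a drug-specific screen
#'
#' Extreme-decile correlation of every gene for one drug, with the selection
#' band marked.
#'
#' @param screen A [select_dsg()] result.
#' @param r_threshold Threshold drawn on the plot (default 0.4).
#' @return A ggplot.
#' @export
plot_dsg_screen <- function(screen, r_threshold = 0.4) {
  dat <- filter(screen, !is.na(.data$r))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-r_threshold, r_threshold),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "extreme-decile r (expression vs ln IC50)", y = "genes",
                  title = attr(screen, "drug_id")) +
    ggplot2::theme_minimal()
}
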