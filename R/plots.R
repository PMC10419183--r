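#' Plot empirical ROC curves for selected indices
#'
#' One curve per index, faceted by sex, in (1 - specificity, sensitivity)
#' space with the chance diagonal.
#'
#' @param data Cohort tibble carrying index columns and the outcome.
#' @param indices Index columns to draw (default the full panel).
#' @param outcome Logical outcome column (default `"mets"`).
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(data, indices = index_names(), outcome = "mets") {
  if (!outcome %in% names(data)) data <- mets_components(data)
  strata <- split(tibble::as_tibble(data), as.character(data$sex))
  curves <- purrr::map(names(strata), function(sx) {
    purrr::map(indices, function(ix) {
      cr <- roc_curve(strata[[sx]][[ix]], strata[[sx]][[outcome]])
      dplyr::mutate(cr, index = ix, sex = sx)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$spec, y = .data$sens,
                                       colour = .data$index)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = "Index") +
    ggplot2::theme_minimal()
}

#' @describeIn roc_battery Dot-and-errorbar plot of AUC with 95% CI per
#'   index, by sex.
#' @param object A `roc_battery` tibble.
#' @export
#' @method autoplot roc_battery
autoplot.roc_battery <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$index, .data$auc),
                               y = .data$auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AUC (95% CI)") +
    ggplot2::theme_minimal()
}

#' @describeIn association_table Forest plot of unadjusted and adjusted
#'   odds ratios (log scale), faceted by sex and outcome.
#' @param object An `association_table` tibble.
#' @param ... Unused.
#' @export
#' @method autoplot association_table
autoplot.association_table <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      cols = c("or_unadj", "or_adj"),
      names_to = "adjustment", values_to = "or"
    ) |>
    dplyr::mutate(
      lo = ifelse(.data$adjustment == "or_unadj", .data$ci_unadj_lo,
                  .data$ci_adj_lo),
      hi = ifelse(.data$adjustment == "or_unadj", .data$ci_unadj_hi,
                  .data$ci_adj_hi),
      adjustment = ifelse(.data$adjustment == "or_unadj", "unadjusted",
                          "adjusted")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$or, y = .data$index,
                                     colour = .data$adjustment)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(ggplot2::vars(.data$outcome), ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
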