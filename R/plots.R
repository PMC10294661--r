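## ggplot2 views of the result types.

#' @export
ggplot2::autoplot

#' Plot an enrichment track
#'
#' Enrichment value against window start; masked windows appear as gaps.
#'
#' @param object An `enrichment_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_track
#' @export
autoplot.enrichment_track <- function(object, ...) {
  p <- enrichment_params(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("position on %s (nt)", p$replicon),
      y = "enrichment ratio",
      title = sprintf("window %d nt, step %d nt, background %d nt",
                      p$window, p$step, p$background)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a classified differential-expression table
#'
#' @param object A `volcano_table` from [volcano_classify()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 P, coloured by class.
#' @method autoplot volcano_table
#' @export
autoplot.volcano_table <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value),
                 colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-thr[["lfc_gt"]], thr[["lfc_gt"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(thr[["p_le"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c23b22", down = "#2b6cb0", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P") +
    ggplot2::theme_minimal()
}

#' Fitted standard curve with its dilution points
#'
#' @param object A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$fit$model,
                  ggplot2::aes(x = .data$log10_quantity, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2b6cb0") +
    ggplot2::labs(
      x = "log10 starting quantity", y = "Cq",
      title = sprintf("slope %.3f, efficiency %.2f, r2 %.4f",
                      object$slope, object$efficiency, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-design %Rmax binding results
#'
#' Mirrors the standard presentation of capture-duplex binding panels: one
#' bar per design with standard-error bars.
#'
#' @param results Binding results from [analyze_cycles()].
#' @return A ggplot.
#' @export
plot_binding <- function(results) {
  results <- as_tibble(results)
  if (!all(c("design_id", "percent_rmax", "se") %in% names(results))) {
    abort("`results` must come from analyze_cycles().")
  }
  results$design_id <- factor(results$design_id, levels = results$design_id)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$design_id, y = .data$percent_rmax)) +
    ggplot2::geom_col(fill = "#2b6cb0") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent_rmax - .data$se,
                   ymax = .data$percent_rmax + .data$se),
      width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "%Rmax") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
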