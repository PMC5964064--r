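#' @include experiment.R
NULL

#' Plot performance-progression curves
#'
#' One light trace per hyperparameter set and a dark trace for their
#' pointwise average, per method; absolute medians or medians relative to the
#' complete-data model.
#'
#' @param report output of [reportCurves()].
#' @param relative plot the relative panel (default) or absolute medians.
#' @return a ggplot object.
#' @export
plotProgression <- function(report, relative = TRUE) {
  curves <- report$curves
  avg <- report$average
  yvar <- if (relative) "relative" else "median"
  metric <- curves$metric[1L]
  p <- ggplot2::ggplot(curves,
         ggplot2::aes(x = .data$fraction, y = .data[[yvar]],
                      colour = .data$method,
                      group = interaction(.data$method,
                                          .data$hyperparameter_set))) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_line(data = avg,
                       ggplot2::aes(group = .data$method), linewidth = 1) +
    ggplot2::facet_wrap(~removal_model) +
    ggplot2::labs(x = "fraction of training data removed",
                  y = if (relative) sprintf("median %s relative to complete data", metric)
                      else sprintf("median %s", metric)) +
    ggplot2::theme_bw()
  p
}
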