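#' Figures for a case report
#'
#' Draws the rolling drift slope with its credibility bands, the analytic
#' planktivore drift derivative, the destabilization landmarks (attractor
#' switch, point of no return) and the post-transition region, plus a panel
#' of the classical indicators, and writes them to files.
#'
#' @param report A `case_report` from [run_case()].
#' @param dir Output directory.
#' @return A list with `paths` (written files) and `plots` (the ggplot
#'   objects).
#' @export
make_case_figures <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sl <- report$slopes
  lm <- report$landmarks

  p1 <- ggplot2::ggplot(sl, ggplot2::aes(x = window_end_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q01, ymax = q99),
                         fill = "orange", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q16, ymax = q84),
                         fill = "orange", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = zeta_map), color = "blue") +
    ggplot2::geom_line(data = report$analytic,
                       ggplot2::aes(x = window_end_time, y = slope),
                       linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "red") +
    ggplot2::labs(x = "time (years)", y = "drift slope",
                  title = sprintf("Drift slope, %s noise, sigma = %g",
                                  report$config$noise, report$config$sigma))
  if (is.finite(lm$switch_time))
    p1 <- p1 + ggplot2::geom_vline(xintercept = lm$switch_time,
                                   linetype = "dotted", color = "darkgreen")
  if (is.finite(lm$pnr_time))
    p1 <- p1 + ggplot2::geom_vline(xintercept = lm$pnr_time,
                                   color = "orange")
  if (is.finite(lm$transition_time))
    p1 <- p1 + ggplot2::annotate("rect", xmin = lm$transition_time,
                                 xmax = max(sl$window_end_time), ymin = -Inf,
                                 ymax = Inf, alpha = 0.15, fill = "grey40")

  ind <- report$indicators
  long <- stats::reshape(ind, direction = "long",
                         varying = setdiff(names(ind), "window_end_time"),
                         v.names = "value",
                         times = setdiff(names(ind), "window_end_time"),
                         timevar = "indicator")
  p2 <- ggplot2::ggplot(long, ggplot2::aes(x = window_end_time, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "indicator value",
                  title = "Classical early-warning indicators")

  paths <- c(drift_slope = file.path(dir, "drift_slope.png"),
             indicators = file.path(dir, "indicators.png"))
  ggplot2::ggsave(paths[["drift_slope"]], p1, width = 7, height = 4,
                  dpi = 120)
  ggplot2::ggsave(paths[["indicators"]], p2, width = 7, height = 5,
                  dpi = 120)
  list(paths = paths, plots = list(drift_slope = p1, indicators = p2))
}

utils::globalVariables(c("window_end_time", "q01", "q99", "q16", "q84",
                         "zeta_map", "slope", "value"))
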