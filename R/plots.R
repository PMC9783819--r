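#' Plot a replicate set as mean with a standard-deviation band
#'
#' @param set An aggregated [replicate_set()].
#' @return A `ggplot` object.
#' @export
plot_chronogram <- function(set) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_ppchron("io", "plotting requires the `ggplot2` package")
  }
  if (is.null(set$mean)) set <- aggregate_replicates(set)
  df <- data.frame(
    time_h = set$mean$times,
    y_mean = set$mean$intensities,
    y_sd = set$sd$intensities
  )
  ggplot2::ggplot(df, ggplot2::aes(x = time_h, y = y_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = y_mean - y_sd, ymax = y_mean + y_sd),
      fill = "grey80", na.rm = TRUE
    ) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "time since inoculation (h)", y = "relative intensity",
      title = sprintf("%s: biological mean +/- SD", set$condition)
    )
}

#' Poincare scatter of successive intensity pairs
#'
#' Plots \eqn{(x_t, x_{t+1})} with the identity line; the subtitle
#' reports SD1, SD2 and their ratio.
#'
#' @param chron A [chronogram()].
#' @return A `ggplot` object.
#' @export
plot_poincare <- function(chron) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_ppchron("io", "plotting requires the `ggplot2` package")
  }
  x <- chron$intensities
  pc <- poincare(x)
  df <- data.frame(now = x[-length(x)], nxt = x[-1])
  ggplot2::ggplot(df, ggplot2::aes(x = now, y = nxt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, colour = "#31a354") +
    ggplot2::labs(
      x = expression(x[t]), y = expression(x[t + 1]),
      title = sprintf("Poincare plot: %s", chron$condition),
      subtitle = sprintf("SD1 = %.4g, SD2 = %.4g, SD1/SD2 = %.4f",
                         pc$sd1, pc$sd2, pc$ratio)
    )
}

utils::globalVariables(c("time_h", "y_mean", "y_sd", "now", "nxt"))
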