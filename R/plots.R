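#' Plot predicted post-screen incidence curves
#'
#' Line plot of the background incidence and the interval-cancer incidence
#' predicted by the two models against years since the screen (the usual
#' incidence-deficit figure).
#'
#' @param pred A tibble from [predict_interval_incidence()].
#' @param per_1000 Plot rates per 1000 person-years (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_interval_incidence <- function(pred, per_1000 = TRUE) {
  stopifnot(is.data.frame(pred),
            all(c("x_years", "background_rate", "classic_rate",
                  "catchup_rate") %in% names(pred)))
  long <- tidyr::pivot_longer(pred, -"x_years",
                              names_to = "curve", values_to = "rate")
  long$curve <- factor(long$curve,
                       levels = c("background_rate", "classic_rate",
                                  "catchup_rate"),
                       labels = c("background", "classic model",
                                  "catch-up model"))
  if (per_1000) long$rate <- 1000 * long$rate
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x_years, y = .data$rate,
                                     colour = .data$curve,
                                     linetype = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "years since screen",
                  y = if (per_1000) "incidence per 1000 person-years"
                      else "incidence per person-year",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed versus fitted counts for a screening ML fit
#'
#' @param object A `screening_mle` object.
#' @param ... Unused.
#' @return A ggplot object comparing observed and expected counts per
#'   observation stratum.
#' @export
autoplot.screening_mle <- function(object, ...) {
  df <- object$fitted
  df$bin <- ifelse(df$stratum == "screen", "screen",
                   sprintf("%s [%g,%g)", df$stratum, df$start, df$end))
  long <- tidyr::pivot_longer(df, c("observed", "expected"),
                              names_to = "which", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$count,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$stratum, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "cases", fill = NULL,
      title = sprintf("%s model fit%s", object$model_kind,
                      if (nzchar(object$data_label))
                        paste0(" (", object$data_label, ")") else "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
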