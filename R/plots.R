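#' Dot plot of percent of guidelines met by country
#'
#' Countries ordered by score, one dot each, with a reference line at 100%
#' (the national requirement equals the guideline amount). Optionally
#' coloured by legislation scope, to show whether countries mandating
#' iodization of only household or only processed-food salt sit higher than
#' those covering both.
#'
#' @param scores Score table (see [score_countries()]).
#' @param colour_by_scope Colour points by legislation scope (default FALSE).
#' @return A ggplot object.
#' @export
plot_percent_met <- function(scores, colour_by_scope = FALSE) {
  stopifnot(all(c("country", "percent_met") %in% names(scores)))
  df <- scores |>
    dplyr::arrange(.data$percent_met) |>
    dplyr::mutate(country = factor(.data$country, levels = .data$country))
  aes <- if (colour_by_scope && "scope" %in% names(scores)) {
    ggplot2::aes(x = .data$country, y = .data$percent_met,
                 colour = ifelse(.data$scope == "both",
                                 "household and processed",
                                 "household or processed only"))
  } else {
    ggplot2::aes(x = .data$country, y = .data$percent_met)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = 100, colour = "darkgreen") +
    ggplot2::labs(x = NULL, y = "% of guideline amount met",
                  colour = "legislation scope") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Scatter plot of percent of guidelines met against mUIC
#'
#' One point per linked country, with the adequate-intake band
#' (100-299 ug/L by default) shaded.
#'
#' @param linkage Joined table from [correlate_muic()] (`$data`).
#' @param adequate_band mUIC band shaded as adequate, ug/L.
#' @return A ggplot object.
#' @export
plot_score_vs_muic <- function(linkage, adequate_band = c(100, 299)) {
  stopifnot(all(c("percent_met", "muic_ug_L") %in% names(linkage)))
  ggplot2::ggplot(linkage,
                  ggplot2::aes(x = .data$percent_met,
                               y = .data$muic_ug_L)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = adequate_band[1], ymax = adequate_band[2],
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "% of guideline amount met",
                  y = "mUIC (µg/L)") +
    ggplot2::theme_minimal()
}
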