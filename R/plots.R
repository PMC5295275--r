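#' Plot normalized dose trends against EJ score
#'
#' One line per chemical of the percent-of-maximum mean dose across score
#' strata — the standard way to compare dose gradients across pollutants on
#' very different absolute scales.
#'
#' @param summaries single-indicator summary tibble with a `percent`
#'   column (see [group_mean_by_score()] and [normalize_to_percent()]).
#' @return a ggplot object.
#' @export
plot_score_trend <- function(summaries) {
  stopifnot(all(c("score", "chemical", "percent") %in% names(summaries)))
  ggplot2::ggplot(
    summaries[!is.na(summaries$percent), ],
    ggplot2::aes(
      x = .data$score, y = .data$percent, colour = .data$chemical
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(
      x = "EJ score", y = "mean ADD (% of per-chemical maximum)",
      colour = "chemical"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn build_surface heat-map view of the dose surface
#'   (poverty score x race score, fill = mean ADD; empty cells blank).
#' @param object a `score_surface`.
#' @export
autoplot.score_surface <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$race_score, y = .data$poverty_score, fill = .data$mean_add
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::scale_y_continuous(breaks = 1:10) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      x = "race score", y = "poverty score",
      fill = "mean ADD\n(mg/kg-day)", title = object$label
    ) +
    ggplot2::theme_minimal()
}
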