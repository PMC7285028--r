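#' Plot an emergence series
#'
#' Relative cumulative emergence over days, one line per quadrat.
#'
#' @param object An `emergence_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emergence_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$day, y = .data$rel_cum,
                               colour = .data$quadrat_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Time (days)",
                  y = paste0("Relative cumulative ", series_source(object)),
                  colour = "Quadrat") +
    ggplot2::theme_minimal()
}

#' Plot a fitted emergence model
#'
#' Pooled observations with the fitted curve; if the fit has been validated,
#' nothing about the count data is shown here (the counts never enter the
#' fit) — use [autoplot.model_comparison()] for model ranking.
#'
#' @param object An `emergence_fit`.
#' @param n_grid Curve evaluation grid size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emergence_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(day = seq(min(object$data$day), max(object$data$day),
                                   length.out = n_grid))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$day, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "forestgreen", linewidth = 0.8) +
    ggplot2::labs(x = "Time (days)", y = "Relative cumulative emergence",
                  title = sprintf("%s fit (AIC %.1f, RMSE %.3f)",
                                  object$family, object$aic, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' AIC difference to the best model per family.
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$family, .data$delta_aic),
                               y = .data$delta_aic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * AIC ~ "(0 = best)")) +
    ggplot2::theme_minimal()
}
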