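#' Plot a categorical raster
#'
#' @param object a [cat_raster()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cat_raster
#' @export
autoplot.cat_raster <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    x = object$origin[1] + (as.vector(col(v)) - 0.5) * object$resolution,
    y = object$origin[2] + (as.vector(row(v)) - 0.5) * object$resolution,
    category = as.vector(v)
  )
  df$category[df$category == object$nodata] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$category))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot Frescalo effort across squares
#'
#' Histogram of the per-square recorder-effort estimates (1/alpha).
#'
#' @param object a `frescalo_fit`.
#' @param ... unused.
#' @method autoplot frescalo_fit
#' @export
autoplot.frescalo_fit <- function(object, ...) {
  df <- dplyr::filter(object$squares, !.data$flagged)
  ggplot2::ggplot(df, ggplot2::aes(.data$effort)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "recorder effort (1/alpha)", y = "squares") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of average marginal effects
#'
#' The Fig 2c/d-style view: one AME per species, coloured by sign.
#'
#' @param ames tibble with `species_id`, `ame` (one row per species).
#' @param unit_label axis label for the AME unit.
#' @return A ggplot object.
#' @export
plot_ame_distribution <- function(ames, unit_label = "AME per unit change") {
  df <- dplyr::arrange(ames, .data$ame)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$ame,
                                   fill = .data$ame > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "species (ranked)", y = unit_label) +
    ggplot2::theme_minimal()
}

#' Plot an interaction prediction grid
#'
#' Heat map of the interactive-minus-additive predicted persistence
#' difference over the 11 x 11 decile grid.
#'
#' @param object a `prediction_grid` from [build_grid()].
#' @param ... unused.
#' @method autoplot prediction_grid
#' @export
autoplot.prediction_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dT_level, .data$L_level,
                                       fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "warming level (1 = min ... 11 = max)",
                  y = "conversion level",
                  fill = "difference") +
    ggplot2::theme_minimal()
}
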