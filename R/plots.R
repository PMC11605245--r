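#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_df <- function(m, name) {
  tibble::tibble(
    image = name,
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a QDF reconstruction
#'
#' Darkfield, edge and QDF images side by side, on a shared intensity scale
#' per panel, with the raster origin at the top-left (image convention).
#'
#' @param object A `qdf_reconstruction` from [compute_qdf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot qdf_reconstruction
autoplot.qdf_reconstruction <- function(object, ...) {
  d <- dplyr::bind_rows(
    image_df(object$df, "DF"),
    image_df(object$edge, "E"),
    image_df(pmax(object$qdf, 0), "QDF")
  ) |>
    dplyr::group_by(.data$image) |>
    dplyr::mutate(value = .data$value / max(.data$value, 1e-12)) |>
    dplyr::ungroup() |>
    dplyr::mutate(image = factor(.data$image, c("DF", "E", "QDF")))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~image, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "rel. intensity") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Signal-versus-shape scatter with binned overlay and linear fits
#'
#' The standard population display: mass-normalized darkfield and QDF
#' signal against mass per area (a shape proxy), with binned means +/- sd
#' and the straight-line fits whose F-tests quantify shape dependence.
#'
#' @param records Cell-record tibble with `mass_per_area_pg_per_um2`,
#'   `df_per_mass`, `qdf_per_mass`.
#' @param bin_width Bin width in pg/um^2 (default 0.1).
#' @return A ggplot.
#' @export
plot_signal_vs_shape <- function(records, bin_width = 0.1) {
  long <- records |>
    dplyr::filter(!.data$debris %in% TRUE) |>
    tidyr::pivot_longer(c("df_per_mass", "qdf_per_mass"),
                        names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = dplyr::recode(.data$signal,
                                         df_per_mass = "DF / mass",
                                         qdf_per_mass = "QDF / mass"))
  bins <- long |>
    dplyr::group_by(.data$signal) |>
    dplyr::group_modify(~ binned_fit(.x, .data$mass_per_area_pg_per_um2,
                                     .data$value, bin_width = bin_width)) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(.data$mass_per_area_pg_per_um2,
                                     .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_pointrange(data = bins,
                             ggplot2::aes(x = .data$bin_mid, y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "mass per area (pg/um^2)", y = "signal per mass",
                  colour = NULL)
}

#' Per-cell signal distributions of two populations
#'
#' Histograms of per-cell totals for two populations, faceted by signal
#' type — the display behind the KL-divergence and t-test comparison.
#'
#' @param a,b Cell-record tibbles for the two populations.
#' @param signal Column to compare (default `total_qdf`).
#' @param labels Population names.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_population_separation <- function(a, b, signal = "total_qdf",
                                       labels = c("A", "B"), bins = 40) {
  d <- dplyr::bind_rows(
    dplyr::mutate(a, population = labels[1]),
    dplyr::mutate(b, population = labels[2])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data[[signal]],
                                  fill = .data$population)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = signal, y = "cells", fill = NULL)
}
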