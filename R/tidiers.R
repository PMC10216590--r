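#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a contrast sweep into its grid tibble
#' @param x An `omlit_sweep`.
#' @param ... Unused.
#' @return A plain tibble (`wavelength_nm`, `section_nm`, `coating_nm`,
#'   `R_cell`, `R_surround`, `contrast`).
#' @method tidy omlit_sweep
#' @export
tidy.omlit_sweep <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a contrast sweep
#' @param x An `omlit_sweep`.
#' @param ... Unused.
#' @return One-row tibble: the overall argmax (wavelength, section and coating
#'   thickness, best contrast) plus the reduced-thickness annotation.
#' @method glance omlit_sweep
#' @export
glance.omlit_sweep <- function(x, ...) {
  am <- attr(x, "argmax")
  tibble::tibble(coating_material = attr(x, "coating_material"),
                 best_contrast = am$best_contrast,
                 wavelength_nm = am$wavelength_nm,
                 section_nm = am$section_nm,
                 coating_nm = am$coating_nm,
                 fraction_thickness_nm = am$fraction_thickness_nm,
                 fraction = attr(x, "fraction"),
                 mode = attr(x, "mode"))
}

#' Per-wavelength optimum table of a sweep
#' @param x An `omlit_sweep`.
#' @return Tibble with one row per wavelength.
#' @export
sweep_optima <- function(x) {
  stopifnot(inherits(x, "omlit_sweep"))
  attr(x, "optimum")
}

#' Tidy per-pair contrast values
#' @param x A `contrast_estimate`.
#' @param ... Unused.
#' @return Tibble with one row per ROI pair.
#' @method tidy contrast_estimate
#' @export
tidy.contrast_estimate <- function(x, ...) x$pairs

#' One-row summary of a contrast estimate
#' @param x A `contrast_estimate`.
#' @param ... Unused.
#' @return One-row tibble: mean, sd, n, exclusions, mode.
#' @method glance contrast_estimate
#' @export
glance.contrast_estimate <- function(x, ...) {
  tibble::tibble(mean_contrast = x$mean_contrast, sd_contrast = x$sd_contrast,
                 n = x$n, n_excluded = x$n_excluded, mode = x$mode)
}

#' Heatmap of a contrast sweep (one panel per wavelength)
#' @param object An `omlit_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omlit_sweep
#' @export
autoplot.omlit_sweep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coating_nm, y = .data$section_nm,
                                   fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~wavelength_nm, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "coating thickness (nm)", y = "section thickness (nm)",
                  fill = "contrast",
                  title = sprintf("Cell/surround contrast, %s coating",
                                  attr(object, "coating_material"))) +
    ggplot2::theme_minimal()
}

#' Render a section image as a ggplot raster
#' @param object A `section_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot section_image
#' @export
autoplot.section_image <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(ncol(object)), y = seq_len(nrow(object)))
  df$intensity <- as.vector(unclass(object))  # column-major: y fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I") +
    ggplot2::theme_void()
}

#' Histogram of per-pair contrasts
#' @param object A `contrast_estimate`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrast_estimate
#' @export
autoplot.contrast_estimate <- function(object, bins = 15, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!df$excluded, ], ggplot2::aes(x = .data$contrast)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_contrast, colour = "red") +
    ggplot2::labs(x = sprintf("per-pair contrast (%s)", object$mode),
                  y = "pairs") +
    ggplot2::theme_minimal()
}
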