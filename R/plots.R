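#' Plot an accessibility map
#'
#' Entry-region map in the sagittal chart (u anterior, v superior), coloured
#' by safety margin, SCC entry angle, or the accessibility flag.
#'
#' @param object an `access_map`.
#' @param fill `"margin"`, `"angle"` or `"accessible"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.access_map <- function(object, fill = c("accessible", "margin", "angle"),
                                ...) {
  fill <- match.arg(fill)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[fill]]), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior-posterior u (mm)", y = "inferior-superior v (mm)",
                  title = sprintf("%s canal: %.0f%% accessible",
                                  object$canal[1], accessibility(object))) +
    ggplot2::theme_minimal()
  if (fill == "margin")
    p <- p + ggplot2::scale_colour_viridis_c(name = "margin (mm)",
                                             limits = c(-1, NA), oob = scales_squish)
  if (fill == "angle")
    p <- p + ggplot2::scale_colour_viridis_c(name = "entry angle (deg)",
                                             option = "plasma")
  if (fill == "accessible")
    p <- p + ggplot2::scale_colour_manual(name = "accessible",
                                          values = c(`TRUE` = "#2a9d8f",
                                                     `FALSE` = "#bbbbbb"))
  p
}

# minimal stand-in for scales::squish, avoiding an extra dependency
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  x[x < range[1]] <- range[1]; x[x > range[2]] <- range[2]; x
}

#' Plot the exposed-area curve
#'
#' @param curve a [exposed_area_curve()] tibble.
#' @param ideal_angle angle to mark (degrees).
#' @return a ggplot.
#' @export
plot_exposure_curve <- function(curve, ideal_angle = 30) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$theta, y = .data$area)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = curve[which.min(abs(curve$theta - ideal_angle)), ],
                        shape = 8, size = 3) +
    ggplot2::labs(x = "SCC entry angle (deg)", y = expression("exposed area (mm"^2*")")) +
    ggplot2::theme_minimal()
}

#' Plot a fenestration-site sweep
#'
#' @param sweep a [fenestration_sweep()] tibble.
#' @return a ggplot with accessibility and minimal accessible angle vs offset.
#' @export
plot_fenestration_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, -"offset", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = c(accessibility = "accessibility (%)",
                                     min_accessible_angle = "min accessible angle (deg)"))) +
    ggplot2::labs(x = "fenestration offset from electrode target (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.entry_region <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.entry_region <- function(x, ...) {
  tibble::tibble(n_points = nrow(x), planar_area = attr(x, "area"),
                 eac_u = 0, eac_v = 0)
}

#' @export
tidy.clearance_report <- function(x, ...) x$per_obstacle

#' @export
glance.clearance_report <- function(x, ...) {
  tibble::tibble(safety_margin = x$safety_margin, n_samples = x$n_samples)
}

#' @export
tidy.centreline <- function(x, ...) tibble::as_tibble(x)
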