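#' Plot a wound closure curve
#'
#' @param object A [closure_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot closure_curve
#' @export
autoplot.closure_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$closure_pct)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (h)", y = "wound closure (%)") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph
#'
#' @param object A [kymograph()] object.
#' @param ... Unused.
#' @return A ggplot with position on x and time running down the y axis.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  m <- object$intensity
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$intensity <- as.numeric(t(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position across wound (px)", y = "frame (time)") +
    ggplot2::theme_minimal()
}

#' Plot the field-magnitude map of a solution
#'
#' @param object A [solve_field()] solution.
#' @param what `"E"` (mV/mm), `"V"` (mV) or `"p"` (W/m^2).
#' @param ... Unused.
#' @return A ggplot raster of the selected quantity on conducting cells.
#' @method autoplot field_solution
#' @export
autoplot.field_solution <- function(object, what = c("E", "V", "p"), ...) {
  what <- match.arg(what)
  m <- switch(what, E = object$E_mag, V = object$V_mV, p = object$p_areal_W_m2)
  lab <- switch(what, E = "|E| (mV/mm)", V = "V (mV)", p = "p (W/m^2)")
  map <- object$map
  d <- tidyr::expand_grid(iy = seq_along(map$y), ix = seq_along(map$x))
  d$x <- map$x[d$ix]; d$y <- map$y[d$iy]
  d$value <- m[cbind(d$iy, d$ix)]
  d <- d[map$conducting[cbind(d$iy, d$ix)], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a hue-pH calibration curve with its data
#'
#' @param object A [fit_calibration()] or [ph_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ph_calibration
#' @export
autoplot.ph_calibration <- function(object, ...) {
  ph <- seq(object$domain[1], object$domain[2], length.out = 200)
  line <- tibble(ph = ph, hue = bidose_response(ph, object$params))
  g <- ggplot2::ggplot(line, ggplot2::aes(x = .data$ph, y = .data$hue)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "pH", y = "hue (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    g <- g + ggplot2::geom_point(data = object$data, colour = "steelblue")
  }
  g
}

#' Plot ROI pH traces
#'
#' @param object A [roi_ph_traces()] tibble.
#' @param ... Unused.
#' @return A ggplot of pH against stimulation time, one line per ROI.
#' @method autoplot ph_traces
#' @export
autoplot.ph_traces <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$ph,
                                       colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stimulation time (h)", y = "pH") +
    ggplot2::theme_minimal()
}
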