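# Plotting: density functions, census, and slice renderings with the
# thickness color presets (2-160 um linear; 0-280 um logarithmic).

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a thickness density function
#'
#' @param object a [thickness_pdf()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.thickness_pdf <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center_um, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width_um"),
                      fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "thickness (µm)", y = "probability density",
                  title = sprintf("volume-weighted thickness density (%s)",
                                  attr(object, "foreground"))) +
    ggplot2::theme_minimal()
}

#' Plot the two density functions of a report
#'
#' @param object a [compile_report()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.morphometry_report <- function(object, ...) {
  pieces <- list()
  if (!is.null(object$thickness_pdf))
    pieces$thickness <- transform(as.data.frame(object$thickness_pdf),
                                  which = "trabecular thickness")
  if (!is.null(object$separation_pdf))
    pieces$separation <- transform(as.data.frame(object$separation_pdf),
                                   which = "trabecular separation")
  if (length(pieces) == 0) stop("report carries no density functions")
  df <- do.call(rbind, pieces)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_um,
                                   y = .data$density,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "diameter (µm)", y = "probability density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render one z-slice of a grid, mask or thickness map
#'
#' For thickness maps the two color presets of the morphometry renderings
#' are available: `"linear"` maps 2-160 µm linearly from blue to red, and
#' `"log"` maps 0-280 µm on a log1p scale.
#'
#' @param x a [voxel_grid], [binary_mask] or [thickness_map].
#' @param z slice index (default: middle).
#' @param preset `"linear"` or `"log"` (thickness maps only).
#' @return A ggplot.
#' @export
plot_slice <- function(x, z = NULL, preset = c("linear", "log")) {
  preset <- match.arg(preset)
  if (inherits(x, "thickness_map")) {
    arr <- x$thickness
  } else if (inherits(x, "voxel_grid")) {
    arr <- x$data * 1.0
  } else stop("unsupported object")
  d <- dim(arr)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- arr[, , z]
  df <- data.frame(x = rep(seq_len(d[1]), times = d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   value = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (inherits(x, "thickness_map")) {
    if (preset == "linear") {
      p <- p + ggplot2::scale_fill_gradientn(
        colours = c("grey20", "blue", "cyan", "yellow", "red"),
        limits = c(0, 160), oob = scales_squish, name = "µm")
    } else {
      p <- p + ggplot2::scale_fill_gradientn(
        colours = c("grey20", "blue", "cyan", "yellow", "red"),
        limits = c(0, 280), trans = "log1p", oob = scales_squish,
        name = "µm")
    }
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "black", high = "white")
  }
  p
}

# minimal squish (avoids depending on the scales package directly)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom rlang .data
NULL
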