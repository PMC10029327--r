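# broom-style tidiers for report objects.

#' Tidy a morphometry report
#'
#' @param x a [compile_report()] result.
#' @param ... unused.
#' @return A long tibble with `quantity`, `measured`, `no_microstructure`.
#' @export
tidy.morphometry_report <- function(x, ...) {
  tibble::tibble(
    quantity = c("section_length_mm", "csf_volume_mm3",
                 "interface_area_mm2", "interface_area_interior_mm2"),
    measured = c(x$section_length_mm, x$csf_volume_mm3[["measured"]],
                 x$interface_area_mm2[["measured"]],
                 x$interface_area_interior_mm2[["measured"]]),
    no_microstructure = c(x$section_length_mm,
                          x$csf_volume_mm3[["no_microstructure"]],
                          x$interface_area_mm2[["no_microstructure"]],
                          x$interface_area_interior_mm2[["no_microstructure"]]))
}

#' One-row summary of a morphometry report
#'
#' @param x a [compile_report()] result.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.morphometry_report <- function(x, ...) {
  tibble::tibble(
    amplification_factor = x$amplification_factor,
    microstructure_volume_fraction = x$microstructure_volume_fraction,
    microstructure_volume_mm3 = x$microstructure_volume_mm3,
    renormalization_factor = x$renormalization_factor,
    section_length_mm = x$section_length_mm,
    n_spaces = if (is.null(x$space_census)) NA_integer_
               else nrow(x$space_census))
}

#' Tidy a thickness density function
#'
#' @param x a [thickness_pdf()].
#' @param ... unused.
#' @return A plain tibble.
#' @export
tidy.thickness_pdf <- function(x, ...) {
  tibble::tibble(bin_center_um = x$bin_center_um, density = x$density)
}
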