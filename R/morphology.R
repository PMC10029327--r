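# 3D binary morphology with Euclidean (ball) structuring elements, built on
# the exact squared distance transform. Radii are in um; voxels outside the
# grid are treated as replicating the boundary (no implicit background).

edt_sq_vox <- function(data) {
  cpp_edt_sq(as.logical(data), dim(data))
}

# distance (um) from every voxel to the nearest TRUE voxel of `data`
distance_to_um <- function(data, voxel_size_um) {
  d <- sqrt(edt_sq_vox(data))
  array(d * voxel_size_um, dim(data))
}

#' Dilate, erode, open and close with a Euclidean ball
#'
#' Exact Euclidean-metric morphology: `dilate_ball()` keeps voxels within
#' `radius_um` of the foreground, `erode_ball()` keeps voxels farther than
#' `radius_um` from the background; opening and closing are the usual
#' compositions. The structuring element is the set of voxel centers within
#' the given radius.
#'
#' @param mask a [binary_mask].
#' @param radius_um ball radius in µm.
#' @return A [binary_mask] of the same geometry.
#' @export
dilate_ball <- function(mask, radius_um) {
  assert_mask(mask)
  r <- radius_um / mask$voxel_size_um
  d2 <- edt_sq_vox(mask$data)
  binary_mask(array(d2 <= r^2, dim(mask$data)), mask$voxel_size_um,
              mask$origin)
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius_um) {
  assert_mask(mask)
  r <- radius_um / mask$voxel_size_um
  d2 <- edt_sq_vox(!mask$data)
  binary_mask(array(d2 > r^2, dim(mask$data)), mask$voxel_size_um,
              mask$origin)
}

#' @rdname dilate_ball
#' @export
open_ball <- function(mask, radius_um) {
  dilate_ball(erode_ball(mask, radius_um), radius_um)
}

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius_um) {
  erode_ball(dilate_ball(mask, radius_um), radius_um)
}

#' Connected-component labelling
#'
#' @param mask a [binary_mask].
#' @param connectivity 6 or 26.
#' @return Integer array of labels (0 = background), with attribute `sizes`.
#' @export
label_components <- function(mask, connectivity = 26) {
  assert_mask(mask)
  stopifnot(connectivity %in% c(6, 26))
  lab <- cpp_label_components(mask$data, dim(mask$data),
                              as.integer(connectivity))
  lab <- array(lab, dim(mask$data))
  attr(lab, "sizes") <- if (max(lab) > 0) tabulate(lab) else integer(0)
  lab
}

#' Retain the largest connected component
#'
#' @inheritParams label_components
#' @param exclude_boundary optional character vector among `"x"`, `"y"`,
#'   `"z"`: components touching those grid faces are not eligible (used to
#'   separate the nerve, which runs axially, from peripheral tissue that
#'   touches the lateral faces). If no component is eligible the overall
#'   largest is returned.
#' @return A [binary_mask] keeping only the selected component.
#' @export
largest_component <- function(mask, connectivity = 26,
                              exclude_boundary = NULL) {
  lab <- label_components(mask, connectivity)
  sizes <- attr(lab, "sizes")
  if (length(sizes) == 0)
    stop("mask has no foreground component")
  eligible <- rep(TRUE, length(sizes))
  if (!is.null(exclude_boundary)) {
    d <- dim(lab)
    touch <- integer(0)
    if ("x" %in% exclude_boundary)
      touch <- c(touch, lab[c(1, d[1]), , ])
    if ("y" %in% exclude_boundary)
      touch <- c(touch, lab[, c(1, d[2]), ])
    if ("z" %in% exclude_boundary)
      touch <- c(touch, lab[, , c(1, d[3])])
    eligible[unique(touch[touch > 0])] <- FALSE
  }
  if (!any(eligible)) eligible[] <- TRUE
  keep <- which(eligible)[which.max(sizes[eligible])]
  binary_mask(array(lab == keep, dim(lab)), mask$voxel_size_um, mask$origin)
}

#' Fill enclosed cavities
#'
#' Background components (6-connected, the dual of 26-connected foreground)
#' that do not touch any face of the grid are merged into the foreground.
#'
#' @inheritParams label_components
#' @return A [binary_mask].
#' @export
fill_cavities <- function(mask) {
  assert_mask(mask)
  bg <- binary_mask(!mask$data, mask$voxel_size_um, mask$origin)
  lab <- label_components(bg, connectivity = 6)
  d <- dim(lab)
  touching <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                       lab[, , c(1, d[3])]))
  touching <- touching[touching > 0]
  cavity <- bg$data & !(lab %in% touching)
  binary_mask(array(mask$data | cavity, d), mask$voxel_size_um, mask$origin)
}
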