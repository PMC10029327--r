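#' 3D scalar intensity field with isotropic voxel spacing
#'
#' The basic carrier for raw, stitched and enhanced signals: a 3D numeric
#' array plus an isotropic voxel spacing in micrometres and an integer
#' origin offset (voxel units) locating the grid in a global frame.
#'
#' @param data 3D numeric array.
#' @param voxel_size_um isotropic voxel spacing, µm/voxel.
#' @param origin integer voxel offset of the first voxel in a global frame.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size_um, origin = c(0L, 0L, 0L)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(voxel_size_um), length(voxel_size_um) == 1L,
            voxel_size_um > 0, length(origin) == 3L)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' 3D boolean foreground on a voxel-grid geometry
#'
#' @param data 3D logical array.
#' @inheritParams voxel_grid
#' @return An object of class `binary_mask` (which also inherits
#'   `voxel_grid`).
#' @export
binary_mask <- function(data, voxel_size_um, origin = c(0L, 0L, 0L)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.logical(data))
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 origin = as.numeric(origin)),
            class = c("binary_mask", "voxel_grid"))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels @ %g um/voxel, origin (%g, %g, %g)\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size_um,
              x$origin[1], x$origin[2], x$origin[3]))
  if (is.logical(x$data)) {
    cat(sprintf("  foreground: %d voxels (%.2f%%)\n", sum(x$data),
                100 * mean(x$data)))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
as.array.voxel_grid <- function(x, ...) x$data

# voxel-center coordinate axes in um, centered on the grid midpoint
grid_axes_um <- function(d, voxel_size_um) {
  lapply(d, function(n) (seq_len(n) - 1 - (n - 1) / 2) * voxel_size_um)
}

# cylindrical radius (um) about the z axis through the grid center,
# as a (nx x ny) matrix recyclable over z
radial_coord <- function(d, voxel_size_um) {
  ax <- grid_axes_um(d, voxel_size_um)
  outer(ax[[1]]^2, ax[[2]]^2, `+`)^0.5
}

# voxel azimuth (radians in [0, 2pi)) about an axis through `center_um`
azimuth_coord <- function(d, voxel_size_um, center_um = c(0, 0)) {
  ax <- grid_axes_um(d, voxel_size_um)
  th <- atan2(rep(ax[[2]] - center_um[2], each = d[1]),
              rep(ax[[1]] - center_um[1], times = d[2]))
  matrix((th + 2 * pi) %% (2 * pi), d[1], d[2])
}

assert_mask <- function(x, arg = "mask") {
  if (!inherits(x, "binary_mask"))
    stop(sprintf("`%s` must be a binary_mask", arg), call. = FALSE)
  invisible(x)
}
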