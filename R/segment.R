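# Compartment segmentation: hard threshold on the enhanced signal, then
# connectivity logic and Euclidean-ball morphology to build three mutually
# consistent foregrounds: optic nerve (ON), SAS microstructure, CSF.

#' Hard threshold
#'
#' @param enhanced a [voxel_grid] (typically the output of
#'   [enhance_volume()]).
#' @param threshold cut value; `NULL` selects it by Otsu's method on the
#'   intensity histogram. A threshold at the minimum saturates (all-true)
#'   and one above the maximum yields an all-false mask ("nothing
#'   detected"); both are valid.
#' @return A [binary_mask] of voxels `>= threshold`; the attribute
#'   `threshold` records the value used.
#' @export
threshold_segment <- function(enhanced, threshold = NULL) {
  stopifnot(inherits(enhanced, "voxel_grid"))
  x <- enhanced$data
  if (is.null(threshold)) {
    threshold <- otsu_threshold(x)
  } else if (!is.finite(threshold)) {
    stop("threshold must be finite")
  }
  m <- binary_mask(array(x >= threshold, dim(x)), enhanced$voxel_size_um,
                   enhanced$origin)
  attr(m, "threshold") <- threshold
  m
}

# Global Otsu threshold on the nonnegative lobe of the enhanced histogram.
# The band-passed signal is two zero-centered lobes (background response vs
# structure response); Otsu on the signed histogram lands inside the
# background lobe, so the split is computed on the positive side where the
# structure response separates cleanly.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xp <- x[x >= 0]
  img <- EBImage::Image(array(xp, c(length(xp), 1L)))
  EBImage::otsu(img, range = range(xp), levels = 512L)
}

#' Segment set: ON, SAS microstructure, and CSF foregrounds
#'
#' @param on_mask,sas_mask,csf_mask pairwise disjoint [binary_mask]s.
#' @param excluded_sector optional list with `angle_deg` (width),
#'   `reference_deg` (start azimuth) and `center_um` (axis point in the
#'   grid-centered frame).
#' @param params list of parameters recorded for provenance.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(on_mask, sas_mask, csf_mask,
                        excluded_sector = NULL, params = list()) {
  v <- csf_mask$voxel_size_um
  stopifnot(identical(dim(on_mask$data), dim(csf_mask$data)),
            identical(dim(sas_mask$data), dim(csf_mask$data)))
  if (any(on_mask$data & sas_mask$data) || any(on_mask$data & csf_mask$data) ||
      any(sas_mask$data & csf_mask$data))
    stop("segment masks must be pairwise disjoint")
  structure(list(on_mask = on_mask, sas_mask = sas_mask, csf_mask = csf_mask,
                 excluded_sector = excluded_sector, voxel_size_um = v,
                 params = params),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  v3 <- x$voxel_size_um^3
  cat(sprintf(paste0(
    "<segment_set> ON %.4g um^3 | SAS microstructure %.4g um^3 | ",
    "CSF %.4g um^3\n"),
    sum(x$on_mask$data) * v3, sum(x$sas_mask$data) * v3,
    sum(x$csf_mask$data) * v3))
  if (!is.null(x$excluded_sector))
    cat(sprintf("  excluded sector: %g deg from %g deg\n",
                x$excluded_sector$angle_deg, x$excluded_sector$reference_deg))
  invisible(x)
}

#' Build the ON / SAS / CSF foregrounds from a thresholded volume
#'
#' The construction follows the connectivity recipe of the pipeline:
#' (1) cavities in the thresholded foreground are filled; (2) the ON is
#' captured by a morphological closing (consolidating the speckled nerve
#' interior) followed by an opening that removes all structures thinner
#' than the nerve — trabeculae, septae and the thin peripheral responses —
#' and retention of the largest component that does not touch the lateral
#' faces; (3) the CSF is the largest 26-connected component of the
#' complement; (4) the SAS microstructure is the closing of the CSF
#' (engulfing everything the CSF surrounds) intersected with the
#' foreground, minus the ON.
#'
#' @param raw_fg a [binary_mask] from [threshold_segment()].
#' @param closing_radius_um reach of the CSF envelope (default 1.4 times
#'   the largest expected trabecular radius): microstructure voxels must
#'   lie within this distance of the CSF.
#' @param on_opening_radius_um radius of the ON-capture opening; must
#'   exceed the largest expected trabecular radius and be below the nerve
#'   radius.
#' @param consolidate_radius_um closing radius used to consolidate the
#'   speckled band-pass tissue response into solid foregrounds before any
#'   connectivity logic (closing leaves convex structures such as
#'   trabecular tubes at their original caliber).
#' @param reference optional [voxel_grid] of the pre-enhancement signal.
#'   The band-passed response places structure boundaries up to a couple
#'   of voxels inside the true interface (large structures sit in the
#'   negative basin of their own removed low frequencies), so when the
#'   reference is supplied the thresholded mask is grown into
#'   reference-bright voxels within a narrow guard band: the enhanced
#'   signal decides what is structure, the original grayscale decides
#'   where its boundary lies.
#' @param reference_threshold cut on the reference signal for the caliber
#'   refinement; `NULL` selects it by Otsu's method.
#' @param refine_iterations guard-band growth passes (each reaches two
#'   voxels).
#' @return A [segment_set].
#' @export
build_segments <- function(raw_fg, closing_radius_um = 14,
                           on_opening_radius_um = 16,
                           consolidate_radius_um = 6,
                           reference = NULL, reference_threshold = NULL,
                           refine_iterations = 2L) {
  assert_mask(raw_fg, "raw_fg")
  if (!any(raw_fg$data)) stop("raw foreground is empty")
  if (closing_radius_um < raw_fg$voxel_size_um)
    stop("closing radius must be at least one voxel")

  raw <- raw_fg
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "voxel_grid"),
              identical(dim(reference$data), dim(raw_fg$data)))
    if (is.null(reference_threshold)) {
      # quarter point between the Otsu class means: safely above the
      # background class, yet low enough that fine tissue texture rarely
      # punches through and inscribed balls keep their full caliber
      t0 <- otsu_threshold(reference$data)
      m0 <- mean(reference$data[reference$data < t0])
      m1 <- mean(reference$data[reference$data >= t0])
      reference_threshold <- m0 + 0.25 * (m1 - m0)
    }
    ref_fg <- reference$data >= reference_threshold
    for (it in seq_len(refine_iterations)) {
      guard <- dilate_ball(raw, 2 * raw$voxel_size_um)
      raw <- binary_mask(raw$data | (ref_fg & guard$data),
                         raw$voxel_size_um, raw$origin)
    }
  }

  raw <- fill_cavities(raw)
  if (consolidate_radius_um > 0)
    raw <- fill_cavities(close_ball(raw, consolidate_radius_um))

  # CSF: main connected component of the complement. The SAS runs axially
  # through the section, so components touching the lateral faces
  # (peripheral tissue porosity) are not eligible. The complement of the
  # retained CSF is solid by construction, which makes the ON capture
  # below robust to residual porosity of the thresholded tissue response.
  rest <- binary_mask(!raw$data, raw$voxel_size_um, raw$origin)
  if (!any(rest$data)) stop("empty main component: no CSF candidate")
  csf <- largest_component(rest, 26, exclude_boundary = c("x", "y"))

  not_csf <- binary_mask(!csf$data, raw$voxel_size_um, raw$origin)
  opened <- open_ball(not_csf, on_opening_radius_um)
  if (!any(opened$data)) stop("empty main component: no ON-scale structure")
  on <- largest_component(opened, 26, exclude_boundary = c("x", "y"))
  on <- fill_cavities(on)
  # peripheral (dura-side) tissue: the opened components that touch the
  # lateral faces; subtracted from the microstructure explicitly. This
  # realizes the CSF-envelope closing through its dual opening: the
  # complement of the identified wall bodies is exactly the closing of
  # the CSF at the opening radius, but identifying the walls as
  # components is robust where a closing ball would interact with the
  # domain boundary.
  lab_open <- label_components(opened, 26)
  d <- dim(lab_open)
  lat <- unique(c(lab_open[c(1, d[1]), , ], lab_open[, c(1, d[2]), ]))
  lat <- lat[lat > 0]
  dura_est <- array(lab_open %in% lat, d)

  # bound the microstructure to the dilation reach of the CSF so stray
  # responses deep inside unidentified tissue are excluded
  reach <- dilate_ball(csf, closing_radius_um)
  sas <- binary_mask(reach$data & raw$data & !on$data & !dura_est,
                     raw$voxel_size_um, raw$origin)
  # clean residual films and specks: a one-voxel opening removes the thin
  # wall-hugging response sheets (convex trabecular tubes keep their
  # caliber), and isolated fragments below ~100 um^3 are dropped
  if (any(sas$data)) {
    sas <- open_ball(sas, sas$voxel_size_um)
    if (any(sas$data)) {
      lab <- label_components(sas, 26)
      keep <- which(attr(lab, "sizes") >=
                      ceiling(100 / sas$voxel_size_um^3))
      sas <- binary_mask(array(lab %in% keep, dim(lab)),
                         sas$voxel_size_um, sas$origin)
    }
  }

  segment_set(on, sas, csf,
              params = list(closing_radius_um = closing_radius_um,
                            on_opening_radius_um = on_opening_radius_um,
                            consolidate_radius_um = consolidate_radius_um,
                            reference_threshold = reference_threshold,
                            threshold = attr(raw_fg, "threshold")))
}

#' Digitally remove the SAS microstructure
#'
#' Returns the "no microstructure" counterfactual: the CSF absorbs every
#' former microstructure voxel and the SAS foreground becomes empty; the
#' ON is unchanged. Total CSF + SAS voxel count is conserved exactly.
#'
#' @param segs a [segment_set].
#' @return A [segment_set].
#' @export
remove_microstructure <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  if (!any(segs$sas_mask$data)) return(segs)
  csf <- binary_mask(segs$csf_mask$data | segs$sas_mask$data,
                     segs$voxel_size_um, segs$csf_mask$origin)
  empty <- binary_mask(array(FALSE, dim(csf$data)), segs$voxel_size_um,
                       csf$origin)
  segment_set(segs$on_mask, empty, csf,
              excluded_sector = segs$excluded_sector,
              params = c(segs$params, list(microstructure_removed = TRUE)))
}

# angular sector membership about the ON axis (z) through `center_um`
sector_membership <- function(d, voxel_size_um, sector) {
  az <- azimuth_coord(d, voxel_size_um,
                      center_um = sector$center_um[1:2]) * 180 / pi
  a0 <- sector$reference_deg %% 360
  rel <- (az - a0) %% 360
  inside2d <- rel < sector$angle_deg
  array(rep(inside2d, times = d[3]), d)
}

#' Exclude an angular sector from all foregrounds
#'
#' Zeroes every mask inside a circular sector about the nerve axis —
#' emulating the discarding of a damaged region — and records the sector
#' so that downstream measurements can be renormalized by
#' `360 / (360 - angle)`.
#'
#' @param segs a [segment_set].
#' @param angle_deg sector width in degrees; 0 is a no-op, 360 empties
#'   all masks.
#' @param reference_deg start azimuth of the sector (degrees).
#' @param center_um axis point; default is the ON centroid (or the grid
#'   center when the ON is empty).
#' @return A [segment_set] with the sector recorded.
#' @export
apply_sector_exclusion <- function(segs, angle_deg = 60, reference_deg = 0,
                                   center_um = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  if (angle_deg < 0 || angle_deg > 360)
    stop("sector angle must be within [0, 360]")
  d <- dim(segs$csf_mask$data)
  v <- segs$voxel_size_um
  if (is.null(center_um)) center_um <- on_axis_center(segs)
  sector <- list(angle_deg = angle_deg, reference_deg = reference_deg,
                 center_um = center_um)
  if (angle_deg == 0) {
    segs$excluded_sector <- sector
    return(segs)
  }
  inside <- sector_membership(d, v, sector)
  zero <- function(m) binary_mask(m$data & !inside, v, m$origin)
  structure(list(on_mask = zero(segs$on_mask), sas_mask = zero(segs$sas_mask),
                 csf_mask = zero(segs$csf_mask), excluded_sector = sector,
                 voxel_size_um = v, params = segs$params),
            class = "segment_set")
}

# centroid of the ON mask in the grid-centered um frame (x, y)
on_axis_center <- function(segs) {
  d <- dim(segs$on_mask$data)
  if (!any(segs$on_mask$data)) return(c(0, 0))
  ax <- grid_axes_um(d, segs$voxel_size_um)
  idx <- which(segs$on_mask$data, arr.ind = TRUE)
  c(mean(ax[[1]][idx[, 1]]), mean(ax[[2]][idx[, 2]]))
}

#' Segment set from phantom ground truth
#'
#' Builds the reference segmentation directly from a phantom's truth
#' masks, bypassing enhancement and thresholding. Useful for validating
#' geometry and morphometry independently of the imaging chain.
#'
#' @param truth a `phantom_truth`.
#' @return A [segment_set].
#' @export
segments_from_truth <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  segment_set(truth$nerve_mask, truth$micro_mask, truth$csf_mask,
              params = list(source = "phantom_truth"))
}
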