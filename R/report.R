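# Table-style summaries: CSF volume, interface area, surface amplification
# factor and microstructure volume fraction, with and without the
# microstructure, with angular renormalization for an excluded sector.

#' Surface amplification factor
#'
#' Ratio of the measured interface area to the interface area of the same
#' compartment with the microstructure digitally removed.
#'
#' @param measured_area interface area with microstructure.
#' @param no_micro_area interface area of the emptied compartment.
#' @return The unitless amplification factor.
#' @export
amplification_factor <- function(measured_area, no_micro_area) {
  if (no_micro_area <= 0) stop("reference area must be positive")
  measured_area / no_micro_area
}

#' Microstructure volume fraction
#'
#' Fraction of the emptied-compartment volume that the microstructure
#' occupies: `(no_micro - measured) / no_micro`.
#'
#' @param measured_csf_mm3 CSF volume with microstructure in place.
#' @param no_micro_csf_mm3 CSF volume with the microstructure removed.
#' @return Fraction in `[0, 1]`.
#' @export
volume_fraction <- function(measured_csf_mm3, no_micro_csf_mm3) {
  if (!(no_micro_csf_mm3 >= measured_csf_mm3 && measured_csf_mm3 > 0))
    stop("require no_micro >= measured > 0")
  (no_micro_csf_mm3 - measured_csf_mm3) / no_micro_csf_mm3
}

#' Angular renormalization factor
#'
#' @param excluded_angle_deg width of the discarded sector, degrees.
#' @return `360 / (360 - angle)`.
#' @export
renormalization_factor <- function(excluded_angle_deg) {
  if (excluded_angle_deg < 0 || excluded_angle_deg >= 360)
    stop("excluded angle must be in [0, 360)")
  360 / (360 - excluded_angle_deg)
}

# round half away from zero at k decimals (presentation rounding)
round_half_up <- function(x, k = 2) {
  sign(x) * floor(abs(x) * 10^k + 0.5) / 10^k
}

#' Reference morphometric measurements of the human ON SAS
#'
#' Published reference measurements of two optic-nerve subarachnoid-space
#' specimens (a bulbar and an intraorbital segment): section length, CSF
#' volume and CSF interface area, each measured with the microstructure in
#' place and digitally removed. Used for arithmetic consistency checks of
#' the derived amplification factors and volume fractions.
#'
#' @return A tibble with columns `dataset`, `segment`, `quantity`,
#'   `measured`, `no_microstructure`.
#' @export
on_sas_reference_table <- function() {
  path <- system.file("extdata", "on_sas_reference_table.csv",
                      package = "sasmorph")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Amplification and volume fraction from a reference table
#'
#' Recomputes the derived quantities of [on_sas_reference_table()] (or a
#' table of the same shape) from its printed areas and volumes.
#'
#' @param ref a reference table; default [on_sas_reference_table()].
#' @return A tibble with one row per dataset: `amplification_factor`,
#'   `volume_fraction`.
#' @export
reference_consistency <- function(ref = on_sas_reference_table()) {
  ds <- unique(ref$dataset)
  rows <- lapply(ds, function(d) {
    sub <- ref[ref$dataset == d, ]
    area <- sub[sub$quantity == "interface_area_mm2", ]
    vol <- sub[sub$quantity == "csf_volume_mm3", ]
    tibble::tibble(
      dataset = d, segment = sub$segment[1],
      amplification_factor = amplification_factor(area$measured,
                                                  area$no_microstructure),
      volume_fraction = volume_fraction(vol$measured,
                                        vol$no_microstructure))
  })
  do.call(rbind, rows)
}

# ---- full report ---------------------------------------------------------

# measure volume and interface area of the CSF compartment of a segment
# set, discarding an angular sector at measurement time (voxels for the
# volume, triangles for the area — masks are left intact so the sector
# boundary creates no artificial cut faces) and renormalizing by
# 360/(360 - angle).
measure_compartment <- function(segs, epsilon_um, regularize_sigma_vox) {
  v <- segs$voxel_size_um
  d <- dim(segs$csf_mask$data)
  sector <- segs$excluded_sector
  renorm <- 1
  inside_vox <- NULL
  if (!is.null(sector) && sector$angle_deg > 0) {
    renorm <- renormalization_factor(sector$angle_deg)
    inside_vox <- sector_membership(d, v, sector)
  }
  phi <- signed_distance(segs$csf_mask, source = "csf")
  u <- pmin(pmax((phi$phi + epsilon_um) / (2 * epsilon_um), 0), 1)
  if (!is.null(inside_vox)) u[inside_vox] <- 0
  vol_um3 <- sum(u) * v^3 * renorm

  mesh <- extract_zero_levelset(phi, regularize_sigma_vox)
  ar <- triangle_areas(mesh)
  keep <- rep(TRUE, length(ar))
  cen <- mesh_triangle_centroids(mesh)
  if (nrow(cen) > 0) {
    # centroids to the grid-centered um frame
    cc <- sweep(cen, 2, (d - 1) / 2 * v)
    if (!is.null(inside_vox)) {
      az <- (atan2(cc[, 2] - sector$center_um[2],
                   cc[, 1] - sector$center_um[1]) * 180 / pi) %% 360
      rel <- (az - sector$reference_deg %% 360) %% 360
      keep <- rel >= sector$angle_deg
    }
    # outer (dura-facing) boundary: triangles at the outermost CSF radius
    idx <- which(segs$csf_mask$data, arr.ind = TRUE)
    ax <- grid_axes_um(d, v)
    r_out <- max(sqrt(ax[[1]][idx[, 1]]^2 + ax[[2]][idx[, 2]]^2))
    outer_tri <- sqrt(cc[, 1]^2 + cc[, 2]^2) >= r_out - 1.5 * v
  } else {
    outer_tri <- logical(0)
  }
  comp <- mesh_components(mesh)
  area_total <- sum(ar[keep]) * renorm
  area_interior <- sum(ar[keep & !outer_tri]) * renorm
  area_by_comp <- if (length(comp) > 0)
    vapply(split(ar[keep], comp[keep]), sum, numeric(1)) * renorm
    else numeric(0)
  list(volume_um3 = vol_um3, volume_mm3 = vol_um3 * 1e-12,
       area_um2 = area_total, area_mm2 = area_total * 1e-6,
       area_interior_mm2 = area_interior * 1e-6,
       area_by_component_um2 = area_by_comp,
       renormalization_factor = renorm)
}

#' Compile the morphometry report
#'
#' Runs volumetry, surface extraction and morphometry on the measured
#' segmentation and on its "no microstructure" counterfactual, applies
#' sector exclusion at measurement time, and assembles the summary:
#' volumes, interface areas (total, and excluding the outer dura-facing
#' boundary), amplification factor, microstructure volume fraction,
#' thickness/separation density functions, and the space census.
#'
#' @param segs a [segment_set] (with an `excluded_sector` recorded if a
#'   damaged sector is to be discarded).
#' @param epsilon_um mollification half-width for volumetry (default: one
#'   voxel).
#' @param regularize_sigma_vox meshing regularization (see
#'   [extract_zero_levelset()]).
#' @param bin_width_um bin width for the density functions (default: one
#'   voxel).
#' @param census_threshold_um diameter threshold of the space census;
#'   `NULL` skips the census.
#' @param h_um h-maxima depth for the census.
#' @param compute_pdfs logical; skip the density functions if FALSE.
#' @return An object of class `morphometry_report`.
#' @export
compile_report <- function(segs, epsilon_um = NULL,
                           regularize_sigma_vox = 0.8,
                           bin_width_um = NULL,
                           census_threshold_um = 130, h_um = NULL,
                           compute_pdfs = TRUE) {
  stopifnot(inherits(segs, "segment_set"))
  v <- segs$voxel_size_um
  if (is.null(epsilon_um)) epsilon_um <- v
  if (is.null(bin_width_um)) bin_width_um <- v
  d <- dim(segs$csf_mask$data)

  measured <- measure_compartment(segs, epsilon_um, regularize_sigma_vox)
  nomicro_segs <- remove_microstructure(segs)
  nomicro <- measure_compartment(nomicro_segs, epsilon_um,
                                 regularize_sigma_vox)

  amp <- amplification_factor(measured$area_mm2, nomicro$area_mm2)
  amp_by_comp <- sum(measured$area_by_component_um2) /
    sum(nomicro$area_by_component_um2)
  vf <- volume_fraction(measured$volume_mm3, nomicro$volume_mm3)

  thick_pdf <- sep_pdf <- NULL
  census <- NULL
  if (compute_pdfs || !is.null(census_threshold_um)) {
    sep_map <- if (any(segs$csf_mask$data)) separation(segs) else NULL
    if (compute_pdfs) {
      if (any(segs$sas_mask$data))
        thick_pdf <- thickness_pdf(
          local_thickness(segs$sas_mask, foreground = "sas"), bin_width_um)
      if (!is.null(sep_map)) sep_pdf <- thickness_pdf(sep_map, bin_width_um)
    }
    if (!is.null(census_threshold_um) && !is.null(sep_map))
      census <- count_intertrabecular_spaces(sep_map, census_threshold_um,
                                             h_um)
  }

  structure(list(
    section_length_mm = d[3] * v * 1e-3,
    csf_volume_mm3 = c(measured = measured$volume_mm3,
                       no_microstructure = nomicro$volume_mm3),
    interface_area_mm2 = c(measured = measured$area_mm2,
                           no_microstructure = nomicro$area_mm2),
    interface_area_interior_mm2 = c(
      measured = measured$area_interior_mm2,
      no_microstructure = nomicro$area_interior_mm2),
    amplification_factor = amp,
    amplification_factor_by_component = amp_by_comp,
    microstructure_volume_fraction = vf,
    microstructure_volume_mm3 = nomicro$volume_mm3 - measured$volume_mm3,
    renormalization_factor = measured$renormalization_factor,
    thickness_pdf = thick_pdf,
    separation_pdf = sep_pdf,
    space_census = census,
    params = list(epsilon_um = epsilon_um,
                  regularize_sigma_vox = regularize_sigma_vox,
                  bin_width_um = bin_width_um,
                  census_threshold_um = census_threshold_um,
                  segment_params = segs$params)),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  f <- function(q) sprintf("%.2f", round_half_up(q, 2))
  cat("Quantitative analysis of the CSF space\n")
  cat(sprintf("  %-28s %10s %18s\n", "", "Measured", "No microstructure"))
  cat(sprintf("  %-28s %10s %18s\n", "Section length (mm)",
              f(x$section_length_mm), f(x$section_length_mm)))
  cat(sprintf("  %-28s %10s %18s\n", "CSF space volume (mm^3)",
              f(x$csf_volume_mm3[["measured"]]),
              f(x$csf_volume_mm3[["no_microstructure"]])))
  cat(sprintf("  %-28s %10s %18s\n", "SAS/CSF interface area (mm^2)",
              f(x$interface_area_mm2[["measured"]]),
              f(x$interface_area_mm2[["no_microstructure"]])))
  cat(sprintf("  amplification factor: %s\n", f(x$amplification_factor)))
  cat(sprintf("  microstructure volume fraction: %.1f%%\n",
              100 * x$microstructure_volume_fraction))
  if (x$renormalization_factor != 1)
    cat(sprintf("  angular renormalization: x%.4f\n",
                x$renormalization_factor))
  if (!is.null(x$space_census))
    cat(sprintf("  intertrabecular spaces (> %g um): %d\n",
                attr(x$space_census, "diameter_threshold_um"),
                nrow(x$space_census)))
  invisible(x)
}
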