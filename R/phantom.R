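#' Specification of the synthetic optic-nerve phantom
#'
#' The phantom emulates a tomographic section through the optic nerve and
#' its subarachnoid space: a solid nerve cylinder along z, an annular
#' CSF-filled gap, a peripheral dural wall extending to the grid edge, and
#' a microstructure of trabeculae (capsules bridging nerve and dura) and
#' septae (thickened radial half-planes of limited axial extent). Tissue
#' carries fine-scale internal texture (fascicle-like), the CSF is dark,
#' and thin bright filaments mimic fixation damage. All geometry has
#' closed-form volume and area, recorded independently of voxelization.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size_um isotropic voxel spacing, µm.
#' @param nerve_radius_um radius of the nerve cylinder.
#' @param dura_radius_um inner radius of the dural wall (outer boundary of
#'   the SAS annulus); the wall itself extends to the grid edge.
#' @param trabecula_count number of trabeculae.
#' @param trabecula_radius_um_range `(min, max)` trabecular radii.
#' @param trabecula_min_gap_um minimum surface-to-surface clearance between
#'   trabeculae, so neighboring tubes stay individually resolvable.
#' @param septum_count number of septae.
#' @param septum_thickness_um septal thickness.
#' @param noise_sigma additive Gaussian noise, grayscale units.
#' @param texture_amplitude amplitude of the band-limited intra-tissue
#'   texture (grayscale units); tomograms of nerve tissue are textured at
#'   the fascicle scale, and the segmentation stage relies on this.
#' @param texture_scale_um correlation length of the tissue texture.
#' @param gradient_amplitude per-tile smooth background amplitude (used by
#'   [add_tile_backgrounds_and_split()], not by [generate_phantom()]).
#' @param artifact_count number of fixation-like bright filaments.
#' @param artifact_thickness_um filament thickness (must be thinner than
#'   the smallest trabecula so enhancement can separate them by scale).
#' @param excluded_sector_deg angular width of the damaged sector that the
#'   analysis discards (recorded for downstream renormalization).
#' @param membrane_thickness_um thickness of the bright meningeal lining
#'   (pia / arachnoid with their meningothelial cell layers) on the
#'   CSF-facing nerve and dura walls.
#' @param membrane_extra_intensity intensity added to the lining on top of
#'   `solid_intensity`.
#' @param solid_intensity,csf_intensity mean grayscale of tissue and CSF.
#' @param invert_polarity flip the intensity polarity.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(192L, 192L, 192L),
                         voxel_size_um = 1,
                         nerve_radius_um = 28,
                         dura_radius_um = 68,
                         trabecula_count = 16L,
                         trabecula_radius_um_range = c(4, 10),
                         trabecula_min_gap_um = 14,
                         septum_count = 2L,
                         septum_thickness_um = 6,
                         noise_sigma = 0.04,
                         texture_amplitude = 0.12,
                         texture_scale_um = 3,
                         gradient_amplitude = 0.15,
                         artifact_count = 6L,
                         artifact_thickness_um = 2,
                         excluded_sector_deg = 60,
                         membrane_thickness_um = 4,
                         membrane_extra_intensity = 0.25,
                         solid_intensity = 0.75,
                         csf_intensity = 0.25,
                         invert_polarity = FALSE,
                         rng_seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_um = voxel_size_um,
               nerve_radius_um = nerve_radius_um,
               dura_radius_um = dura_radius_um,
               trabecula_count = as.integer(trabecula_count),
               trabecula_radius_um_range = trabecula_radius_um_range,
               trabecula_min_gap_um = trabecula_min_gap_um,
               septum_count = as.integer(septum_count),
               septum_thickness_um = septum_thickness_um,
               noise_sigma = noise_sigma,
               texture_amplitude = texture_amplitude,
               texture_scale_um = texture_scale_um,
               gradient_amplitude = gradient_amplitude,
               artifact_count = as.integer(artifact_count),
               artifact_thickness_um = artifact_thickness_um,
               excluded_sector_deg = excluded_sector_deg,
               membrane_thickness_um = membrane_thickness_um,
               membrane_extra_intensity = membrane_extra_intensity,
               solid_intensity = solid_intensity,
               csf_intensity = csf_intensity,
               invert_polarity = isTRUE(invert_polarity),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  half_extent <- min(spec$grid_shape[1:2]) * spec$voxel_size_um / 2
  if (!(spec$nerve_radius_um < spec$dura_radius_um))
    stop("nerve_radius_um must be smaller than dura_radius_um")
  if (!(spec$dura_radius_um < half_extent))
    stop("dura_radius_um must be smaller than half the lateral grid extent")
  rng <- spec$trabecula_radius_um_range
  if (spec$trabecula_count > 0 && rng[1] < 2 * spec$voxel_size_um)
    stop("minimum trabecula radius must be at least 2 voxels to be resolvable")
  gap <- spec$dura_radius_um - spec$nerve_radius_um
  if (spec$trabecula_count > 0 && 2 * rng[2] >= gap)
    stop("trabeculae cannot fit inside the annulus: 2*max radius >= gap")
  invisible(spec)
}

# --- primitive signed distances (negative inside solid), points in um ----

capsule_sdf <- function(px, py, pz, p0, p1, r) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]; vz <- p1[3] - p0[3]
  l2 <- vx^2 + vy^2 + vz^2
  t <- ((px - p0[1]) * vx + (py - p0[2]) * vy + (pz - p0[3]) * vz) / l2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - p0[1] - t * vx)^2 + (py - p0[2] - t * vy)^2 +
       (pz - p0[3] - t * vz)^2) - r
}

septum_sdf <- function(px, py, pz, sep) {
  # thickened radial half-plane, clipped to the annulus and a z interval
  u <- px * sep$n[1] + py * sep$n[2]         # across-thickness coordinate
  v <- px * sep$dir[1] + py * sep$dir[2]     # outward radial coordinate
  rho <- sqrt(px^2 + py^2)
  pmax(abs(u) - sep$half_thickness,
       sep$za - pz, pz - sep$zb,
       sep$rmin - rho, rho - sep$rmax,
       -v)
}

# minimum over a set of capsules, evaluated only inside their bounding boxes
min_capsule_field <- function(field, axes, caps, voxel_size_um) {
  d <- dim(field)
  for (ci in seq_len(nrow(caps))) {
    p0 <- as.numeric(caps[ci, c("x0", "y0", "z0")])
    p1 <- as.numeric(caps[ci, c("x1", "y1", "z1")])
    r <- caps$radius_um[ci]
    pad <- r + 2 * voxel_size_um
    ii <- which(axes[[1]] >= min(p0[1], p1[1]) - pad &
                axes[[1]] <= max(p0[1], p1[1]) + pad)
    jj <- which(axes[[2]] >= min(p0[2], p1[2]) - pad &
                axes[[2]] <= max(p0[2], p1[2]) + pad)
    kk <- which(axes[[3]] >= min(p0[3], p1[3]) - pad &
                axes[[3]] <= max(p0[3], p1[3]) + pad)
    if (!length(ii) || !length(jj) || !length(kk)) next
    px <- axes[[1]][ii]; py <- axes[[2]][jj]; pz <- axes[[3]][kk]
    g <- capsule_sdf(rep(px, times = length(jj) * length(kk)),
                     rep(rep(py, each = length(ii)), times = length(kk)),
                     rep(pz, each = length(ii) * length(jj)),
                     p0, p1, r)
    sub <- field[ii, jj, kk, drop = FALSE]
    field[ii, jj, kk] <- array(pmin(as.vector(sub), g), dim(sub))
  }
  field
}

# evaluate the full solid SDF at arbitrary points (um, grid-centered)
solid_sdf_points <- function(px, py, pz, geom) {
  rho <- sqrt(px^2 + py^2)
  d <- pmin(rho - geom$nerve_radius_um, geom$dura_radius_um - rho)
  caps <- geom$trabeculae
  if (!is.null(caps) && nrow(caps) > 0) {
    for (ci in seq_len(nrow(caps))) {
      p0 <- as.numeric(caps[ci, c("x0", "y0", "z0")])
      p1 <- as.numeric(caps[ci, c("x1", "y1", "z1")])
      r <- caps$radius_um[ci]
      sel <- which(px >= min(p0[1], p1[1]) - r - 2 &
                   px <= max(p0[1], p1[1]) + r + 2 &
                   py >= min(p0[2], p1[2]) - r - 2 &
                   py <= max(p0[2], p1[2]) + r + 2 &
                   pz >= min(p0[3], p1[3]) - r - 2 &
                   pz <= max(p0[3], p1[3]) + r + 2)
      if (length(sel))
        d[sel] <- pmin(d[sel], capsule_sdf(px[sel], py[sel], pz[sel],
                                           p0, p1, r))
    }
  }
  for (sep in geom$septa)
    d <- pmin(d, septum_sdf(px, py, pz, sep))
  d
}

# segment-segment minimum distance (used to keep trabeculae from merging)
segseg_dist <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  dd <- sum(u * w); e <- sum(v * w)
  den <- a * c - b * b
  s <- if (den > 1e-12) (b * e - c * dd) / den else 0
  s <- min(max(s, 0), 1)
  t <- if (c > 1e-12) (b * s + e) / c else 0
  t <- min(max(t, 0), 1)
  s <- if (a > 1e-12) min(max((b * t - dd) / a, 0), 1) else 0
  sqrt(sum((p0 + s * u - q0 - t * v)^2))
}

#' Generate the synthetic phantom
#'
#' Produces the grayscale volume and the matching ground truth: component
#' masks, per-primitive records, and closed-form solid volume and CSF
#' interface area computed from the generating primitives before
#' voxelization. Boundary voxels are supersampled 2x per axis so the
#' grayscale carries sub-voxel intensity ramps.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_grid]) and `truth`
#'   (class `phantom_truth`): masks `solid_mask` (nerve + microstructure),
#'   `csf_mask`, `nerve_mask`, `dura_mask`, `micro_mask`, tibbles
#'   `trabeculae`, `septa`, `artifacts`, and the analytic summaries
#'   `analytic_solid_volume_um3` and `analytic_interface_area_um2`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  withr::with_seed(spec$rng_seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape
  v <- spec$voxel_size_um
  axes <- grid_axes_um(d, v)
  Rn <- spec$nerve_radius_um; Rd <- spec$dura_radius_um
  Lz <- d[3] * v
  zmin <- axes[[3]][1] - v / 2; zmax <- axes[[3]][d[3]] + v / 2
  gap <- Rd - Rn

  # ---- draw trabeculae (capsules bridging nerve and dura) ----
  trab <- NULL
  if (spec$trabecula_count > 0) {
    rows <- vector("list", spec$trabecula_count)
    placed <- list()
    for (i in seq_len(spec$trabecula_count)) {
      ok <- FALSE
      for (try in seq_len(2000)) {
        r <- runif(1, spec$trabecula_radius_um_range[1],
                   spec$trabecula_radius_um_range[2])
        th <- runif(1, 0, 2 * pi)
        z0 <- runif(1, zmin + 0.12 * Lz, zmax - 0.12 * Lz)
        dth <- runif(1, -0.25, 0.25)
        dz <- runif(1, -0.5, 0.5) * gap
        p0 <- c((Rn - 2) * cos(th), (Rn - 2) * sin(th), z0)
        p1 <- c((Rd + 2) * cos(th + dth), (Rd + 2) * sin(th + dth), z0 + dz)
        if (abs(p1[3]) > Lz / 2 - 2 * v) next
        clear <- TRUE
        for (pp in placed) {
          # keep a clear surface-to-surface gap so neighboring trabeculae
          # stay individually resolvable by the segmentation chain
          if (segseg_dist(p0, p1, pp$p0, pp$p1) <
                r + pp$r + spec$trabecula_min_gap_um) {
            clear <- FALSE; break
          }
        }
        if (!clear) next
        placed[[length(placed) + 1]] <- list(p0 = p0, p1 = p1, r = r)
        rows[[i]] <- c(p0, p1, r)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("trabeculae cannot fit inside the annulus at this density")
    }
    m <- do.call(rbind, rows)
    trab <- tibble::tibble(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3],
                           x1 = m[, 4], y1 = m[, 5], z1 = m[, 6],
                           radius_um = m[, 7])
    # analytic in-annulus length: segment parameters where |P_xy(t)| = Rn, Rd
    geom_len <- function(row) {
      p0 <- c(row[["x0"]], row[["y0"]], row[["z0"]])
      p1 <- c(row[["x1"]], row[["y1"]], row[["z1"]])
      u <- p1 - p0
      tcross <- function(R) {
        a <- u[1]^2 + u[2]^2
        b <- 2 * (p0[1] * u[1] + p0[2] * u[2])
        cc <- p0[1]^2 + p0[2]^2 - R^2
        disc <- b^2 - 4 * a * cc
        ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
        ts[ts >= 0 & ts <= 1][1]
      }
      tn <- tcross(Rn); td <- tcross(Rd)
      len <- abs(td - tn) * sqrt(sum(u^2))
      # wall incidence: angle between segment and the wall normal (radial)
      uhat <- u / sqrt(sum(u^2))
      cosn <- function(tt) {
        p <- p0 + tt * u
        nr <- c(p[1], p[2], 0) / sqrt(p[1]^2 + p[2]^2)
        abs(sum(uhat * nr))
      }
      c(len = len, cos_n = cosn(tn), cos_d = cosn(td))
    }
    gl <- t(apply(trab, 1, geom_len))
    trab$length_in_annulus_um <- gl[, "len"]
    trab$lateral_area_um2 <- 2 * pi * trab$radius_um * gl[, "len"]
    trab$wall_hole_area_um2 <- pi * trab$radius_um^2 *
      (1 / gl[, "cos_n"] + 1 / gl[, "cos_d"])
  } else {
    trab <- tibble::tibble(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                           x1 = numeric(), y1 = numeric(), z1 = numeric(),
                           radius_um = numeric(),
                           length_in_annulus_um = numeric(),
                           lateral_area_um2 = numeric(),
                           wall_hole_area_um2 = numeric())
  }

  # ---- septa: thickened radial half-planes over a z sub-interval ----
  septa <- list()
  if (spec$septum_count > 0) {
    for (i in seq_len(spec$septum_count)) {
      phi <- runif(1, 0, 2 * pi)
      dirv <- c(cos(phi), sin(phi))
      nv <- c(-sin(phi), cos(phi))
      zl <- 0.3 * Lz
      za <- runif(1, zmin + 0.1 * Lz, zmax - 0.1 * Lz - zl)
      septa[[i]] <- list(n = nv, dir = dirv, za = za, zb = za + zl,
                         half_thickness = spec$septum_thickness_um / 2,
                         rmin = Rn - 2, rmax = Rd + 2)
    }
  }

  geom <- list(nerve_radius_um = Rn, dura_radius_um = Rd,
               trabeculae = trab, septa = septa)

  # ---- voxelize: full-grid SDF with per-primitive bounding boxes ----
  rho <- radial_coord(d, v)
  sdf <- array(rep(pmin(rho - Rn, Rd - rho), times = d[3]), d)
  if (nrow(trab) > 0)
    sdf <- min_capsule_field(sdf, axes, trab, v)
  if (length(septa) > 0) {
    px <- rep(axes[[1]], times = d[2] * d[3])
    py <- rep(rep(axes[[2]], each = d[1]), times = d[3])
    pz <- rep(axes[[3]], each = d[1] * d[2])
    for (sep in septa)
      sdf <- array(pmin(as.vector(sdf), septum_sdf(px, py, pz, sep)), d)
  }

  solid_all <- sdf <= 0
  nerve_mask <- array(rep(rho <= Rn, times = d[3]), d)
  dura_mask <- array(rep(rho >= Rd, times = d[3]), d)
  micro_mask <- solid_all & !nerve_mask & !dura_mask
  csf <- !solid_all & !dura_mask

  # ---- partial-volume grayscale: 2x supersampling on boundary voxels ----
  frac <- ifelse(sdf <= 0, 1, 0)
  bidx <- which(abs(sdf) <= 0.87 * v)
  if (length(bidx) > 0) {
    ij <- arrayInd(bidx, d)
    bx <- axes[[1]][ij[, 1]]; by <- axes[[2]][ij[, 2]]; bz <- axes[[3]][ij[, 3]]
    acc <- numeric(length(bidx))
    for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25))
      for (oz in c(-0.25, 0.25)) {
        ds <- solid_sdf_points(bx + ox * v, by + oy * v, bz + oz * v, geom)
        acc <- acc + (ds <= 0)
      }
    frac[bidx] <- acc / 8
  }

  # ---- fixation-like bright filaments crossing the CSF ----
  arts <- tibble::tibble(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                         x1 = numeric(), y1 = numeric(), z1 = numeric(),
                         radius_um = numeric())
  afrac <- NULL
  artifact_mask <- array(FALSE, d)
  if (spec$artifact_count > 0) {
    rows <- vector("list", spec$artifact_count)
    for (i in seq_len(spec$artifact_count)) {
      thc <- runif(1, 0, 2 * pi)
      rc <- runif(1, Rn + 0.2 * gap, Rd - 0.2 * gap)
      zc <- runif(1, zmin + 0.15 * Lz, zmax - 0.15 * Lz)
      ctr <- c(rc * cos(thc), rc * sin(thc), zc)
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      hl <- runif(1, 0.4, 0.9) * gap
      rows[[i]] <- c(ctr - hl * dirv, ctr + hl * dirv,
                     spec$artifact_thickness_um / 2)
    }
    m <- do.call(rbind, rows)
    arts <- tibble::tibble(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3],
                           x1 = m[, 4], y1 = m[, 5], z1 = m[, 6],
                           radius_um = m[, 7])
    asdf <- array(1e9, d)
    asdf <- min_capsule_field(asdf, axes, arts, v)
    artifact_mask <- asdf <= 0
    afrac <- ifelse(asdf <= -0.87 * v, 1, ifelse(asdf >= 0.87 * v, 0, 0))
    abidx <- which(abs(asdf) < 0.87 * v)
    if (length(abidx) > 0) {
      # linear sub-voxel ramp is adequate for these sub-resolution filaments
      afrac[abidx] <- pmin(pmax(0.5 - asdf[abidx] / v, 0), 1)
    }
  }

  # ---- assemble grayscale ----
  img <- spec$csf_intensity + frac * (spec$solid_intensity - spec$csf_intensity)
  mem <- NULL
  if (spec$membrane_extra_intensity > 0 && spec$membrane_thickness_um > 0) {
    # bright meningothelial lining on the CSF-facing walls: a dense,
    # homogeneous cell layer (no fascicle texture)
    wall <- pmin(abs(rho - Rn), abs(rho - Rd))
    mem <- array(rep(wall <= spec$membrane_thickness_um, times = d[3]), d)
    img <- img + spec$membrane_extra_intensity * frac * mem
  }
  if (spec$texture_amplitude > 0) {
    tex <- array(rnorm(prod(d)), d)
    tex <- array(cpp_gauss3(tex, d, spec$texture_scale_um / v), d)
    tex <- tex / sd(tex) * spec$texture_amplitude
    tex_w <- if (is.null(mem)) frac else frac * !mem
    img <- img + tex * tex_w
  }
  if (!is.null(afrac))
    img <- img * (1 - afrac) + (spec$solid_intensity + 0.1) * afrac
  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(prod(d), 0, spec$noise_sigma), d)
  if (spec$invert_polarity)
    img <- 1 - img

  # ---- analytic ground truth from the generating primitives ----
  sept_vol <- sum(vapply(septa, function(s)
    2 * s$half_thickness * (Rd - Rn) * (s$zb - s$za), numeric(1)))
  sept_area <- sum(vapply(septa, function(s) {
    w <- Rd - Rn; h <- s$zb - s$za; t <- 2 * s$half_thickness
    2 * w * h + 2 * t * w - 2 * t * h
  }, numeric(1)))
  vol_solid <- pi * Rn^2 * Lz +
    sum(pi * trab$radius_um^2 * trab$length_in_annulus_um) + sept_vol
  area_csf <- 2 * pi * (Rn + Rd) * Lz +
    sum(trab$lateral_area_um2 - trab$wall_hole_area_um2) + sept_area

  truth <- structure(list(
    solid_mask = binary_mask(array(nerve_mask | micro_mask, d), v),
    csf_mask = binary_mask(array(csf, d), v),
    nerve_mask = binary_mask(array(nerve_mask, d), v),
    dura_mask = binary_mask(array(dura_mask, d), v),
    micro_mask = binary_mask(array(micro_mask, d), v),
    artifact_mask = binary_mask(array(artifact_mask, d), v),
    trabeculae = trab, septa = septa, artifacts = arts,
    analytic_solid_volume_um3 = vol_solid,
    analytic_interface_area_um2 = area_csf,
    excluded_sector_deg = spec$excluded_sector_deg,
    spec = spec), class = "phantom_truth")

  list(volume = voxel_grid(img, v), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d trabeculae, %d septa, %d artifacts\n",
              nrow(x$trabeculae), length(x$septa), nrow(x$artifacts)))
  cat(sprintf("  analytic solid volume  %.4g um^3\n",
              x$analytic_solid_volume_um3))
  cat(sprintf("  analytic CSF interface %.4g um^2\n",
              x$analytic_interface_area_um2))
  invisible(x)
}

#' Decompose a volume into overlapping tiles with per-tile backgrounds
#'
#' Covers the volume with a regular grid of overlapping tiles, adds an
#' independent smooth (low-order polynomial) additive background field to
#' each tile — emulating the slowly varying intensity offsets of in-axis
#' acquisition — and returns the true voxel offsets for registration
#' scoring.
#'
#' @param volume a [voxel_grid].
#' @param tile_shape voxels per axis of each tile.
#' @param overlap_fraction nominal fractional overlap in (0, 0.5].
#' @param gradient_amplitude peak amplitude of each tile's background.
#' @param rng_seed seed for the background fields.
#' @param poly_degree polynomial degree of the backgrounds (default 2).
#' @return A list of tiles; each element has `tile` (a [voxel_grid] whose
#'   origin is its true global offset), `true_offset` (0-based voxel
#'   triple) and `id`.
#' @export
add_tile_backgrounds_and_split <- function(volume, tile_shape,
                                           overlap_fraction = 0.2,
                                           gradient_amplitude = 0.15,
                                           rng_seed = 1L,
                                           poly_degree = 2L) {
  stopifnot(inherits(volume, "voxel_grid"))
  d <- dim(volume$data)
  tile_shape <- as.integer(rep(tile_shape, length.out = 3))
  if (!(overlap_fraction > 0 && overlap_fraction <= 0.5))
    stop("overlap_fraction must be in (0, 0.5]")
  if (any(tile_shape > d))
    stop("tile_shape cannot exceed the volume; cannot cover with overlap")

  starts <- lapply(1:3, function(a) {
    n <- d[a]; t <- tile_shape[a]
    if (t == n) return(1L)
    step <- max(1L, as.integer(floor(t * (1 - overlap_fraction))))
    s <- seq(1L, n - t + 1L, by = step)
    if (tail(s, 1) != n - t + 1L) s <- c(s, n - t + 1L)
    as.integer(s)
  })
  pos <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])

  monomials <- function(u1, u2, u3, degree) {
    out <- list()
    for (i in 0:degree) for (j in 0:degree) for (k in 0:degree)
      if (i + j + k <= degree && i + j + k > 0)
        out[[length(out) + 1]] <- u1^i * u2^j * u3^k
    out
  }

  withr::with_seed(rng_seed, {
    lapply(seq_len(nrow(pos)), function(ti) {
      s <- as.integer(pos[ti, ])
      e <- s + tile_shape - 1L
      sub <- volume$data[s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE]
      if (gradient_amplitude > 0) {
        u <- lapply(1:3, function(a) seq(-1, 1, length.out = tile_shape[a]))
        U1 <- array(rep(u[[1]], times = prod(tile_shape[2:3])), tile_shape)
        U2 <- array(rep(rep(u[[2]], each = tile_shape[1]),
                        times = tile_shape[3]), tile_shape)
        U3 <- array(rep(u[[3]], each = prod(tile_shape[1:2])), tile_shape)
        mono <- monomials(U1, U2, U3, poly_degree)
        coef <- runif(length(mono), -1, 1)
        bg <- Reduce(`+`, Map(`*`, mono, coef))
        bg <- bg / max(abs(bg)) * gradient_amplitude * runif(1, 0.6, 1)
        sub <- sub + bg
      }
      list(tile = voxel_grid(sub, volume$voxel_size_um,
                             origin = volume$origin + (s - 1L)),
           true_offset = as.numeric(s - 1L), id = ti)
    })
  })
}
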