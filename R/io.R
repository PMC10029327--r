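# Readers and writers for the standard interchange formats: multi-page
# TIFF stacks for volumes and masks, a plain-text layout file for tiles,
# CSV for offsets / density functions / census, JSON for metadata, and
# PLY/STL for meshes.

#' Write / read a volume as a multi-page 32-bit float TIFF stack
#'
#' @param grid a [voxel_grid].
#' @param path output file.
#' @return `path`, invisibly (writer); a [voxel_grid] (reader).
#' @export
write_volume_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  # the TIFF writer stores samples in [0, 1]; map affinely and record the
  # transform in the JSON sidecar so reading restores physical values
  lo <- min(grid$data); hi <- max(grid$data)
  scale <- if (hi > lo) hi - lo else 1
  slices <- lapply(seq_len(d[3]),
                   function(k) (grid$data[, , k] - lo) / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(voxel_size_um = grid$voxel_size_um, origin = grid$origin,
               value_offset = lo, value_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size_um spacing override if no JSON sidecar is present.
#' @export
read_volume_tiff <- function(path, voxel_size_um = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE)
  d <- c(dim(slices[[1]]), length(slices))
  arr <- array(unlist(slices), d)
  origin <- c(0, 0, 0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
    origin <- meta$origin
    if (!is.null(meta$value_scale))
      arr <- arr * meta$value_scale + meta$value_offset
  }
  if (is.null(voxel_size_um)) voxel_size_um <- 1
  voxel_grid(arr, voxel_size_um, origin)
}

#' Write a binary mask as an 8-bit TIFF stack
#'
#' @param mask a [binary_mask].
#' @param path output file.
#' @export
write_mask_tiff <- function(mask, path) {
  assert_mask(mask)
  d <- dim(mask$data)
  slices <- lapply(seq_len(d[3]), function(k) mask$data[, , k] * 1.0)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' Write / read a tile set with a plain-text layout file
#'
#' The layout file has one line per tile: `id x y z` (nominal 0-based
#' voxel offsets); tiles are stored as individual TIFF stacks alongside.
#'
#' @param tiles output of [add_tile_backgrounds_and_split()].
#' @param dir output directory.
#' @return The layout file path (writer); a tile list (reader).
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- file.path(dir, "layout.txt")
  con <- file(layout, "w")
  on.exit(close(con))
  for (t in tiles) {
    fn <- sprintf("tile_%03d.tif", t$id)
    write_volume_tiff(t$tile, file.path(dir, fn))
    writeLines(sprintf("%d %g %g %g", t$id, t$true_offset[1],
                       t$true_offset[2], t$true_offset[3]), con)
  }
  invisible(layout)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir) {
  layout <- read.table(file.path(dir, "layout.txt"),
                       col.names = c("id", "x", "y", "z"))
  lapply(seq_len(nrow(layout)), function(i) {
    id <- layout$id[i]
    tile <- read_volume_tiff(file.path(dir, sprintf("tile_%03d.tif", id)))
    list(tile = tile, true_offset = as.numeric(layout[i, c("x", "y", "z")]),
         id = id)
  })
}

#' Write resolved tile offsets as CSV
#'
#' @param offsets output of [resolve_offsets()].
#' @param path output file.
#' @export
write_offsets_csv <- function(offsets, path) {
  write.csv(as.data.frame(offsets), path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh as ASCII PLY or STL
#'
#' @param mesh a [triangle_mesh].
#' @param path output file.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nt),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nv > 0)
    writeLines(sprintf("%g %g %g", mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3]), con)
  if (nt > 0)
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L),
               con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  V <- mesh$vertices; Tr <- mesh$triangles
  for (t in seq_len(nrow(Tr))) {
    p <- V[Tr[t, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
             (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
             (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

#' Write a morphometry report as JSON (+ CSV tables)
#'
#' @param report a [compile_report()] result.
#' @param path JSON output file; sibling CSVs are written for the density
#'   functions and census when present.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "morphometry_report"))
  scal <- report[c("section_length_mm", "csf_volume_mm3",
                   "interface_area_mm2", "interface_area_interior_mm2",
                   "amplification_factor",
                   "microstructure_volume_fraction",
                   "microstructure_volume_mm3", "renormalization_factor",
                   "params")]
  jsonlite::write_json(scal, path, auto_unbox = TRUE, digits = NA)
  base <- sub("\\.json$", "", path)
  if (!is.null(report$thickness_pdf))
    write.csv(as.data.frame(report$thickness_pdf),
              paste0(base, "_thickness_pdf.csv"), row.names = FALSE)
  if (!is.null(report$separation_pdf))
    write.csv(as.data.frame(report$separation_pdf),
              paste0(base, "_separation_pdf.csv"), row.names = FALSE)
  if (!is.null(report$space_census))
    write.csv(as.data.frame(report$space_census),
              paste0(base, "_space_census.csv"), row.names = FALSE)
  invisible(path)
}

#' Write a thickness/separation map as a 32-bit float TIFF stack
#'
#' @param map a [thickness_map].
#' @param path output file.
#' @export
write_thickness_tiff <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  write_volume_tiff(voxel_grid(map$thickness, map$voxel_size_um), path)
}
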