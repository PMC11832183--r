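#' Estimate specimen (lobe) volume from segmentation masks
#'
#' The labeled networks sketch the tissue envelope: the voxelwise union of
#' the per-channel masks is closed with a physical ball (anisotropy-aware,
#' radius in um), enclosed cavities are filled, and the resulting lobe mask
#' is counted. Volume is `foreground voxels x dz*dy*dx`.
#'
#' @param masks list of aligned binary `label_mask` objects (one per
#'   channel; single-channel runs pass a list of one).
#' @param closing_radius_um closing ball radius in um (default 50);
#'   bridges the gaps between neighboring structures.
#' @param min_hole only cavities smaller than this voxel count are filled
#'   (default `Inf`: all enclosed cavities).
#' @return A `lobe_volume_result`: `volume_um3`, `lobe_mask`,
#'   `fill_params`.
#' @export
estimate_lobe_volume <- function(masks, closing_radius_um = 50,
                                 min_hole = Inf) {
  if (!length(masks)) stop("need at least one mask")
  if (!all(vapply(masks, inherits, TRUE, "label_mask")))
    stop("masks must be label_mask objects")
  d <- dim(masks[[1]]$voxels)
  sp <- masks[[1]]$spacing
  for (m in masks[-1]) {
    if (!identical(dim(m$voxels), d)) stop("masks must share one shape")
    if (any(abs(m$spacing - sp) > 1e-9)) stop("masks must share spacing")
  }
  un <- Reduce(`|`, lapply(masks, as_binary))
  if (!any(un)) {
    warning("empty mask union: lobe volume is 0; downstream tiles flagged")
    lobe <- label_mask(array(0L, d), sp, c("1" = "lobe"))
    return(structure(list(volume_um3 = 0, lobe_mask = lobe,
                          fill_params = list(
                            closing_radius_um = closing_radius_um,
                            min_hole = min_hole)),
                     class = "lobe_volume_result"))
  }
  lobe <- close_ball(un, closing_radius_um, sp)
  lobe <- fill_holes3d(lobe, min_hole)
  structure(list(
    volume_um3 = sum(lobe) * prod(sp),
    lobe_mask = label_mask(array(as.integer(lobe), d), sp,
                           c("1" = "lobe")),
    fill_params = list(closing_radius_um = closing_radius_um,
                       min_hole = min_hole)),
    class = "lobe_volume_result")
}

DENSITY_FACTORS <- c("m/m3" = 1e12, "mm/mm3" = 1e6, "um/um3" = 1)

#' Network density: length per lobe volume
#'
#' Internally all lengths are um and volumes um^3; conversion to the
#' reporting unit happens here and nowhere else, with exact power-of-ten
#' factors: `m/m3 = (L*1e-6)/(V*1e-18) = L/V * 1e12`, `mm/mm3 = L/V *
#' 1e6`, `um/um3 = L/V`.
#'
#' @param length_um network length(s) in um.
#' @param volume_um3 lobe volume(s) in um^3.
#' @param units `"m/m3"`, `"um/um3"` or `"mm/mm3"`.
#' @return Numeric density vector in the requested units. Entries with
#'   non-positive volume are `NA` and flagged in the logical attribute
#'   `"flagged"` -- distinct from a genuine density of 0 (zero length over
#'   positive volume).
#' @export
compute_density <- function(length_um, volume_um3, units = "m/m3") {
  if (!units %in% names(DENSITY_FACTORS))
    stop("units must be one of: ",
         paste(names(DENSITY_FACTORS), collapse = ", "))
  flagged <- !(volume_um3 > 0)
  dens <- ifelse(flagged, NA_real_,
                 length_um / volume_um3 * DENSITY_FACTORS[[units]])
  attr(dens, "flagged") <- flagged
  attr(dens, "units") <- units
  dens
}

tile_ranges <- function(n, size) {
  starts <- seq(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

#' Per-tile skeleton length and lobe volume
#'
#' Tiles the `(y, x)` extent (full z depth per tile), measuring each
#' tile's skeleton length on the tile's own sub-stack and its lobe volume
#' by counting lobe voxels inside the tile. The lobe mask must be built on
#' the whole stack *before* tiling so that tile volumes are additive and
#' closing does not create seam artifacts.
#'
#' @param skeleton skeleton `label_mask` of the whole stack.
#' @param lobe_mask lobe `label_mask` of the whole stack.
#' @param tile_shape `(ny, nx)` tile size in voxels.
#' @return Data frame with one row per tile: `tile_index`, `tile_z`,
#'   `tile_y`, `tile_x` (origins, 1-based voxels), `length_um`,
#'   `volume_um3`, `tile_voxels`.
#' @export
tile_metrics <- function(skeleton, lobe_mask, tile_shape) {
  stopifnot(inherits(skeleton, "label_mask"),
            inherits(lobe_mask, "label_mask"))
  d <- dim(skeleton$voxels)
  if (!identical(d, dim(lobe_mask$voxels)))
    stop("skeleton and lobe mask shapes differ")
  ys <- tile_ranges(d[2], tile_shape[1])
  xs <- tile_ranges(d[3], tile_shape[2])
  sp <- skeleton$spacing
  rows <- list()
  idx <- 0L
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    idx <- idx + 1L
    sub <- skeleton$voxels[, ys[[iy]], xs[[ix]], drop = FALSE]
    lm <- label_mask(array(sub, dim(sub)), sp)
    len <- measure_length(build_skeleton_graph(lm))$total_length_um
    vol <- sum(lobe_mask$voxels[, ys[[iy]], xs[[ix]]] > 0) * prod(sp)
    rows[[idx]] <- data.frame(
      tile_index = idx, tile_z = 1L, tile_y = ys[[iy]][1],
      tile_x = xs[[ix]][1], length_um = len, volume_um3 = vol,
      tile_voxels = d[1] * length(ys[[iy]]) * length(xs[[ix]]))
  }
  do.call(rbind, rows)
}

#' Tiled density map (heatmap grid)
#'
#' Combines per-tile lengths and volumes into a grid of densities. Tiles
#' whose lobe volume is below `volume_floor` (default 1% of the tile's
#' physical extent) are reported `NaN` -- "outside the lobe" -- rather than
#' 0, to distinguish absent tissue from tissue without network.
#'
#' @param length_by_tile per-tile lengths in um (tile raster order: x
#'   fastest, matching [tile_metrics()]).
#' @param volume_by_tile per-tile lobe volumes in um^3.
#' @param tiling `(n_tiles_y, n_tiles_x)` grid shape.
#' @param units density reporting units.
#' @param volume_floor volume threshold in um^3 below which a tile is
#'   `NaN`; default `0.01 * tile_extent_um3` when `tile_extent_um3` given,
#'   else 0.
#' @param tile_extent_um3 full physical extent of one tile in um^3 (used
#'   only for the default floor).
#' @return A `heatmap_grid`: `grid` (matrix `n_tiles_y x n_tiles_x`),
#'   `records` (data frame, one row per tile), `units`.
#' @export
tile_density_map <- function(length_by_tile, volume_by_tile, tiling,
                             units = "m/m3", volume_floor = NULL,
                             tile_extent_um3 = NULL) {
  if (length(length_by_tile) != length(volume_by_tile))
    stop("per-tile length and volume counts differ")
  if (length(length_by_tile) != prod(tiling))
    stop("tiling shape does not match the number of tiles")
  if (is.null(volume_floor))
    volume_floor <- if (!is.null(tile_extent_um3))
      0.01 * tile_extent_um3 else 0
  dens <- compute_density(length_by_tile, volume_by_tile, units)
  vals <- as.numeric(dens)
  below <- volume_by_tile < volume_floor | attr(dens, "flagged")
  vals[below] <- NaN
  grid <- matrix(vals, nrow = tiling[1], ncol = tiling[2], byrow = TRUE)
  records <- data.frame(tile_index = seq_along(vals),
                        length_um = length_by_tile,
                        volume_um3 = volume_by_tile,
                        density = vals, density_units = units)
  structure(list(grid = grid, records = records, units = units,
                 volume_floor = volume_floor),
            class = "heatmap_grid")
}

#' Maximum intensity projection along z
#'
#' @param voxels 3D array `(nz, ny, nx)`.
#' @return 2D matrix `(ny, nx)`.
#' @export
max_projection <- function(voxels) {
  apply(voxels, c(2, 3), max)
}

#' Quality-control montage: raw MIP | skeleton MIP | overlay
#'
#' Side-by-side panel of the maximum intensity projection of the raw data,
#' the skeleton projection, and an overlay with the skeleton in magenta
#' over the gray raw projection. Panels are separated by 2-pixel white
#' gutters.
#'
#' @param stack single-channel `calibrated_stack`.
#' @param skeleton skeleton `label_mask` aligned with the stack.
#' @param path optional PNG output path.
#' @return RGB array `(ny, 3*nx + 2*sep, 3)` in `[0, 1]`, invisibly if
#'   written to `path`.
#' @export
make_qc_montage <- function(stack, skeleton, path = NULL) {
  stopifnot(inherits(stack, "calibrated_stack"),
            inherits(skeleton, "label_mask"))
  check_aligned(skeleton, stack)
  sep <- 2L
  raw <- max_projection(stack$voxels) / (2^stack$bit_depth - 1)
  sk <- max_projection(skeleton$voxels)
  ny <- nrow(raw); nx <- ncol(raw)
  out <- array(1, c(ny, 3L * nx + 2L * sep, 3L))
  put <- function(x0, r, g, b) {
    out[, x0:(x0 + nx - 1L), 1] <<- r
    out[, x0:(x0 + nx - 1L), 2] <<- g
    out[, x0:(x0 + nx - 1L), 3] <<- b
  }
  put(1L, raw, raw, raw)
  put(nx + sep + 1L, sk, sk, sk)
  ov_r <- pmax(raw, sk); ov_g <- raw * (1 - sk); ov_b <- pmax(raw, sk)
  put(2L * (nx + sep) + 1L, ov_r, ov_g, ov_b)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Render a heatmap grid to a PNG image
#'
#' Cells are upscaled to blocks and mapped through a dark-blue-to-yellow
#' ramp over the stated value range; `NaN` tiles render gray.
#'
#' @param hm a `heatmap_grid`.
#' @param path optional PNG path.
#' @param cell_px pixels per tile cell.
#' @param zlim value range mapped to the ramp; defaults to the finite data
#'   range.
#' @return RGB array, invisibly if written.
#' @export
render_heatmap <- function(hm, path = NULL, cell_px = 16L, zlim = NULL) {
  stopifnot(inherits(hm, "heatmap_grid"))
  g <- hm$grid
  fin <- g[is.finite(g)]
  if (is.null(zlim))
    zlim <- if (length(fin)) range(fin) else c(0, 1)
  if (diff(zlim) == 0) zlim[2] <- zlim[1] + 1
  ramp <- colorRamp(c("#10104a", "#2166ac", "#1fa187", "#fde725"))
  norm <- pmin(pmax((g - zlim[1]) / diff(zlim), 0), 1)
  nr <- nrow(g); nc <- ncol(g)
  img <- array(0.5, c(nr, nc, 3))
  ok <- is.finite(norm)
  if (any(ok)) {
    cols <- ramp(norm[ok]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ok] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  big <- array(0, c(nr * cell_px, nc * cell_px, 3))
  for (ch in 1:3)
    big[, , ch] <- img[rep(seq_len(nr), each = cell_px),
                       rep(seq_len(nc), each = cell_px), ch]
  attr(big, "zlim") <- zlim
  if (!is.null(path)) {
    png::writePNG(big, path)
    return(invisible(big))
  }
  big
}
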