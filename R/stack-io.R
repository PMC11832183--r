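#' Calibrated 3D image stack
#'
#' Container for a 3D (optionally multi-channel) intensity grid with
#' physical voxel spacing. Voxels are stored as an array indexed
#' `[z, y, x]` (single channel) or `[channel, z, y, x]` (channel-first),
#' matching z-stack acquisition order.
#'
#' @param voxels numeric/integer array, 3D `(nz, ny, nx)` or 4D
#'   `(nc, nz, ny, nx)`.
#' @param spacing numeric length-3, physical voxel size `(dz, dy, dx)` in
#'   micrometres; all components must be positive.
#' @param channels optional character vector naming the channel axis; its
#'   length must match the first dimension of a 4D `voxels` array.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @param name identifier string carried through to results tables.
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(voxels, spacing, channels = NULL, bit_depth = 8,
                             name = "stack") {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in um")
  nd <- length(dim(voxels))
  if (is.null(dim(voxels)) || !(nd %in% c(3, 4)))
    stop("voxels must be a 3D (z, y, x) or 4D (channel, z, y, x) array")
  if (nd == 4) {
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(voxels)[1]))
    if (length(channels) != dim(voxels)[1])
      stop("channel names must match the channel axis length")
  } else if (!is.null(channels) && length(channels) != 1) {
    stop("a 3D stack can carry at most one channel name")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside the ", bit_depth, "-bit range")
  structure(
    list(voxels = voxels, spacing = setNames(spacing, c("dz", "dy", "dx")),
         channels = channels, bit_depth = as.integer(bit_depth),
         name = name, z_correction = 1),
    class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  geom <- if (length(d) == 4) {
    sprintf("%d channel(s) [%s], %d x %d x %d (z,y,x)",
            d[1], paste(x$channels, collapse = ", "), d[2], d[3], d[4])
  } else sprintf("%d x %d x %d (z,y,x)", d[1], d[2], d[3])
  cat(sprintf("<calibrated_stack '%s'> %s, spacing %.4g/%.4g/%.4g um, %d-bit\n",
              x$name, geom, x$spacing[1], x$spacing[2], x$spacing[3],
              x$bit_depth))
  invisible(x)
}

#' @rdname calibrated_stack
#' @param x a `calibrated_stack`.
#' @export
n_channels <- function(x) {
  if (length(dim(x$voxels)) == 4) dim(x$voxels)[1] else 1L
}

#' Extract one channel as a single-channel stack
#'
#' @param x a `calibrated_stack`.
#' @param channel channel name or index.
#' @return A single-channel `calibrated_stack`.
#' @export
get_channel <- function(x, channel) {
  if (length(dim(x$voxels)) == 3) {
    if (is.character(channel) && !is.null(x$channels) &&
        !identical(channel, x$channels))
      stop("unknown channel: ", channel)
    return(x)
  }
  i <- if (is.character(channel)) match(channel, x$channels) else channel
  if (is.na(i) || i < 1 || i > dim(x$voxels)[1])
    stop("unknown channel: ", channel)
  out <- calibrated_stack(array(x$voxels[i, , , ], dim(x$voxels)[-1]),
                          x$spacing, channels = x$channels[i],
                          bit_depth = x$bit_depth,
                          name = paste0(x$name, "_", x$channels[i]))
  out$z_correction <- x$z_correction
  out
}

#' Binary/label mask aligned to a stack
#'
#' @param voxels 3D integer array `(nz, ny, nx)`; 0 is background.
#' @param spacing physical voxel size `(dz, dy, dx)` in micrometres.
#' @param class_names named character vector mapping labels to names.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(voxels, spacing,
                       class_names = c("1" = "foreground")) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  if (length(dim(voxels)) != 3) stop("mask voxels must be a 3D array")
  if (any(voxels < 0)) stop("labels must be non-negative integers")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels,
                 spacing = setNames(spacing, c("dz", "dy", "dx")),
                 class_names = class_names),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_mask> %d x %d x %d (z,y,x), %d foreground voxel(s)\n",
              d[1], d[2], d[3], sum(x$voxels > 0)))
  invisible(x)
}

as_binary <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  mask$voxels > 0L
}

check_aligned <- function(mask, stack) {
  d <- dim(stack$voxels)
  if (length(d) == 4) d <- d[-1]
  if (!identical(dim(mask$voxels), d))
    stop("mask and stack shapes differ")
  invisible(TRUE)
}

#' Read a calibrated stack from a multi-page TIFF
#'
#' Pages are taken in file order as ascending z. Pages with a third array
#' dimension (samples per pixel > 1) are treated as channels, yielding a
#' channel-first 4D stack. Voxel spacing is always supplied by the caller:
#' TIFF resolution tags are not trusted (dialects vary); when tags are
#' present and disagree with `spacing`, a warning is issued and `spacing`
#' wins.
#'
#' @param path path to a multi-page TIFF (8- or 16-bit grayscale, optional
#'   channel axis).
#' @param spacing physical voxel size `(dz, dy, dx)` in micrometres.
#' @param channels optional channel names when the file is multi-channel.
#' @param name stack identifier; defaults to the file name without
#'   extension.
#' @return A `calibrated_stack`.
#' @export
read_stack <- function(path, spacing, channels = NULL,
                       name = tools::file_path_sans_ext(basename(path))) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in um")
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                    info = TRUE)),
    error = function(e) stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e)))
  if (length(pages) == 0) stop("TIFF '", path, "' holds no pages")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  xres <- attr(pages[[1]], "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    tag_dx <- 1e4 / xres  # TIFF resolution is per cm by default
    if (abs(tag_dx - spacing[3]) > 0.05 * spacing[3])
      warning("TIFF resolution tag implies dx ~ ", signif(tag_dx, 4),
              " um; using supplied spacing instead")
  }
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("cannot read TIFF '", path, "': page shapes differ (page 2+)")
  # multi-sample pages come back scaled to [0, 1] even under as.is
  if (is.double(pages[[1]]) && max(unlist(pages)) <= 1 &&
      any(unlist(pages) %% 1 != 0))
    pages <- lapply(pages, function(pg)
      array(as.integer(round(pg * (2^bits - 1))), dim(pg)))
  d1 <- dims[[1]]
  nz <- length(pages)
  if (length(d1) == 2) {
    vox <- array(0L, c(nz, d1[1], d1[2]))
    for (z in seq_len(nz)) vox[z, , ] <- pages[[z]]
  } else {
    nc <- d1[3]
    vox <- array(0L, c(nc, nz, d1[1], d1[2]))
    for (z in seq_len(nz))
      for (ch in seq_len(nc)) vox[ch, z, , ] <- pages[[z]][, , ch]
    if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  }
  calibrated_stack(vox, spacing, channels = channels,
                   bit_depth = as.integer(bits), name = name)
}

#' Write a calibrated stack to a multi-page TIFF
#'
#' Inverse of [read_stack()]: z slices become pages; a channel axis is
#' written as samples per pixel. Round-trips are voxel-exact for 8- and
#' 16-bit integer data.
#'
#' @param stack a `calibrated_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  maxval <- 2^stack$bit_depth - 1
  d <- dim(stack$voxels)
  pages <- if (length(d) == 3) {
    lapply(seq_len(d[1]), function(z) stack$voxels[z, , ] / maxval)
  } else {
    lapply(seq_len(d[2]), function(z) {
      pg <- array(0, c(d[3], d[4], d[1]))
      for (ch in seq_len(d[1])) pg[, , ch] <- stack$voxels[ch, z, , ] / maxval
      pg
    })
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path,
                                 bits.per.sample = stack$bit_depth),
                 error = function(e) stop("cannot write TIFF '", path, "': ",
                                          conditionMessage(e)))
  if (ok < length(pages)) stop("short write to '", path, "'")
  invisible(path)
}

#' Write / read a binary mask as an 8-bit TIFF (foreground = 255)
#'
#' @param mask a `label_mask`.
#' @param path file path.
#' @return `path` (write) or a `label_mask` (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  vox <- array(ifelse(mask$voxels > 0L, 255L, 0L), dim(mask$voxels))
  write_stack(calibrated_stack(vox, mask$spacing, bit_depth = 8), path)
}

#' @rdname write_mask
#' @param spacing voxel spacing of the mask being read.
#' @export
read_mask <- function(path, spacing) {
  st <- read_stack(path, spacing)
  label_mask(array(as.integer(st$voxels > 0), dim(st$voxels)), spacing)
}

#' Correct apparent z compression from refractive-index mismatch
#'
#' Imaging through media with mismatched refractive index compresses the
#' apparent z axis; the correction is a single positive scale factor applied
#' to the z spacing. Voxel data are untouched; the cumulative factor is
#' recorded in the stack metadata.
#'
#' @param stack a `calibrated_stack`.
#' @param factor positive scalar; corrected `dz' = dz * factor`.
#' @return The corrected `calibrated_stack`.
#' @export
apply_z_correction <- function(stack, factor) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("z-correction factor must be a positive scalar")
  stack$spacing[1] <- stack$spacing[1] * factor
  stack$z_correction <- stack$z_correction * factor
  stack
}

results_columns <- c("sample", "tile_index", "tile_z", "tile_y", "tile_x",
                     "neuron_length_um", "vessel_length_um",
                     "lobe_volume_um3", "neuron_density", "vessel_density",
                     "density_units")

#' Write per-tile density records to CSV
#'
#' Columns follow a fixed schema (sample, tile index and origin, per-channel
#' lengths in um, lobe volume in um^3, per-channel densities, density
#' units); single-channel runs omit the vessel columns. Rows are sorted by
#' `(sample, tile_index)` so repeated runs are byte-identical.
#'
#' @param records data frame of density records (see [tile_density_map()]
#'   and [run_pipeline()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  cols <- results_columns[results_columns %in% names(records)]
  extra <- setdiff(names(records), results_columns)
  if (length(extra)) stop("unknown record columns: ",
                          paste(extra, collapse = ", "))
  need <- c("sample", "tile_index", "lobe_volume_um3", "density_units")
  if (nrow(records) > 0 && !all(need %in% cols))
    stop("records lack required columns: ",
         paste(setdiff(need, cols), collapse = ", "))
  if (nrow(records) == 0 && length(cols) == 0) {
    records <- as.data.frame(
      setNames(rep(list(logical(0)), length(results_columns)),
               results_columns))
    cols <- results_columns
  }
  out <- records[cols]
  if (nrow(out) > 1)
    out <- out[order(out$sample, out$tile_index), , drop = FALSE]
  ok <- tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE,
                           na = "NA"),
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything [run_pipeline()] needs: directories, per-channel
#' classifier files, voxel spacing, optional particle exclusion, the
#' refractive-index z correction, tiling for density heatmaps, and the run
#' seed.
#'
#' @param input_dir directory of input TIFF stacks.
#' @param output_dir directory for all outputs (created if absent).
#' @param classifier_paths named character vector of classifier archive
#'   paths, one per active channel (e.g. `c(neuron = "...", vessel =
#'   "...")`).
#' @param spacing voxel size `(dz, dy, dx)` in micrometres.
#' @param mode `"single_channel"` or `"two_channel"`.
#' @param channel_names channel names, in the order channels appear in the
#'   input files.
#' @param particle_exclusion list: `enabled`, `max_size` (px^2),
#'   `circularity` = `c(lo, hi)` within `[0, 1]`, `connectivity` (4 or 8).
#' @param acceleration logical; chunked classifier application. A pure
#'   throughput knob: results are numerically identical either way.
#' @param z_correction_factor positive scalar applied to dz before
#'   processing (1 = no correction).
#' @param tile_shape optional `(ny, nx)` tile size in voxels for tiled
#'   density maps; `NULL` quantifies each stack as a single tile.
#' @param lobe_closing_um closing radius (um) for lobe-volume estimation.
#' @param density_units `"m/m3"`, `"um/um3"` or `"mm/mm3"`.
#' @param seed integer seed controlling all stochastic stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir, classifier_paths,
                       spacing, mode = c("two_channel", "single_channel"),
                       channel_names = NULL,
                       particle_exclusion = list(enabled = FALSE),
                       acceleration = FALSE, z_correction_factor = 1,
                       tile_shape = NULL, lobe_closing_um = 50,
                       density_units = "m/m3", seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(channel_names))
    channel_names <- if (mode == "two_channel") c("neuron", "vessel")
                     else "neuron"
  pe <- utils::modifyList(
    list(enabled = FALSE, max_size = 50, circularity = c(0.5, 1),
         connectivity = 8L),
    particle_exclusion)
  if (pe$max_size < 0) stop("particle max_size must be >= 0")
  circ <- pe$circularity
  if (length(circ) != 2 || circ[1] < 0 || circ[2] > 1 || circ[1] > circ[2])
    stop("circularity range must satisfy 0 <= lo <= hi <= 1")
  if (z_correction_factor <= 0) stop("z_correction_factor must be positive")
  if (!is.null(tile_shape) &&
      (length(tile_shape) != 2 || any(tile_shape < 1)))
    stop("tile_shape must be (ny, nx) positive voxel counts")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  n_ch <- if (mode == "two_channel") 2L else 1L
  if (length(channel_names) != n_ch)
    stop("need ", n_ch, " channel name(s) for mode ", mode)
  if (length(classifier_paths) != n_ch)
    stop("need ", n_ch, " classifier path(s) for mode ", mode)
  if (is.null(names(classifier_paths)))
    names(classifier_paths) <- channel_names
  structure(list(
    input_dir = input_dir, output_dir = output_dir,
    classifier_paths = classifier_paths, spacing = spacing, mode = mode,
    channel_names = channel_names, particle_exclusion = pe,
    acceleration = isTRUE(acceleration),
    z_correction_factor = z_correction_factor, tile_shape = tile_shape,
    lobe_closing_um = lobe_closing_um, density_units = density_units,
    seed = as.integer(seed)), class = "run_config")
}

#' Write / read a run configuration as a flat key = value file
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  kv <- c(
    input_dir = config$input_dir, output_dir = config$output_dir,
    mode = config$mode,
    channel_names = paste(config$channel_names, collapse = ","),
    classifier_paths = paste(config$classifier_paths, collapse = ","),
    spacing = paste(config$spacing, collapse = ","),
    particle_exclusion = tolower(config$particle_exclusion$enabled),
    particle_max_size = config$particle_exclusion$max_size,
    particle_circularity =
      paste(config$particle_exclusion$circularity, collapse = ","),
    particle_connectivity = config$particle_exclusion$connectivity,
    acceleration = tolower(config$acceleration),
    z_correction_factor = config$z_correction_factor,
    tile_shape = if (is.null(config$tile_shape)) ""
                 else paste(config$tile_shape, collapse = ","),
    lobe_closing_um = config$lobe_closing_um,
    density_units = config$density_units,
    seed = config$seed)
  writeLines(paste0(names(kv), " = ", kv), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  g <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)]
                                   else default
  nums <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  tile <- g("tile_shape", "")
  run_config(
    input_dir = g("input_dir"), output_dir = g("output_dir"),
    classifier_paths = strsplit(g("classifier_paths"), ",")[[1]],
    spacing = nums(g("spacing")),
    mode = g("mode", "two_channel"),
    channel_names = strsplit(g("channel_names", "neuron,vessel"), ",")[[1]],
    particle_exclusion = list(
      enabled = identical(g("particle_exclusion", "false"), "true"),
      max_size = as.numeric(g("particle_max_size", "50")),
      circularity = nums(g("particle_circularity", "0.5,1")),
      connectivity = as.integer(g("particle_connectivity", "8"))),
    acceleration = identical(g("acceleration", "false"), "true"),
    z_correction_factor = as.numeric(g("z_correction_factor", "1")),
    tile_shape = if (nzchar(tile)) as.integer(nums(tile)) else NULL,
    lobe_closing_um = as.numeric(g("lobe_closing_um", "50")),
    density_units = g("density_units", "m/m3"),
    seed = as.integer(g("seed", "1")))
}
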