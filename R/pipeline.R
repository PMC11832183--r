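#' Run the end-to-end quantification pipeline
#'
#' For every TIFF stack in `config$input_dir`: optional z correction, per
#' channel random-forest segmentation (classifiers are loaded up front and
#' missing ones fail fast), optional particle exclusion, 3D
#' skeletonization, length measurement, lobe-volume estimation from the
#' combined channel masks, and density per tile. Outputs land in
#' `config$output_dir`:
#' `segmented_<channel>/`, `skeletons_<channel>/`, `montages/`,
#' `heatmaps/` (when tiling is configured), `results.csv` and
#' `manifest.json`. Per-stack failures are recorded in the manifest and do
#' not abort the run. The whole run is deterministic given inputs, config
#' and seed, with or without the acceleration toggle.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with `manifest` (per-stack status/timing) and
#'   `results` (the density records data frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- sort(list.files(config$input_dir,
                           pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no TIFF stacks in ", config$input_dir)
  for (p in config$classifier_paths)
    if (!file.exists(p)) stop("missing classifier archive: ", p)
  classifiers <- lapply(config$classifier_paths, load_classifier)
  names(classifiers) <- config$channel_names

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (ch in config$channel_names) {
    dir.create(file.path(out, paste0("segmented_", ch)),
               showWarnings = FALSE)
    dir.create(file.path(out, paste0("skeletons_", ch)),
               showWarnings = FALSE)
  }
  dir.create(file.path(out, "montages"), showWarnings = FALSE)
  if (!is.null(config$tile_shape))
    dir.create(file.path(out, "heatmaps"), showWarnings = FALSE)

  pf <- particle_filter_spec(
    enabled = config$particle_exclusion$enabled,
    max_size = config$particle_exclusion$max_size,
    circularity = config$particle_exclusion$circularity,
    connectivity = config$particle_exclusion$connectivity)

  status <- character(length(files))
  timing <- numeric(length(files))
  errors <- character(length(files))
  records <- list()

  for (fi in seq_along(files)) {
    f <- files[fi]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      stack <- read_stack(f, config$spacing,
                          channels = if (config$mode == "two_channel")
                            config$channel_names else NULL)
      if (config$z_correction_factor != 1)
        stack <- apply_z_correction(stack, config$z_correction_factor)
      if (config$mode == "two_channel" && n_channels(stack) < 2)
        stop("two_channel mode but '", basename(f),
             "' has a single channel")
      ch_masks <- list()
      ch_skels <- list()
      for (ch in config$channel_names) {
        chan <- if (config$mode == "two_channel") get_channel(stack, ch)
                else stack
        mask <- apply_classifier(chan, classifiers[[ch]],
                                 acceleration = config$acceleration)
        mask <- exclude_particles(mask, pf)
        write_mask(mask, file.path(out, paste0("segmented_", ch),
                                   paste0(stack$name, ".tif")))
        skel <- skeletonize_3d(mask)
        write_mask(skel, file.path(out, paste0("skeletons_", ch),
                                   paste0(stack$name, ".tif")))
        make_qc_montage(chan, skel,
                        path = file.path(out, "montages",
                                         paste0(stack$name, "_", ch,
                                                ".png")))
        ch_masks[[ch]] <- mask
        ch_skels[[ch]] <- skel
      }
      lobe <- estimate_lobe_volume(ch_masks,
                                   closing_radius_um =
                                     config$lobe_closing_um)
      sp <- if (config$mode == "two_channel")
              get_channel(stack, 1)$spacing else stack$spacing
      d <- dim(ch_masks[[1]]$voxels)
      tile_shape <- if (is.null(config$tile_shape)) c(d[2], d[3])
                    else config$tile_shape
      per_ch <- lapply(ch_skels, function(sk)
        tile_metrics(sk, lobe$lobe_mask, tile_shape))
      base <- per_ch[[1]]
      rec <- data.frame(sample = stack$name,
                        tile_index = base$tile_index,
                        tile_z = base$tile_z, tile_y = base$tile_y,
                        tile_x = base$tile_x)
      nm <- config$channel_names
      rec[[paste0(nm[1], "_length_um")]] <- per_ch[[1]]$length_um
      if (length(nm) > 1)
        rec[[paste0(nm[2], "_length_um")]] <- per_ch[[2]]$length_um
      rec$lobe_volume_um3 <- base$volume_um3
      floor_vol <- 0.01 * base$tile_voxels * prod(sp)
      for (k in seq_along(nm)) {
        dens <- compute_density(per_ch[[k]]$length_um, base$volume_um3,
                                config$density_units)
        vals <- as.numeric(dens)
        vals[base$volume_um3 < floor_vol | attr(dens, "flagged")] <- NaN
        rec[[paste0(nm[k], "_density")]] <- vals
      }
      rec$density_units <- config$density_units
      if (!is.null(config$tile_shape)) {
        tiling <- c(length(tile_ranges(d[2], tile_shape[1])),
                    length(tile_ranges(d[3], tile_shape[2])))
        for (k in seq_along(nm)) {
          hm <- tile_density_map(per_ch[[k]]$length_um, base$volume_um3,
                                 tiling, units = config$density_units,
                                 tile_extent_um3 =
                                   base$tile_voxels[1] * prod(sp))
          render_heatmap(hm, path = file.path(
            out, "heatmaps", paste0(stack$name, "_", nm[k], ".png")))
          write.csv(cbind(sample = stack$name, hm$records),
                    file.path(out, "heatmaps",
                              paste0(stack$name, "_", nm[k], ".csv")),
                    row.names = FALSE)
        }
      }
      list(status = if (any(base$volume_um3 <= 0)) "flagged" else "ok",
           rec = rec)
    }, error = function(e) list(status = "failed",
                                error = conditionMessage(e), rec = NULL))
    timing[fi] <- proc.time()[["elapsed"]] - t0
    status[fi] <- res$status
    errors[fi] <- if (res$status == "failed") res$error else ""
    if (!is.null(res$rec)) records[[length(records) + 1]] <- res$rec
  }

  results <- if (length(records)) do.call(rbind, records) else
    data.frame()
  write_results_csv(results, file.path(out, "results.csv"))
  manifest <- list(
    tool_version = as.character(packageVersion("netdens")),
    seed = config$seed,
    config = unclass(config),
    stacks = data.frame(file = basename(files), status = status,
                        seconds = round(timing, 3), error = errors))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, results = results))
}

#' Train a classifier from files and write the archive
#'
#' Reads a training stack and a sparse annotation CSV (columns `z, y, x,
#' label`), trains the random-forest classifier and writes the archive.
#' Nothing is written when training fails (no partial archives).
#'
#' @param stack_path training stack TIFF.
#' @param labels_path annotation CSV.
#' @param out_path classifier archive destination.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param bank a `feature_bank`.
#' @param n_trees,seed forest parameters.
#' @param channel channel name/index to train on for multi-channel
#'   stacks.
#' @return The trained `pixel_classifier`, invisibly.
#' @export
train_classifier_file <- function(stack_path, labels_path, out_path,
                                  spacing, bank = feature_bank(),
                                  n_trees = 100L, seed = 1L,
                                  channel = NULL) {
  if (!file.exists(stack_path)) stop("stack not found: ", stack_path)
  annotation <- read_annotation_csv(labels_path)
  stack <- read_stack(stack_path, spacing)
  if (!is.null(channel)) stack <- get_channel(stack, channel)
  clf <- train_classifier(stack, annotation, bank = bank,
                          n_trees = n_trees, seed = seed)
  message(sprintf(
    "trained on %d labels (%s); training accuracy %.3f",
    length(annotation$labels),
    paste(names(clf$label_counts), clf$label_counts, sep = "=",
          collapse = ", "),
    clf$training_accuracy))
  save_classifier(clf, out_path)
  invisible(clf)
}
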