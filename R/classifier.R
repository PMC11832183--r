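#' Sparse voxel annotation for classifier training
#'
#' @param coordinates integer matrix with columns `(z, y, x)`, one row per
#'   annotated voxel (1-based indices).
#' @param labels character/factor vector parallel to `coordinates`, values
#'   `"foreground"` or `"background"`; both classes must be present.
#' @return A `training_annotation` object.
#' @export
training_annotation <- function(coordinates, labels) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must have columns (z, y, x)")
  storage.mode(coordinates) <- "integer"
  labels <- as.character(labels)
  if (length(labels) != nrow(coordinates))
    stop("labels must parallel coordinates")
  bad <- setdiff(unique(labels), c("foreground", "background"))
  if (length(bad)) stop("labels must be foreground/background, got: ",
                        paste(bad, collapse = ", "))
  structure(list(coordinates = coordinates, labels = labels),
            class = "training_annotation")
}

#' Read a training annotation from CSV (columns z, y, x, label)
#'
#' @param path CSV file path.
#' @return A `training_annotation`.
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("z", "y", "x", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV needs columns z, y, x, label")
  training_annotation(as.matrix(df[c("z", "y", "x")]), df$label)
}

check_annotation <- function(annotation, stack) {
  d <- dim(stack$voxels)
  if (length(d) == 4) d <- d[-1]
  co <- annotation$coordinates
  if (any(co < 1) || any(co[, 1] > d[1]) || any(co[, 2] > d[2]) ||
      any(co[, 3] > d[3]))
    stop("annotation coordinates outside stack bounds")
  if (length(unique(annotation$labels)) < 2)
    stop("both classes required in the training annotation")
  invisible(TRUE)
}

coord_to_row <- function(coordinates, d) {
  # column-major voxel order: z fastest, matching compute_features rows
  (coordinates[, 1] - 1L) + d[1] * ((coordinates[, 2] - 1L) +
                                    d[2] * (coordinates[, 3] - 1L)) + 1L
}

#' Train a random-forest pixel classifier
#'
#' Fits a probability random forest on the filter-bank features of the
#' annotated voxels. Fully deterministic for fixed inputs and seed (single
#' thread).
#'
#' @param stack single-channel `calibrated_stack` the annotation refers to.
#' @param annotation a `training_annotation` with both classes present.
#' @param bank a `feature_bank`; stored in the classifier and re-used at
#'   application time.
#' @param n_trees number of trees (default 100).
#' @param seed integer RNG seed for the forest.
#' @param features optional precomputed feature matrix for `stack`
#'   (avoids recomputation when the caller already has it).
#' @return A `pixel_classifier` with the trained model, the bank, the
#'   training-set accuracy, and per-class label counts.
#' @export
train_classifier <- function(stack, annotation, bank = feature_bank(),
                             n_trees = 100L, seed = 1L, features = NULL) {
  stopifnot(inherits(annotation, "training_annotation"))
  check_annotation(annotation, stack)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (is.null(features)) features <- compute_features(stack, bank)
  rows <- coord_to_row(annotation$coordinates, dim(stack$voxels))
  x <- features[rows, , drop = FALSE]
  y <- factor(annotation$labels, levels = c("background", "foreground"))
  df <- data.frame(x, check.names = FALSE)
  df$.class <- y
  model <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = as.integer(n_trees),
                          probability = TRUE, seed = as.integer(seed),
                          num.threads = 1L)
  prob <- predict(model, data = df, num.threads = 1L,
                  verbose = FALSE)$predictions
  pred <- ifelse(prob[, "foreground"] >= 0.5, "foreground", "background")
  acc <- mean(pred == annotation$labels)
  structure(list(model = model, bank = bank, n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 class_names = c("background", "foreground"),
                 feature_names = colnames(features),
                 training_accuracy = acc,
                 label_counts = table(annotation$labels),
                 training_spacing = stack$spacing,
                 format_version = 1L),
            class = "pixel_classifier")
}

#' Train one classifier on annotations pooled from several stacks
#'
#' Mirrors the common design of training on a small set of dedicated
#' training stacks: features are computed per stack and the annotated
#' rows are pooled into a single forest.
#'
#' @param stacks list of single-channel `calibrated_stack` objects.
#' @param annotations list of `training_annotation`s, parallel to
#'   `stacks`.
#' @inheritParams train_classifier
#' @return A `pixel_classifier`.
#' @export
train_classifier_multi <- function(stacks, annotations,
                                   bank = feature_bank(), n_trees = 100L,
                                   seed = 1L) {
  if (length(stacks) != length(annotations) || !length(stacks))
    stop("need one annotation per stack")
  xs <- list()
  ys <- character(0)
  for (i in seq_along(stacks)) {
    check_annotation(annotations[[i]], stacks[[i]])
    feats <- compute_features(stacks[[i]], bank)
    rows <- coord_to_row(annotations[[i]]$coordinates,
                         dim(stacks[[i]]$voxels))
    xs[[i]] <- feats[rows, , drop = FALSE]
    ys <- c(ys, annotations[[i]]$labels)
  }
  x <- do.call(rbind, xs)
  df <- data.frame(x, check.names = FALSE)
  df$.class <- factor(ys, levels = c("background", "foreground"))
  model <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = as.integer(n_trees),
                          probability = TRUE, seed = as.integer(seed),
                          num.threads = 1L)
  prob <- predict(model, data = df, num.threads = 1L,
                  verbose = FALSE)$predictions
  acc <- mean(ifelse(prob[, "foreground"] >= 0.5, "foreground",
                     "background") == ys)
  structure(list(model = model, bank = bank, n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 class_names = c("background", "foreground"),
                 feature_names = colnames(x),
                 training_accuracy = acc, label_counts = table(ys),
                 training_spacing = stacks[[1]]$spacing,
                 format_version = 1L),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %d trees, %d features, training accuracy %.3f\n",
    x$n_trees, length(x$feature_names), x$training_accuracy))
  invisible(x)
}

#' Posterior foreground probability per voxel
#'
#' @param stack single-channel `calibrated_stack`.
#' @param clf a `pixel_classifier`.
#' @param features optional precomputed feature matrix.
#' @param chunk_voxels rows per prediction chunk (chunking changes nothing
#'   numerically; it bounds memory).
#' @return Numeric vector of foreground posteriors, voxel order z fastest.
#' @export
predict_proba <- function(stack, clf, features = NULL,
                          chunk_voxels = Inf) {
  stopifnot(inherits(clf, "pixel_classifier"))
  if (!is.null(clf$training_spacing)) {
    ratio <- stack$spacing / clf$training_spacing
    if (any(ratio > 10 | ratio < 0.1))
      warning("stack spacing differs from training spacing by >10x; ",
              "proceeding anyway")
  }
  if (is.null(features)) features <- compute_features(stack, clf$bank)
  if (!identical(colnames(features), clf$feature_names))
    stop("feature bank of the classifier does not match the computed bank")
  n <- nrow(features)
  starts <- seq(1L, n, by = if (is.finite(chunk_voxels))
                              as.integer(chunk_voxels) else n)
  out <- numeric(n)
  for (s in starts) {
    e <- min(s + (if (is.finite(chunk_voxels)) chunk_voxels else n) - 1L, n)
    out[s:e] <- predict(clf$model,
                        data = data.frame(features[s:e, , drop = FALSE],
                                          check.names = FALSE),
                        num.threads = 1L,
                        verbose = FALSE)$predictions[, "foreground"]
  }
  out
}

#' Apply a trained classifier to a stack
#'
#' Thresholds the foreground posterior at 0.5 (ties count as foreground,
#' favoring recall of thin structures). Chunked ("accelerated") and
#' whole-stack application produce identical masks.
#'
#' @inheritParams predict_proba
#' @param acceleration logical; apply in chunks.
#' @return A binary `label_mask` (foreground = 1).
#' @export
apply_classifier <- function(stack, clf, features = NULL,
                             acceleration = FALSE) {
  p <- predict_proba(stack, clf, features = features,
                     chunk_voxels = if (acceleration) 65536 else Inf)
  d <- dim(stack$voxels)
  label_mask(array(as.integer(p >= 0.5), d), stack$spacing)
}

#' Save / load a classifier archive
#'
#' The archive is self-describing: it carries the bank specification, the
#' seed, class names and the model state. Loading validates the format and
#' restores predictions bit-identically.
#'
#' @param clf a `pixel_classifier`.
#' @param path archive path.
#' @return `path` (save) or the `pixel_classifier` (load).
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("classifier archive not found: ", path)
  clf <- readRDS(path)
  if (!inherits(clf, "pixel_classifier") ||
      is.null(clf$format_version) || is.null(clf$bank))
    stop("'", path, "' is not a classifier archive")
  clf
}

#' Voxels above a fixed intensity threshold
#'
#' The simple comparator to trainable segmentation: counts voxels with
#' intensity strictly greater than `threshold` and reports the physical
#' in-plane area (count x dy*dx) and volume (count x dz*dy*dx).
#'
#' @param stack single-channel `calibrated_stack`.
#' @param threshold gray value within the stack's bit-depth range;
#'   comparison is strict (`> threshold`).
#' @return List with `count`, `area_um2`, `volume_um3`.
#' @export
fixed_threshold_area <- function(stack, threshold) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (threshold < 0 || threshold > 2^stack$bit_depth - 1)
    stop("threshold outside the ", stack$bit_depth, "-bit range")
  count <- sum(stack$voxels > threshold)
  sp <- stack$spacing
  list(count = count,
       area_um2 = count * sp[["dy"]] * sp[["dx"]],
       volume_um3 = count * sp[["dz"]] * sp[["dy"]] * sp[["dx"]])
}
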