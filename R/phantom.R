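#' Specification of a synthetic tubular-network phantom
#'
#' Phantoms emulate stacks of bright curvilinear tube networks (neurites,
#' vessels) over a diffuse background: persistent random-walk centerlines
#' with exact known length, rasterized at a physical tube radius on an
#' anisotropic grid, blurred by a Gaussian PSF and corrupted with Gaussian
#' noise. Defaults are a scaled-down cleared-tissue field: 40 x 160 x 160
#' voxels at (1.5, 1, 1) um spacing, 6 tubes of 160 um each -- a dilute
#' fiber regime (about 1% volume fill) comparable to sparse innervation.
#'
#' @param shape grid `(nz, ny, nx)` in voxels; every axis must be >= 3.
#' @param spacing voxel size `(dz, dy, dx)` in um.
#' @param n_tubes number of tubes.
#' @param n_steps steps per tube; each step has exactly `step_um` length.
#' @param step_um polyline step length in um.
#' @param persistence direction correlation in `[0, 1)`; 0 = isotropic
#'   random walk, values near 1 = nearly straight tubes.
#' @param radius_um tube radius in um.
#' @param avoid_self logical; re-draw steps that would bring the walk
#'   within `2 * radius_um + 3 * max(spacing)` of its own earlier path or
#'   of other tubes (biological fibers do not self-overlap, and
#'   self-merging masks have no curve skeleton).
#' @param envelope `NULL`, or `list(semiaxes = c(az, ay, ax))` in um for
#'   an ellipsoidal lobe envelope centered in the grid; walks are confined
#'   to it.
#' @param intensity named vector `c(tube, background, noise_sd)` in gray
#'   values.
#' @param psf_sigma_um isotropic Gaussian blur scale in um (0 = none).
#' @param bit_depth 8 or 16.
#' @param seed integer; drives all stochastic stages reproducibly.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 160, 160), spacing = c(1.5, 1, 1),
                         n_tubes = 6, n_steps = 40, step_um = 4,
                         persistence = 0.92, radius_um = 2.5,
                         avoid_self = TRUE, envelope = NULL,
                         intensity = c(tube = 200, background = 30,
                                       noise_sd = 10),
                         psf_sigma_um = 0.8, bit_depth = 8, seed = 1L) {
  if (any(shape < 3)) stop("degenerate grid: every axis needs >= 3 voxels")
  if (any(spacing <= 0) || step_um <= 0 || radius_um <= 0 || n_tubes < 1 ||
      n_steps < 1)
    stop("all physical phantom parameters must be positive")
  if (persistence < 0 || persistence >= 1)
    stop("persistence must lie in [0, 1)")
  if (!is.null(envelope)) {
    if (is.null(envelope$semiaxes) || length(envelope$semiaxes) != 3 ||
        any(envelope$semiaxes <= 0))
      stop("envelope needs positive semiaxes (az, ay, ax) in um")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_tubes = as.integer(n_tubes),
                 n_steps = as.integer(n_steps), step_um = step_um,
                 persistence = persistence, radius_um = radius_um,
                 avoid_self = isTRUE(avoid_self),
                 envelope = envelope, intensity = intensity,
                 psf_sigma_um = psf_sigma_um,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

rand_unit <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-12) return(u / n)
  }
}

inside_domain <- function(p, ext, env_center, env_semiaxes) {
  if (any(p < 0) || any(p > ext)) return(FALSE)
  if (!is.null(env_semiaxes))
    return(sum(((p - env_center) / env_semiaxes)^2) <= 1)
  TRUE
}

#' Grow persistent-random-walk tube centerlines
#'
#' Each tube is an ordered polyline in physical um coordinates `(z, y,
#' x)`. The walk direction at each step is the normalized blend
#' `persistence * previous + (1 - persistence) * random unit vector`;
#' every segment has exactly `step_um` length, so the ground-truth length
#' `n_tubes * n_steps * step_um` is exact geometry, independent of any
#' rasterization. Walks reflect at the grid (and envelope) boundary.
#'
#' @param spec a `phantom_spec`.
#' @return A `phantom_truth`: `polylines` (list of matrices, um),
#'   `total_length_um`, `envelope_volume_um3` (analytic, `NA` without an
#'   envelope), and the originating `spec`.
#' @export
grow_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$shape < 3)) stop("degenerate grid")
  set.seed(spec$seed)
  ext <- spec$shape * spec$spacing
  env_semi <- if (!is.null(spec$envelope)) spec$envelope$semiaxes else NULL
  env_center <- ext / 2
  polylines <- vector("list", spec$n_tubes)
  prev_pts <- matrix(numeric(0), 0, 3)  # points of earlier tubes
  # tubes must be separated by more than their diameter plus a few voxels,
  # or rasterization bridges them intermittently into spurious junctions
  min_sep0 <- 2 * spec$radius_um + 3 * max(spec$spacing)
  for (t in seq_len(spec$n_tubes)) {
    # start point uniform inside the domain (rejection for the envelope,
    # and away from earlier tubes when avoidance is on)
    start_try <- 0
    repeat {
      start_try <- start_try + 1
      p <- runif(3) * ext
      if (!inside_domain(p, ext, env_center, env_semi)) next
      if (spec$avoid_self && nrow(prev_pts) > 0 && start_try <= 50) {
        d2 <- min(rowSums(sweep(prev_pts, 2, p)^2))
        if (d2 < min_sep0^2) next
      }
      break
    }
    dirv <- rand_unit()
    pts <- matrix(0, spec$n_steps + 1L, 3,
                  dimnames = list(NULL, c("z", "y", "x")))
    pts[1, ] <- p
    min_sep <- min_sep0
    lag <- as.integer(ceiling(min_sep / spec$step_um)) + 1L
    for (s in seq_len(spec$n_steps)) {
      best_dir <- NULL
      best_cand <- NULL
      best_clear <- -Inf
      for (attempt in 1:12) {
        # later attempts relax persistence so a cornered walk can
        # actually turn away instead of re-proposing the same direction
        pers <- spec$persistence * c(1, 1, 1, 0.6, 0.6, 0.6, 0.3, 0.3,
                                     0.3, 0, 0, 0)[attempt]
        dv <- pers * dirv + (1 - pers) * rand_unit()
        nn <- sqrt(sum(dv^2))
        dv <- if (nn < 1e-12) rand_unit() else dv / nn
        cand <- p + spec$step_um * dv
        tries <- 0
        while (!inside_domain(cand, ext, env_center, env_semi)) {
          tries <- tries + 1
          if (tries <= 3) {
            # grazing reflection: project the direction onto the wall
            # tangent plane with a small inward bias. Turns never exceed
            # ~90 degrees, so a reflected tube cannot fold back onto
            # itself (a mirror bounce at normal incidence would).
            if (any(cand < 0) || any(cand > ext)) {
              inward <- as.numeric(cand < 0) - as.numeric(cand > ext)
              dv[inward != 0] <- 0
              nin <- sqrt(sum(inward^2))
              if (sqrt(sum(dv^2)) < 1e-9) dv <- inward / nin
              else dv <- dv / sqrt(sum(dv^2)) + 0.3 * inward / nin
            } else {
              nrm <- (p - env_center) / env_semi^2
              nrm <- nrm / sqrt(sum(nrm^2))
              dv <- dv - sum(dv * nrm) * nrm
              if (sqrt(sum(dv^2)) < 1e-9) dv <- -nrm
              else dv <- dv / sqrt(sum(dv^2)) - 0.3 * nrm
            }
            dv <- dv / sqrt(sum(dv^2))
          } else {
            # corner fallback: aim at the domain center
            dv <- env_center - p
            dv <- dv / sqrt(sum(dv^2))
          }
          cand <- p + spec$step_um * dv
          if (tries > 10) {  # pathological; stay put direction-wise
            cand <- p
            break
          }
        }
        # clearance to this tube's own earlier path (excluding the last
        # few segments, which are legitimately within one step) and to
        # all earlier tubes
        clear <- Inf
        if (spec$avoid_self) {
          if (s > lag)
            clear <- min(rowSums(sweep(pts[seq_len(s - lag), ,
                                           drop = FALSE], 2, cand)^2))
          if (nrow(prev_pts) > 0)
            clear <- min(clear, min(rowSums(sweep(prev_pts, 2, cand)^2)))
          clear <- sqrt(clear)
        }
        if (clear > best_clear) {
          best_clear <- clear
          best_dir <- dv
          best_cand <- cand
        }
        if (best_clear >= min_sep) break
      }
      dirv <- best_dir
      p <- best_cand
      pts[s + 1L, ] <- p
    }
    polylines[[t]] <- pts
    prev_pts <- rbind(prev_pts, pts)
  }
  total <- sum(vapply(polylines, function(m) {
    sum(sqrt(rowSums(diff(m)^2)))
  }, 0))
  env_vol <- if (!is.null(env_semi)) 4 / 3 * pi * prod(env_semi)
             else NA_real_
  structure(list(polylines = polylines, total_length_um = total,
                 envelope_volume_um3 = env_vol, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d tube(s), total length %.1f um\n",
              length(x$polylines), x$total_length_um))
  invisible(x)
}

point_to_voxel <- function(pts, spacing, shape) {
  # voxel i (1-based) is centered at (i - 0.5) * spacing
  v <- sweep(pts, 2, spacing, "/") + 0.5
  v <- round(v)
  for (a in 1:3) v[, a] <- pmin(pmax(v[, a], 1), shape[a])
  storage.mode(v) <- "integer"
  v
}

#' Rasterize phantom centerlines into a mask and an intensity stack
#'
#' The binary tube mask holds every voxel whose center lies within
#' `radius_um` of a polyline (anisotropy-aware Euclidean distance,
#' computed from densely sampled centerline points). The intensity stack
#' is background plus tube intensity on the mask, Gaussian-blurred at
#' `psf_sigma_um`, plus Gaussian read noise, clipped and rounded to the
#' bit depth. The noise RNG derives deterministically from the spec seed.
#'
#' @param truth a `phantom_truth` from [grow_network()].
#' @param spec the `phantom_spec` (defaults to the one inside `truth`).
#' @return List with `stack` (a `calibrated_stack`) and `mask` (a
#'   `label_mask` of the true tubes).
#' @export
rasterize_phantom <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (spec$radius_um < max(spec$spacing) / 2)
    warning("tube radius below half the largest voxel dimension: ",
            "tubes may disconnect across slices")
  d <- spec$shape
  seeds <- array(FALSE, d)
  sub <- min(spec$spacing) / 2
  for (pl in truth$polylines) {
    for (s in seq_len(nrow(pl) - 1)) {
      a <- pl[s, ]; b <- pl[s + 1, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / sub) + 1L)
      tt <- seq(0, 1, length.out = n)
      pts <- outer(1 - tt, a) + outer(tt, b)
      vx <- point_to_voxel(pts, spec$spacing, d)
      seeds[vx] <- TRUE
    }
  }
  dist <- edt_um(seeds, spec$spacing)
  mask <- dist <= spec$radius_um
  maxval <- 2^spec$bit_depth - 1
  img <- array(spec$intensity[["background"]], d)
  img[mask] <- spec$intensity[["tube"]]
  if (spec$psf_sigma_um > 0)
    img <- gauss3(img, spec$psf_sigma_um / spec$spacing)
  if (spec$intensity[["noise_sd"]] > 0) {
    set.seed((spec$seed + 777L) %% .Machine$integer.max)
    img <- img + rnorm(length(img), sd = spec$intensity[["noise_sd"]])
  }
  img <- array(as.integer(round(pmin(pmax(img, 0), maxval))), d)
  list(stack = calibrated_stack(img, spec$spacing,
                                bit_depth = spec$bit_depth,
                                name = sprintf("phantom_seed%d",
                                               spec$seed)),
       mask = label_mask(array(as.integer(mask), d), spec$spacing,
                         c("1" = "tube")))
}

#' Sample a default training annotation from phantom truth
#'
#' Draws balanced foreground/background voxel labels from the true tube
#' mask (background at least one radius away from any tube), emulating
#' sparse manual scribbles.
#'
#' @param raster output of [rasterize_phantom()].
#' @param n_per_class labels per class.
#' @param seed RNG seed.
#' @return A `training_annotation`.
#' @export
phantom_annotation <- function(raster, n_per_class = 400, seed = 1L) {
  mask <- raster$mask$voxels > 0
  d <- dim(mask)
  dist <- edt_um(mask, raster$mask$spacing)
  fg <- which(mask)
  # background labels include the blurred rim just outside the tubes:
  # without them the classifier never learns the boundary and predicts
  # a dilated halo
  bg <- which(!mask & dist > max(raster$mask$spacing))
  set.seed(seed)
  fg_s <- sample(fg, min(n_per_class, length(fg)))
  bg_s <- sample(bg, min(n_per_class, length(bg)))
  to_zyx <- function(lin) {
    lin0 <- lin - 1L
    cbind(z = lin0 %% d[1] + 1L,
          y = (lin0 %/% d[1]) %% d[2] + 1L,
          x = lin0 %/% (d[1] * d[2]) + 1L)
  }
  training_annotation(rbind(to_zyx(fg_s), to_zyx(bg_s)),
                      c(rep("foreground", length(fg_s)),
                        rep("background", length(bg_s))))
}

#' Generate a reproducible validation set of phantom stacks
#'
#' Produces `n_stacks` phantoms with per-stack ground truth and a
#' designated train/validation split (the first `n_train` stacks train the
#' classifier, mirroring a 2-train / 8-validate design). Tube count and
#' radius vary deterministically across stacks so that true lengths span a
#' wide range; per-stack seeds derive from the single global seed.
#'
#' @param n_stacks total stacks (>= 2).
#' @param template a `phantom_spec` supplying all other parameters.
#' @param seed global integer seed.
#' @param n_train stacks reserved for training.
#' @return List with `stacks`, `masks`, `truths` (parallel lists) and
#'   `manifest` (data frame: stack, role, n_tubes, radius_um, seed,
#'   total_length_um, envelope_volume_um3).
#' @export
make_validation_set <- function(n_stacks = 10, template = phantom_spec(),
                                seed = 1L, n_train = 2) {
  if (n_stacks < 2) stop("need at least 2 stacks")
  n_tubes_cycle <- 2 + (seq_len(n_stacks) - 1) %% 8
  radius_cycle <- 2 + (seq_len(n_stacks) - 1) %% 5 * 0.5
  stacks <- masks <- truths <- vector("list", n_stacks)
  rows <- list()
  for (i in seq_len(n_stacks)) {
    sp <- template
    sp$seed <- as.integer((seed * 1009L + i * 9973L) %%
                          .Machine$integer.max)
    sp$n_tubes <- as.integer(n_tubes_cycle[i])
    sp$radius_um <- radius_cycle[i]
    tr <- grow_network(sp)
    ra <- rasterize_phantom(tr, sp)
    ra$stack$name <- sprintf("phantom_%02d", i)
    stacks[[i]] <- ra$stack
    masks[[i]] <- ra$mask
    truths[[i]] <- tr
    rows[[i]] <- data.frame(
      stack = ra$stack$name,
      role = if (i <= n_train) "train" else "validation",
      n_tubes = sp$n_tubes, radius_um = sp$radius_um, seed = sp$seed,
      total_length_um = tr$total_length_um,
      envelope_volume_um3 = tr$envelope_volume_um3)
  }
  list(stacks = stacks, masks = masks, truths = truths,
       manifest = do.call(rbind, rows))
}

#' Write a validation set to disk (TIFF stacks + truth manifest CSV)
#'
#' @param vs output of [make_validation_set()].
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_validation_set <- function(vs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(vs$stacks))
    write_stack(vs$stacks[[i]],
                file.path(dir, paste0(vs$manifest$stack[i], ".tif")))
  manifest_path <- file.path(dir, "truth_manifest.csv")
  write.csv(vs$manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
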