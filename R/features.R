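FEATURE_NAMES <- c("identity", "gaussian", "difference_of_gaussians",
                   "gradient_magnitude", "laplacian", "hessian_eigenvalues",
                   "local_min", "local_max", "local_mean")

#' Multiscale filter-bank specification for pixel classification
#'
#' Defines the per-voxel features the random-forest classifier is trained
#' on. Smoothing scales are physical (um) and converted to per-axis voxel
#' units, so one bank transfers between stacks with different calibration.
#'
#' @param sigmas strictly increasing positive smoothing scales in um;
#'   default `c(1, 2, 4, 8) * dx` is filled in from the stack at feature
#'   time when `NULL`.
#' @param features subset of `identity`, `gaussian`,
#'   `difference_of_gaussians`, `gradient_magnitude`, `laplacian`,
#'   `hessian_eigenvalues`, `local_min`, `local_max`, `local_mean`.
#' @param use_3d if `TRUE` filters act in 3D; if `FALSE` they act per z
#'   slice, for strongly anisotropic stacks (dz >> dx).
#' @return A `feature_bank` object.
#' @export
feature_bank <- function(sigmas = NULL,
                         features = c("gaussian", "difference_of_gaussians",
                                      "gradient_magnitude", "laplacian",
                                      "hessian_eigenvalues"),
                         use_3d = TRUE) {
  if (!is.null(sigmas)) {
    sigmas <- as.numeric(sigmas)
    if (any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE))
      stop("sigmas must be strictly positive and strictly increasing")
  }
  features <- unique(features)
  bad <- setdiff(features, FEATURE_NAMES)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  if (length(features) == 0) stop("feature set must be non-empty")
  structure(list(sigmas = sigmas, features = features,
                 use_3d = isTRUE(use_3d)),
            class = "feature_bank")
}

bank_sigmas <- function(bank, spacing) {
  if (!is.null(bank$sigmas)) bank$sigmas else c(1, 2, 4, 8) * spacing[3]
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %s | sigmas: %s um | %s\n",
              paste(x$features, collapse = ", "),
              if (is.null(x$sigmas)) "auto (1,2,4,8 x dx)"
              else paste(x$sigmas, collapse = ", "),
              if (x$use_3d) "3D" else "per-slice 2D"))
  invisible(x)
}

# clamped-index shift of a 3D array along an axis (replicate borders)
shift_arr <- function(v, axis, by) {
  n <- dim(v)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

deriv1 <- function(v, axis, h) (shift_arr(v, axis, 1L) -
                                shift_arr(v, axis, -1L)) / (2 * h)
deriv2 <- function(v, axis, h) (shift_arr(v, axis, 1L) - 2 * v +
                                shift_arr(v, axis, -1L)) / h^2

gauss3 <- function(v, sigma_vox) {
  d <- dim(v)
  array(cpp_gauss3d(as.numeric(v), d, sigma_vox), d)
}

box3 <- function(v, radius_vox, op) {
  d <- dim(v)
  array(cpp_box3d(as.numeric(v), d, as.integer(radius_vox), op), d)
}

# eigenvalues of a symmetric 3x3 matrix field, ascending, vectorized
# (trigonometric closed form)
eig_sym3 <- function(h11, h22, h33, h12, h13, h23) {
  p1 <- h12^2 + h13^2 + h23^2
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > .Machine$double.eps * (abs(q) + 1)
  pp <- ifelse(safe, p, 1)
  b11 <- (h11 - q) / pp; b22 <- (h22 - q) / pp; b33 <- (h33 - q) / pp
  b12 <- h12 / pp; b13 <- h13 / pp; b23 <- h23 / pp
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e3 <- q + 2 * p * cos(phi)
  e2 <- 3 * q - e1 - e3
  e1[!safe] <- q[!safe]; e2[!safe] <- q[!safe]; e3[!safe] <- q[!safe]
  list(e1, e2, e3)
}

#' Compute the per-voxel feature table of a stack
#'
#' Features are enumerated in a fixed order (feature, then ascending
#' sigma), so a classifier trained on one stack applies unchanged to
#' another. Derivative features are spacing-aware: derivatives are taken in
#' physical units per axis. In per-slice 2D mode the z axis is excluded
#' from smoothing and derivatives.
#'
#' @param stack a single-channel `calibrated_stack`.
#' @param bank a `feature_bank`.
#' @return Numeric matrix, one row per voxel (column-major voxel order:
#'   z fastest), named feature columns.
#' @export
compute_features <- function(stack, bank) {
  stopifnot(inherits(stack, "calibrated_stack"),
            inherits(bank, "feature_bank"))
  if (length(dim(stack$voxels)) != 3)
    stop("compute_features needs a single-channel stack")
  sp <- stack$spacing
  sigmas <- bank_sigmas(bank, sp)
  active <- if (bank$use_3d) 1:3 else 2:3
  for (s in sigmas)
    for (a in active)
      if (s < sp[a] / 2)
        stop(sprintf("sigma %g um is below half a voxel on axis %s (%g um)",
                     s, c("z", "y", "x")[a], sp[a]))
  v <- array(as.numeric(stack$voxels), dim(stack$voxels))
  nvox <- length(v)
  sig_vox <- function(s) {
    sv <- s / sp
    if (!bank$use_3d) sv[1] <- 0
    sv
  }
  smoothed <- lapply(sigmas, function(s) gauss3(v, sig_vox(s)))
  cols <- list()
  for (feat in FEATURE_NAMES) {
    if (!feat %in% bank$features) next
    if (feat == "identity") {
      cols[["identity"]] <- as.numeric(v)
    } else if (feat == "gaussian") {
      for (i in seq_along(sigmas))
        cols[[sprintf("gaussian_s%g", sigmas[i])]] <-
          as.numeric(smoothed[[i]])
    } else if (feat == "difference_of_gaussians") {
      if (length(sigmas) >= 2)
        for (i in seq_len(length(sigmas) - 1))
          cols[[sprintf("dog_s%g_s%g", sigmas[i], sigmas[i + 1])]] <-
            as.numeric(smoothed[[i + 1]] - smoothed[[i]])
    } else if (feat == "gradient_magnitude") {
      for (i in seq_along(sigmas)) {
        g2 <- 0
        for (a in active) g2 <- g2 + deriv1(smoothed[[i]], a, sp[a])^2
        cols[[sprintf("gradmag_s%g", sigmas[i])]] <- as.numeric(sqrt(g2))
      }
    } else if (feat == "laplacian") {
      for (i in seq_along(sigmas)) {
        lp <- 0
        for (a in active) lp <- lp + deriv2(smoothed[[i]], a, sp[a])
        cols[[sprintf("laplacian_s%g", sigmas[i])]] <- as.numeric(lp)
      }
    } else if (feat == "hessian_eigenvalues") {
      for (i in seq_along(sigmas)) {
        g <- smoothed[[i]]
        if (bank$use_3d) {
          h11 <- deriv2(g, 1, sp[1]); h22 <- deriv2(g, 2, sp[2])
          h33 <- deriv2(g, 3, sp[3])
          h12 <- deriv1(deriv1(g, 1, sp[1]), 2, sp[2])
          h13 <- deriv1(deriv1(g, 1, sp[1]), 3, sp[3])
          h23 <- deriv1(deriv1(g, 2, sp[2]), 3, sp[3])
        } else {
          zero <- array(0, dim(g))
          h11 <- zero; h12 <- zero; h13 <- zero
          h22 <- deriv2(g, 2, sp[2]); h33 <- deriv2(g, 3, sp[3])
          h23 <- deriv1(deriv1(g, 2, sp[2]), 3, sp[3])
        }
        ee <- eig_sym3(h11, h22, h33, h12, h13, h23)
        for (k in 1:3)
          cols[[sprintf("hessian_e%d_s%g", k, sigmas[i])]] <-
            as.numeric(ee[[k]])
      }
    } else {  # local_min / local_max / local_mean
      op <- match(feat, c("local_mean", "local_min", "local_max")) - 1L
      for (i in seq_along(sigmas)) {
        r <- pmax(as.integer(ceiling(sigmas[i] / sp)), 1L)
        if (!bank$use_3d) r[1] <- 0L
        cols[[sprintf("%s_s%g", feat, sigmas[i])]] <-
          as.numeric(box3(v, r, op))
      }
    }
  }
  out <- matrix(unlist(cols, use.names = FALSE), nrow = nvox,
                ncol = length(cols))
  colnames(out) <- names(cols)
  out
}
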