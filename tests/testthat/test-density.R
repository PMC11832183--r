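test_that("density unit algebra is exact and zero volume is flagged,
           not zero", {
  expect_equal(as.numeric(compute_density(1e6, 1e18, "m/m3")), 1)
  expect_equal(as.numeric(compute_density(1e3, 1e9, "mm/mm3")), 1)
  expect_equal(as.numeric(compute_density(5, 10, "um/um3")), 0.5)
  # zero numerator
  expect_equal(as.numeric(compute_density(0, 1e6, "m/m3")), 0)
  expect_false(attr(compute_density(0, 1e6, "m/m3"), "flagged"))
  # doubling volume halves density exactly
  d1 <- as.numeric(compute_density(123.4, 7e5, "m/m3"))
  d2 <- as.numeric(compute_density(123.4, 14e5, "m/m3"))
  expect_equal(d2, d1 / 2)
  # zero volume: flagged NA, distinct from zero
  f <- compute_density(10, 0, "m/m3")
  expect_true(is.na(as.numeric(f)))
  expect_true(attr(f, "flagged"))
  expect_error(compute_density(1, 1, "km/km3"), "units")
})

test_that("lobe volume: saturated mask, disjoint voxels with zero
           closing, and empty-union warning", {
  sp <- c(1.5, 1, 1)
  solid <- label_mask(array(1L, c(4, 5, 6)), sp)
  r <- estimate_lobe_volume(list(solid), closing_radius_um = 0)
  expect_equal(r$volume_um3, 4 * 5 * 6 * prod(sp))

  a <- array(0L, c(5, 5, 5)); a[2, 2, 2] <- 1L
  b <- array(0L, c(5, 5, 5)); b[4, 4, 4] <- 1L
  r <- estimate_lobe_volume(list(label_mask(a, sp), label_mask(b, sp)),
                            closing_radius_um = 0)
  expect_equal(r$volume_um3, 2 * prod(sp))
  # lobe mask contains the union
  expect_true(all(r$lobe_mask$voxels[a + b > 0] == 1L))

  empty <- label_mask(array(0L, c(4, 4, 4)), sp)
  expect_warning(r0 <- estimate_lobe_volume(list(empty)), "empty")
  expect_equal(r0$volume_um3, 0)
})

test_that("lobe volume of an ellipsoid-envelope phantom recovers the
           analytic volume and is monotone in closing radius", {
  sp <- phantom_spec(shape = c(40, 120, 120),
                     n_tubes = 18, n_steps = 40,
                     envelope = list(semiaxes = c(24, 48, 48)),
                     seed = 13)
  tr <- grow_network(sp)
  ra <- rasterize_phantom(tr, sp)
  vols <- vapply(c(4, 8, 12, 16), function(r)
    estimate_lobe_volume(list(ra$mask), closing_radius_um = r)$volume_um3,
    0)
  expect_true(all(diff(vols) >= 0))  # monotone non-decreasing
  est <- estimate_lobe_volume(list(ra$mask), closing_radius_um = 12)
  expect_lt(abs(est$volume_um3 - tr$envelope_volume_um3) /
            tr$envelope_volume_um3, 0.2)
})

test_that("degenerate single-tile map equals the whole-stack density and
           low-volume tiles are NaN, not zero", {
  skel <- array(0L, c(4, 8, 8)); skel[2, 4, 2:7] <- 1L
  lobe <- array(0L, c(4, 8, 8)); lobe[, , 1:4] <- 1L
  sp <- c(1, 1, 1)
  skm <- label_mask(skel, sp); lbm <- label_mask(lobe, sp)
  tm <- tile_metrics(skm, lbm, c(8, 8))
  expect_equal(nrow(tm), 1)
  hm <- tile_density_map(tm$length_um, tm$volume_um3, c(1, 1),
                         units = "um/um3")
  whole <- as.numeric(compute_density(
    measure_length(build_skeleton_graph(skm))$total_length_um,
    sum(lobe) * prod(sp), "um/um3"))
  expect_equal(hm$grid[1, 1], whole)

  # 2x2 tiling: lobe occupies the left half -> right tiles NaN
  tm2 <- tile_metrics(skm, lbm, c(4, 4))
  hm2 <- tile_density_map(tm2$length_um, tm2$volume_um3, c(2, 2),
                          units = "um/um3",
                          tile_extent_um3 = 4 * 4 * 4 * prod(sp))
  expect_true(all(is.nan(hm2$grid[, 2])))
  expect_true(all(is.finite(hm2$grid[, 1])))
  # grid values re-derivable from the records table alone
  rec <- hm2$records
  re <- matrix(rec$density, 2, 2, byrow = TRUE)
  expect_identical(re, unname(hm2$grid))
})

test_that("tiles that cut no skeleton edge partition the length; cut
           edges lose at most max-edge-length each", {
  sp0 <- small_phantom_spec(seed = 17)
  ra <- rasterize_phantom(grow_network(sp0), sp0)
  sk <- skeletonize_3d(ra$mask)
  lobe <- label_mask(array(1L, dim(sk$voxels)), sk$spacing)
  whole <- measure_length(build_skeleton_graph(sk))$total_length_um
  tm <- tile_metrics(sk, lobe, c(24, 24))
  max_edge <- sqrt(sum((c(1, 1, 1) * sk$spacing)^2))
  n_cut <- nrow(build_skeleton_graph(sk)$edges) -
    sum(vapply(seq_len(nrow(tm)), function(i) {
      ys <- tm$tile_y[i]:min(tm$tile_y[i] + 23, dim(sk$voxels)[2])
      xs <- tm$tile_x[i]:min(tm$tile_x[i] + 23, dim(sk$voxels)[3])
      sub <- sk$voxels[, ys, xs, drop = FALSE]
      nrow(build_skeleton_graph(
        label_mask(array(sub, dim(sub)), sk$spacing))$edges)
    }, 0L))
  expect_lte(sum(tm$length_um), whole)
  expect_lte(whole - sum(tm$length_um), n_cut * max_edge + 1e-9)
  # per-tile volumes always partition the lobe volume exactly
  expect_equal(sum(tm$volume_um3),
               sum(lobe$voxels) * prod(sk$spacing))
})

test_that("tiling a phantom with tubes in one region leaves other tiles
           at zero", {
  v <- array(0L, c(6, 40, 40))
  v[3, 5:15, 5:15] <- diag(11)[, 11:1]  # a diagonal strand, y,x < 20
  sk <- label_mask(v, c(1, 1, 1))
  lobe <- label_mask(array(1L, dim(v)), c(1, 1, 1))
  tm <- tile_metrics(sk, lobe, c(20, 20))
  expect_equal(sum(tm$length_um > 0), 1)
  expect_equal(which(tm$length_um > 0), 1L)
})

test_that("QC montage geometry and maximum projections behave", {
  vox <- array(0L, c(3, 10, 12))
  vox[2, 3, 4] <- 200L
  st <- calibrated_stack(vox, c(1, 1, 1))
  mip <- max_projection(vox)
  expect_equal(dim(mip), c(10, 12))
  expect_equal(mip[3, 4], 200)
  expect_equal(sum(mip), 200)  # single nonzero slice: MIP equals it

  skel <- label_mask(array(0L, c(3, 10, 12)), c(1, 1, 1))
  m <- make_qc_montage(st, skel)
  expect_equal(dim(m), c(10, 3 * 12 + 4, 3))
  # empty skeleton: middle panel blank, overlay equals raw
  middle <- m[, 15:26, ]
  expect_equal(max(middle), 0)
  overlay <- m[, 29:40, ]
  raw <- m[, 1:12, ]
  expect_equal(overlay, raw)

  p <- tempfile(fileext = ".png")
  make_qc_montage(st, skel, path = p)
  expect_true(file.exists(p))
  unlink(p)
})

test_that("heatmap rendering maps NaN tiles to gray and writes a PNG", {
  hm <- tile_density_map(c(0, 10, 20, 30), c(0, 100, 100, 100), c(2, 2),
                         units = "um/um3")
  img <- render_heatmap(hm, cell_px = 4)
  expect_equal(dim(img), c(8, 8, 3))
  expect_equal(img[1, 1, ], rep(0.5, 3))  # flagged tile is gray
  p <- tempfile(fileext = ".png")
  render_heatmap(hm, path = p)
  expect_true(file.exists(p))
  unlink(p)
})
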