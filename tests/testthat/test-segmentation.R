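test_that("constant images have zero derivative features and gaussian
           features equal to the constant; identity passes through", {
  st <- calibrated_stack(array(37L, c(8, 8, 8)), c(1.5, 1, 1))
  bank <- feature_bank(sigmas = c(1, 2),
                       features = c("identity", "gaussian",
                                    "gradient_magnitude", "laplacian"))
  f <- compute_features(st, bank)
  expect_equal(unname(f[, "identity"]), rep(37, 512))
  expect_equal(unname(f[, "gaussian_s1"]), rep(37, 512), tolerance = 1e-12)
  expect_equal(max(abs(f[, "gradmag_s1"])), 0, tolerance = 1e-10)
  expect_equal(max(abs(f[, "laplacian_s2"])), 0, tolerance = 1e-10)
})

test_that("gaussian smoothing obeys the semigroup property away from
           borders", {
  set.seed(11)
  dim3 <- c(32, 32, 32)
  st <- calibrated_stack(array(as.integer(sample.int(256, prod(dim3), replace = TRUE) - 1L),
                               dim3), c(1, 1, 1))
  v <- array(as.numeric(st$voxels), dim3)
  g1 <- netdens:::gauss3(v, c(1.5, 1.5, 1.5))
  g12 <- netdens:::gauss3(g1, c(2, 2, 2))
  gdirect <- netdens:::gauss3(v, rep(sqrt(1.5^2 + 2^2), 3))
  core <- 9:24  # keep 8 voxels away from each face
  a <- g12[core, core, core]
  b <- gdirect[core, core, core]
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-3)
})

test_that("sigma below half a voxel on an active axis is rejected by
           axis name, and per-slice 2D mode ignores the z axis", {
  st <- calibrated_stack(array(0L, c(4, 16, 16)), c(15, 1, 1))
  expect_error(compute_features(st, feature_bank(sigmas = c(2, 4))), "z")
  bank2d <- feature_bank(sigmas = c(2, 4), use_3d = FALSE)
  expect_silent(f <- compute_features(st, bank2d))
  expect_equal(nrow(f), prod(dim(st$voxels)))
})

test_that("training on separable intensity populations reaches high
           held-out accuracy and survives save/load byte-identically", {
  fx <- make_separable_stack(seed = 42)
  ann_all <- annotate_from_truth(fx$truth, n_per_class = 300, seed = 1)
  idx <- seq_len(nrow(ann_all$coordinates))
  train_i <- idx[idx %% 3 != 0]
  test_i <- idx[idx %% 3 == 0]
  ann_train <- training_annotation(ann_all$coordinates[train_i, ],
                                   ann_all$labels[train_i])
  feats <- compute_features(fx$stack, small_bank())
  clf <- train_classifier(fx$stack, ann_train, small_bank(),
                          n_trees = 50, seed = 42, features = feats)
  expect_gte(clf$training_accuracy, 0.9)
  p <- predict_proba(fx$stack, clf, features = feats)
  rows <- netdens:::coord_to_row(ann_all$coordinates[test_i, ],
                                 dim(fx$stack$voxels))
  held_out <- mean((p[rows] >= 0.5) ==
                   (ann_all$labels[test_i] == "foreground"))
  expect_gt(held_out, 0.95)

  arch <- tempfile(fileext = ".rds")
  save_classifier(clf, arch)
  clf2 <- load_classifier(arch)
  p2 <- predict_proba(fx$stack, clf2, features = feats)
  expect_identical(p, p2)
  unlink(arch)
})

test_that("conflicting labels on identical features give a posterior
           near one half", {
  st <- calibrated_stack(array(100L, c(4, 8, 8)), c(1, 1, 1))
  co <- cbind(z = rep(1:4, 4), y = rep(1:4, each = 4), x = 1L)
  ann <- training_annotation(co, rep(c("foreground", "background"), 8))
  clf <- train_classifier(st, ann, small_bank(), n_trees = 100, seed = 1)
  p <- predict_proba(st, clf)
  expect_true(all(abs(p - 0.5) < 0.25))
})

test_that("single-class annotations are rejected", {
  st <- calibrated_stack(array(1L, c(4, 4, 4)), c(1, 1, 1))
  ann <- training_annotation(cbind(1:3, 1:3, 1:3),
                             rep("foreground", 3))
  expect_error(train_classifier(st, ann, small_bank()),
               "both classes")
})

test_that("segmentation is deterministic and identical with the
           acceleration (chunked) path", {
  fx <- make_separable_stack(seed = 5)
  ann <- annotate_from_truth(fx$truth, n_per_class = 100, seed = 2)
  feats <- compute_features(fx$stack, small_bank())
  clf_a <- train_classifier(fx$stack, ann, small_bank(), n_trees = 30,
                            seed = 9, features = feats)
  clf_b <- train_classifier(fx$stack, ann, small_bank(), n_trees = 30,
                            seed = 9, features = feats)
  m_plain <- apply_classifier(fx$stack, clf_a, features = feats)
  m_again <- apply_classifier(fx$stack, clf_b, features = feats)
  m_accel <- apply_classifier(fx$stack, clf_a, features = feats,
                              acceleration = TRUE)
  expect_identical(m_plain$voxels, m_again$voxels)
  expect_identical(m_plain$voxels, m_accel$voxels)
  expect_true(all(m_plain$voxels %in% c(0L, 1L)))
})

test_that("classifier applied to its training stack reproduces the
           annotated labels and stays quiet on a blank phantom", {
  fx <- make_separable_stack(seed = 42)
  ann <- annotate_from_truth(fx$truth, n_per_class = 200, seed = 3)
  feats <- compute_features(fx$stack, small_bank())
  clf <- train_classifier(fx$stack, ann, small_bank(), n_trees = 50,
                          seed = 42, features = feats)
  mask <- apply_classifier(fx$stack, clf, features = feats)
  rows <- netdens:::coord_to_row(ann$coordinates, dim(fx$stack$voxels))
  agree <- mean((mask$voxels[rows] == 1L) ==
                (ann$labels == "foreground"))
  expect_gte(agree, 0.9)

  # negative control: pure background noise, no tubes
  set.seed(7)
  blank <- calibrated_stack(
    array(as.integer(pmin(pmax(round(rnorm(prod(dim(fx$truth)), 30, 5)),
                               0), 255)), dim(fx$truth)),
    tiny_spacing, bit_depth = 8)
  mb <- apply_classifier(blank, clf)
  expect_lt(mean(mb$voxels > 0), 0.01)
})

test_that("fixed threshold is strictly greater-than and matches a
           brute-force voxel loop", {
  u170 <- calibrated_stack(array(170L, c(4, 8, 8)), c(15, 1.21, 1.21))
  r <- fixed_threshold_area(u170, 170)
  expect_equal(r$count, 0)
  expect_equal(r$volume_um3, 0)

  u171 <- calibrated_stack(array(171L, c(4, 8, 8)), c(15, 1.21, 1.21))
  r <- fixed_threshold_area(u171, 170)
  expect_equal(r$count, 4 * 8 * 8)
  expect_equal(r$area_um2, 4 * 8 * 8 * 1.21 * 1.21)
  expect_equal(r$volume_um3, 4 * 8 * 8 * 15 * 1.21 * 1.21)

  set.seed(3)
  vox <- array(as.integer(sample.int(256, 16^3, replace = TRUE) - 1L), c(16, 16, 16))
  st <- calibrated_stack(vox, c(2, 1, 1))
  # independent scalar loop oracle
  cnt <- 0L
  for (v in as.integer(vox)) if (v > 170L) cnt <- cnt + 1L
  expect_equal(fixed_threshold_area(st, 170)$count, cnt)
  expect_error(fixed_threshold_area(st, 300), "range")
})

test_that("adding correct annotations never degrades held-out accuracy
           much below the two-labels-per-class baseline", {
  fx <- make_separable_stack(seed = 13)
  feats <- compute_features(fx$stack, small_bank())
  d <- dim(fx$stack$voxels)
  hold <- annotate_from_truth(fx$truth, n_per_class = 150, seed = 99)
  hold_rows <- netdens:::coord_to_row(hold$coordinates, d)
  acc_at <- function(n_per_class) {
    ann <- annotate_from_truth(fx$truth, n_per_class = n_per_class,
                               seed = 5)
    clf <- train_classifier(fx$stack, ann, small_bank(), n_trees = 40,
                            seed = 8, features = feats)
    p <- predict_proba(fx$stack, clf, features = feats)
    mean((p[hold_rows] >= 0.5) == (hold$labels == "foreground"))
  }
  base <- acc_at(2)
  for (n in c(10, 50, 200))
    expect_gte(acc_at(n), base - 0.05)
})

test_that("segmentation of a tube phantom overlaps the rasterized truth
           with high Dice", {
  sp <- phantom_spec(shape = c(20, 80, 80), n_tubes = 3, n_steps = 20,
                     radius_um = 3, seed = 11)
  ra <- rasterize_phantom(grow_network(sp), sp)
  ann <- phantom_annotation(ra, n_per_class = 250, seed = 11)
  bank <- feature_bank()  # the full default bank; boundary fidelity
                          # needs the Hessian/Laplacian cues
  feats <- compute_features(ra$stack, bank)
  clf <- train_classifier(ra$stack, ann, bank, n_trees = 60,
                          seed = 11, features = feats)
  pred <- apply_classifier(ra$stack, clf, features = feats)
  a <- pred$voxels > 0
  b <- ra$mask$voxels > 0
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice, 0.8)
})
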