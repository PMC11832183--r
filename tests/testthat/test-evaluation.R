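# independent normal-equations oracle for OLS of y on x
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y * y) - sy^2))
  list(slope = slope, intercept = intercept, r2 = r^2,
       mae = mean(abs(y - x)))
}

test_that("identity input yields slope 1, intercept 0, r2 1, MAE 0; the
           (1,2,3)->(2,4,6) case matches its closed form", {
  rep1 <- regress_paired(paired_measurements(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(rep1$slope, 1)
  expect_equal(rep1$intercept, 0, tolerance = 1e-12)
  expect_equal(rep1$r_squared, 1)
  expect_equal(rep1$mean_absolute_error, 0)

  rep2 <- regress_paired(paired_measurements(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(rep2$slope, 2)
  expect_equal(rep2$intercept, 0, tolerance = 1e-12)
  expect_equal(rep2$r_squared, 1)
  expect_equal(rep2$mean_absolute_error, 2)
})

test_that("random paired vectors match the normal-equations oracle to
           near machine precision", {
  set.seed(21)
  for (i in 1:5) {
    x <- runif(20, 10, 100)
    y <- 1.4 * x + rnorm(20, 0, 8) + 30
    y <- pmax(y, 0)
    rep <- regress_paired(paired_measurements(x, y))
    orc <- ols_oracle(x, y)
    expect_equal(rep$slope, orc$slope, tolerance = 1e-10)
    expect_equal(rep$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(rep$r_squared, orc$r2, tolerance = 1e-10)
    expect_equal(rep$mean_absolute_error, orc$mae, tolerance = 1e-12)
  }
})

test_that("r2 is invariant under affine rescaling and role swap; MAE
           scales with a common unit rescale", {
  set.seed(30)
  x <- runif(15, 1, 50)
  y <- 2 * x + rnorm(15, 0, 5) + 10
  y <- pmax(y, 0)
  base <- regress_paired(paired_measurements(x, y))
  scaled <- regress_paired(paired_measurements(2 * x + 7, y))
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-12)
  swapped <- regress_paired(paired_measurements(y, x))
  expect_equal(swapped$r_squared, base$r_squared, tolerance = 1e-12)
  both <- regress_paired(paired_measurements(1000 * x, 1000 * y))
  expect_equal(both$mean_absolute_error, 1000 * base$mean_absolute_error,
               tolerance = 1e-9)
})

test_that("degenerate regressions are rejected", {
  expect_error(regress_paired(paired_measurements(c(5, 5, 5), c(1, 2, 3))),
               "degenerate")
  expect_error(paired_measurements(1, 1), "at least 2")
  expect_error(paired_measurements(c(1, 2), c(-1, 2)), "non-negative")
})

test_that("annotator spread: zero for identical values, closed form for
           a pair, loop oracle for random vectors", {
  s <- annotator_spread(c(7, 7, 7))
  expect_equal(s$abs_dev, c(0, 0, 0))
  s <- annotator_spread(c(10, 14))
  expect_equal(s$mean, 12)
  expect_equal(s$abs_dev, c(2, 2))
  expect_equal(s$mean_abs_dev, 2)
  set.seed(4)
  v <- runif(11, 0, 100)
  s <- annotator_spread(v)
  m <- sum(v) / length(v)
  dev <- numeric(length(v))
  for (i in seq_along(v)) dev[i] <- abs(v[i] - m)
  expect_equal(s$abs_dev, dev, tolerance = 1e-12)
  expect_equal(s$mean_abs_dev, mean(dev), tolerance = 1e-12)
})

test_that("thresholded area tracks length for fixed-radius straight
           tubes but degrades when radius varies", {
  mk_tube_stack <- function(len_vox, r_um, seed) {
    sp <- phantom_spec(shape = c(12, 40, 110), spacing = c(1.5, 1, 1),
                       n_tubes = 1, n_steps = len_vox, step_um = 4,
                       persistence = 0.9999, radius_um = r_um,
                       intensity = c(tube = 220, background = 30,
                                     noise_sd = 4),
                       psf_sigma_um = 0, seed = seed)
    tr <- grow_network(sp)
    list(stack = rasterize_phantom(tr, sp)$stack,
         len = tr$total_length_um)
  }
  lens <- c(6, 10, 14, 18, 22)
  fixed <- lapply(seq_along(lens), function(i)
    mk_tube_stack(lens[i], 2.5, 100 + i))
  pm_fixed <- baseline_threshold_predictor(
    lapply(fixed, `[[`, "stack"), vapply(fixed, `[[`, 0, "len"), 170)
  r2_fixed <- regress_paired(pm_fixed)$r_squared
  expect_gt(r2_fixed, 0.9)  # area ~ length when radius is constant

  radii <- c(2, 4, 2, 4, 2)
  varied <- lapply(seq_along(lens), function(i)
    mk_tube_stack(lens[i], radii[i], 200 + i))
  pm_var <- baseline_threshold_predictor(
    lapply(varied, `[[`, "stack"), vapply(varied, `[[`, 0, "len"), 170)
  r2_var <- regress_paired(pm_var)$r_squared
  expect_lt(r2_var, r2_fixed)

  # blank stacks give an all-zero predictor column
  blanks <- lapply(1:3, function(i)
    calibrated_stack(array(30L, c(4, 8, 8)), c(1, 1, 1)))
  pm0 <- baseline_threshold_predictor(blanks, c(10, 20, 30), 170)
  expect_equal(pm0$measured, c(0, 0, 0))
})
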