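# Shared fixtures: tiny deterministic stacks, masks and phantoms used
# across the suite. Everything is generated in code; no binary fixtures.

tiny_spacing <- c(1.5, 1, 1)

# small separable two-population stack: dim background, bright tubes
make_separable_stack <- function(dim3 = c(12, 24, 24), seed = 42,
                                 bg_mean = 30, fg_mean = 200, sd = 5) {
  set.seed(seed)
  vox <- array(pmin(pmax(round(rnorm(prod(dim3), bg_mean, sd)), 0), 255),
               dim3)
  fg <- array(FALSE, dim3)
  fg[, dim3[2] / 2 + (-1:1), ] <- TRUE   # a y-slab "tube sheet"
  fg[, , dim3[3] / 2 + (-1:1)] <- fg[, , dim3[3] / 2 + (-1:1)] | TRUE
  vox[fg] <- pmin(pmax(round(rnorm(sum(fg), fg_mean, sd)), 0), 255)
  list(stack = calibrated_stack(array(as.integer(vox), dim3), tiny_spacing,
                                bit_depth = 8, name = "separable"),
       truth = fg)
}

# balanced annotation sampled from a known foreground map
annotate_from_truth <- function(truth, n_per_class = 200, seed = 7) {
  d <- dim(truth)
  set.seed(seed)
  fg <- which(truth)
  bg <- which(!truth)
  pick <- c(sample(fg, n_per_class), sample(bg, n_per_class))
  lab <- rep(c("foreground", "background"), each = n_per_class)
  lin0 <- pick - 1L
  co <- cbind(z = lin0 %% d[1] + 1L,
              y = (lin0 %/% d[1]) %% d[2] + 1L,
              x = lin0 %/% (d[1] * d[2]) + 1L)
  training_annotation(co, lab)
}

# small fast bank for unit tests (full default bank is exercised in the
# acceptance suite)
small_bank <- function() feature_bank(sigmas = c(1, 2),
                                      features = c("gaussian",
                                                   "gradient_magnitude"))

small_phantom_spec <- function(...) {
  phantom_spec(shape = c(16, 48, 48), n_tubes = 2, n_steps = 15, ...)
}

expect_mask_subset <- function(sub, sup) {
  expect_true(all(sub$voxels[sup$voxels == 0L] == 0L))
}
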