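# brute-force all-pairs 26-adjacency + scalar edge-length oracle
oracle_length <- function(mask_vox, spacing) {
  nodes <- which(mask_vox > 0, arr.ind = TRUE)
  n <- nrow(nodes)
  total <- 0
  edges <- 0L
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dd <- abs(nodes[i, ] - nodes[j, ])
      if (max(dd) == 1) {
        edges <- edges + 1L
        total <- total + sqrt(sum((dd * spacing)^2))
      }
    }
  list(total = total, edges = edges, nodes = n)
}

random_sparse_skeleton <- function(seed, dim3 = c(12, 12, 12), p = 0.08) {
  set.seed(seed)
  array(as.integer(runif(prod(dim3)) < p), dim3)
}

test_that("empty masks give empty skeletons and zero length", {
  mk <- label_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))
  sk <- skeletonize_3d(mk)
  expect_equal(sum(sk$voxels), 0)
  lr <- measure_length(build_skeleton_graph(sk))
  expect_equal(lr$total_length_um, 0)
  expect_equal(lr$n_edges, 0)
  expect_equal(lr$n_components, 0)
})

test_that("a solid 3x3x31 bar thins to a single 26-connected spanning
           path with no 2x2x2 block", {
  v <- array(0L, c(9, 9, 35))
  v[4:6, 4:6, 3:33] <- 1L
  sk <- skeletonize_3d(label_mask(v, c(1, 1, 1)))
  expect_mask_subset(sk, label_mask(v, c(1, 1, 1)))
  lr <- measure_length(build_skeleton_graph(sk))
  expect_equal(lr$n_components, 1L)
  expect_equal(lr$n_edges, lr$n_skeleton_voxels - 1L)  # a tree, in fact a path
  # spans the long axis
  xs <- which(sk$voxels > 0, arr.ind = TRUE)[, 3]
  expect_equal(range(xs), c(3, 33))
  # thinness: no solid 2x2x2 block anywhere
  s <- sk$voxels
  blocks <- s[-9, -9, -35] + s[-1, -9, -35] + s[-9, -1, -35] +
    s[-1, -1, -35] + s[-9, -9, -1] + s[-1, -9, -1] + s[-9, -1, -1] +
    s[-1, -1, -1]
  expect_lt(max(blocks), 8)
})

test_that("a rasterized solid torus keeps exactly one cycle", {
  co <- expand.grid(z = 1:9, y = 1:41, x = 1:41)
  tor <- ((sqrt((co$y - 21)^2 + (co$x - 21)^2) - 12)^2 +
          (co$z - 5)^2) <= 9
  mk <- label_mask(array(as.integer(tor), c(9, 41, 41)), c(1, 1, 1))
  lr <- measure_length(build_skeleton_graph(skeletonize_3d(mk)))
  expect_equal(lr$n_components, 1L)
  expect_equal(lr$n_edges - lr$n_skeleton_voxels + lr$n_components, 1L)
})

test_that("graph construction follows 26-adjacency exactly", {
  # two isolated voxels: 2 nodes, no edge
  v <- array(0L, c(5, 5, 5)); v[1, 1, 1] <- 1L; v[5, 5, 5] <- 1L
  g <- build_skeleton_graph(label_mask(v, c(1, 1, 1)))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 0)

  # three collinear voxels: 2 edges (skip pair is not adjacent)
  v <- array(0L, c(3, 3, 5)); v[2, 2, 2:4] <- 1L
  g <- build_skeleton_graph(label_mask(v, c(1, 1, 1)))
  expect_equal(nrow(g$edges), 2)

  # random sparse volumes match the all-pairs oracle
  for (seed in c(9, 10, 11)) {
    v <- random_sparse_skeleton(seed)
    sp <- c(2, 1, 1.5)
    g <- build_skeleton_graph(label_mask(v, sp))
    orc <- oracle_length(v, sp)
    expect_equal(nrow(g$edges), orc$edges)
    expect_equal(measure_length(g)$total_length_um, orc$total,
                 tolerance = 1e-12)
  }
})

test_that("length closed forms: straight lines and single diagonal
           steps", {
  v <- array(0L, c(3, 3, 13)); v[2, 2, 2:12] <- 1L  # 11 voxels along x
  g <- build_skeleton_graph(label_mask(v, c(15, 1.21, 1.21)))
  expect_equal(measure_length(g)$total_length_um, 10 * 1.21)

  v <- array(0L, c(2, 2, 2)); v[1, 1, 1] <- 1L; v[1, 2, 2] <- 1L
  g <- build_skeleton_graph(label_mask(v, c(15, 1, 1)))
  expect_equal(measure_length(g)$total_length_um, sqrt(2))

  v[2, 2, 2] <- 1L; v[1, 2, 2] <- 0L
  g <- build_skeleton_graph(label_mask(v, c(15, 1, 1)))
  expect_equal(measure_length(g)$total_length_um, sqrt(1 + 1 + 225))
})

test_that("total length scales exactly with spacing and is invariant
           under axis permutation with matched spacing", {
  v <- random_sparse_skeleton(21)
  sp <- c(1.5, 1, 2)
  base <- measure_length(build_skeleton_graph(label_mask(v, sp)))
  tripled <- measure_length(build_skeleton_graph(label_mask(v, 3 * sp)))
  expect_equal(tripled$total_length_um, 3 * base$total_length_um,
               tolerance = 1e-12)
  vp <- aperm(v, c(3, 1, 2))
  perm <- measure_length(build_skeleton_graph(
    label_mask(vp, sp[c(3, 1, 2)])))
  expect_equal(perm$total_length_um, base$total_length_um,
               tolerance = 1e-12)
})

test_that("length is additive over disjoint networks in separate
           bounding boxes", {
  vA <- array(0L, c(8, 20, 20)); vA[4, 3:10, 4] <- 1L
  vB <- array(0L, c(8, 20, 20)); vB[6, 14:18, 15] <- 1L
  sp <- c(1.5, 1, 1)
  lenA <- measure_length(build_skeleton_graph(label_mask(vA, sp)))
  lenB <- measure_length(build_skeleton_graph(label_mask(vB, sp)))
  lenU <- measure_length(build_skeleton_graph(label_mask(vA + vB, sp)))
  expect_equal(lenU$total_length_um,
               lenA$total_length_um + lenB$total_length_um)
  expect_equal(lenU$n_components, 2L)
})

test_that("skeletonizing true phantom masks recovers ground-truth length
           to within the voxelization tolerance", {
  sp <- phantom_spec(n_tubes = 3, radius_um = 3, seed = 17)
  tr <- grow_network(sp)
  ra <- rasterize_phantom(tr, sp)
  lr <- skeleton_length(ra$mask)$length
  expect_lt(abs(lr$total_length_um - tr$total_length_um) /
            tr$total_length_um, 0.15)
})
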