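one_cube_mask <- function() {
  m <- array(0, dim = c(16, 16, 16)); m[6:9, 6:9, 6:9] <- 1
  mask_volume(m)
}

test_that("regular mesh over one lattice cube gives 8 vertices and 5 cells", {
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)   # h = 4 voxels
  expect_equal(nrow(mesh$vertices), 8)
  expect_equal(nrow(mesh$cells), 5)
  # cells are non-degenerate and fill the cube: total volume = h^3
  vols <- vapply(seq_len(5), function(j) {
    v <- mesh$vertices[mesh$cells[j, ], ]
    abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
  }, numeric(1))
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 4^3)
})

test_that("adjacent cubes share interface vertices", {
  m <- array(0, dim = c(24, 24, 24)); m[5:12, 5:8, 5:8] <- 1  # 2x1x1 cubes
  mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
  expect_equal(nrow(mesh$vertices), 12)   # 2 cubes share 4 vertices
  expect_equal(nrow(mesh$cells), 10)
})

test_that("meshing rejects empty masks and tiny elements", {
  empty <- mask_volume(array(0, dim = c(16, 16, 16)))
  expect_error(generate_regular_mesh(empty, 8, 2), "empty mask")
  expect_error(generate_regular_mesh(one_cube_mask(), 3, 2), "at least 2")
})

test_that("fused meshes duplicate cut interfaces and fuse shared ones", {
  N <- 24
  m <- array(0, dim = c(N, N, N)); m[5:12, 5:12, 5:12] <- 1
  mask <- mask_volume(m)
  ref <- generate_regular_mesh(mask, 8, 2)
  # one segment covering everything: identical topology to the regular mesh
  seg1 <- array(0L, dim = c(N, N, N)); seg1[m > 0] <- 1L
  f1 <- build_fused_mesh(segment_volume(seg1), mask, 8, 2)
  expect_equal(nrow(f1$vertices), nrow(ref$vertices))
  expect_equal(nrow(f1$cells), nrow(ref$cells))
  # two segments split by a plane, no fusion: interface vertices duplicated
  seg2 <- array(0L, dim = c(N, N, N))
  seg2[5:8, 5:12, 5:12] <- 1L
  seg2[9:12, 5:12, 5:12] <- 2L
  f2 <- build_fused_mesh(segment_volume(seg2), mask, 8, 2)
  # the split plane carries a 3x3 grid of lattice vertices
  expect_equal(nrow(f2$vertices), nrow(ref$vertices) + 9)
  expect_equal(nrow(f2$cells), nrow(ref$cells))
  # fusing the pair restores the regular topology
  f3 <- build_fused_mesh(segment_volume(seg2, fusion_pairs = c(1, 2)),
                         mask, 8, 2)
  expect_equal(nrow(f3$vertices), nrow(ref$vertices))
  expect_equal(nrow(f3$cells), nrow(ref$cells))
  expect_error(
    build_fused_mesh(segment_volume(seg2, fusion_pairs = c(1, 7)), mask, 8, 2),
    "unknown")
})

test_that("element weights interpolate linearly between w_min and 1", {
  N <- 24
  m <- array(0, dim = c(N, N, N)); m[5:12, 5:12, 5:12] <- 1
  mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
  # craft a volume with per-element mean densities 0, half-max, max
  V <- array(0, dim = c(N, N, N))
  a <- mesh$assignment
  cells_of <- split(seq_along(a$cell), a$cell)
  ids <- as.integer(names(cells_of))
  V[a$voxel_index[cells_of[[1]]]] <- 2      # densest element
  V[a$voxel_index[cells_of[[2]]]] <- 1      # half the max mean
  vol <- canonical_volume(V, 2)
  w <- compute_element_weights(mesh, vol, w_min = 0.5)$element_weights
  expect_equal(w[ids[1]], 1.0)
  expect_equal(w[ids[2]], 0.75)
  expect_equal(w[ids[3]], 0.5)              # empty element -> w_min
  # all-zero volume: every weight w_min
  w0 <- compute_element_weights(mesh, canonical_volume(V * 0, 2),
                                w_min = 0.5)$element_weights
  expect_true(all(w0 == 0.5))
})

test_that("flow interpolation reproduces constant and linear fields", {
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)
  n_v <- nrow(mesh$vertices)
  d <- matrix(rep(c(0.3, -1.1, 0.7), each = n_v), ncol = 3)
  fl <- interpolate_flow(mesh, d)
  ai <- mesh$assignment$voxel_index
  expect_lt(max(abs(fl$dx[ai] - 0.3)), 1e-12)
  expect_lt(max(abs(fl$dy[ai] + 1.1)), 1e-12)
  # linear field L(x) = A x + b is reproduced exactly by linear shape fns
  A <- matrix(c(.1, -.2, .05, .3, .02, -.1, 0, .15, .08), 3, 3)
  b <- c(1, -2, 0.5)
  dl <- mesh$vertices %*% t(A) + rep(b, each = n_v)
  fll <- interpolate_flow(mesh, dl)
  coords <- arrayInd(ai, rep(16, 3)) - 1
  expect_lt(max(abs(fll$dx[ai] - (coords %*% A[1, ] + b[1]))), 1e-9)
  expect_lt(max(abs(fll$dz[ai] - (coords %*% A[3, ] + b[3]))), 1e-9)
  # voxels outside all cells stay put
  outside <- setdiff(seq_len(16^3), ai)
  expect_true(all(fll$dx[outside] == 0))
  expect_error(interpolate_flow(mesh, d * NA), "non-finite")
})

test_that("interpolated values stay within their cell's vertex range", {
  set.seed(8)
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)
  d <- matrix(rnorm(nrow(mesh$vertices) * 3), ncol = 3)
  fl <- interpolate_flow(mesh, d)
  a <- mesh$assignment
  for (k in seq(1, length(a$voxel_index), by = 17)) {
    cell_d <- d[mesh$cells[a$cell[k], ], ]
    v <- c(fl$dx[a$voxel_index[k]], fl$dy[a$voxel_index[k]],
           fl$dz[a$voxel_index[k]])
    expect_true(all(v >= apply(cell_d, 2, min) - 1e-9))
    expect_true(all(v <= apply(cell_d, 2, max) + 1e-9))
  }
})

test_that("rigidity energy vanishes for isometries and scores stretches", {
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)
  n_v <- nrow(mesh$vertices)
  expect_equal(rigidity_energy(mesh, matrix(0, n_v, 3))$energy, 0)
  set.seed(9)
  for (i in 1:25) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- tetraflex:::rotation_about_axis(ax, runif(1, -pi, pi))
    d <- mesh$vertices %*% t(R) - mesh$vertices
    expect_lt(rigidity_energy(mesh, d)$energy, 1e-9)
    # translation invariance
    dt <- d + rep(rnorm(3), each = n_v)
    expect_lt(rigidity_energy(mesh, dt)$energy, 1e-9)
  }
  # single element, w = 1, deformation gradient diag(2, 1, 1): E = (2-1)^2
  verts <- rbind(c(4, 4, 4), c(8, 4, 4), c(4, 8, 4), c(4, 4, 8))
  single <- tetraflex:::tetra_mesh(verts, matrix(1:4, 1), 16L, 1)
  d2 <- verts %*% diag(c(2, 1, 1)) - verts
  expect_equal(rigidity_energy(single, d2)$energy, 1)
})

test_that("rigidity gradient matches central differences on random meshes", {
  set.seed(10)
  for (rep in 1:3) {
    # random 3-cell mesh: a strip of one lattice cube plus jittered vertices
    m <- array(0, dim = c(16, 16, 16)); m[4:12, 4:7, 4:7] <- 1
    mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
    d <- matrix(rnorm(nrow(mesh$vertices) * 3, sd = 0.4), ncol = 3)
    g <- rigidity_energy(mesh, d, gradient = TRUE)$grad
    h <- 1e-4
    for (t in 1:8) {
      i <- sample(nrow(d), 1); j <- sample(3, 1)
      dp <- d; dp[i, j] <- dp[i, j] + h
      dm <- d; dm[i, j] <- dm[i, j] - h
      fd <- (rigidity_energy(mesh, dp)$energy -
               rigidity_energy(mesh, dm)$energy) / (2 * h)
      expect_lt(abs(fd - g[i, j]) / max(abs(fd), 1e-6), 1e-4)
    }
  }
})

test_that("batched rigidity is the sum of per-field energies", {
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)
  set.seed(11)
  n_v <- nrow(mesh$vertices)
  batch <- array(rnorm(2 * n_v * 3, sd = 0.3), dim = c(2, n_v, 3))
  e1 <- rigidity_energy(mesh, batch[1, , ])$energy
  e2 <- rigidity_energy(mesh, batch[2, , ])$energy
  expect_equal(rigidity_energy(mesh, batch)$energy, e1 + e2,
               tolerance = 1e-12)
})

test_that("mesh JSON serialization round trips", {
  mesh <- generate_regular_mesh(one_cube_mask(), 8, 2)
  path <- tempfile(fileext = ".json")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(back$vertices, mesh$vertices, ignore_attr = TRUE)
  expect_equal(back$cells, mesh$cells, ignore_attr = TRUE)
  expect_equal(back$assignment$voxel_index, mesh$assignment$voxel_index)
})
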