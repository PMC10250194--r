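test_that("FSC is 1 for identical volumes and small for independent noise", {
  vol <- blob_volume()
  curve <- fsc(vol, vol)
  pop <- !is.na(curve$fsc)
  expect_true(all(abs(curve$fsc[pop] - 1) < 1e-12))
  set.seed(41)
  a <- canonical_volume(array(rnorm(32^3), dim = rep(32, 3)), 1)
  b <- canonical_volume(array(rnorm(32^3), dim = rep(32, 3)), 1)
  cn <- fsc(a, b)
  # lowest shells hold only a handful of Fourier samples; judge shells >= 2
  expect_lt(mean(abs(cn$fsc[cn$shell >= 2]), na.rm = TRUE), 0.1)
  expect_error(fsc(vol, a), "mismatch")
})

test_that("FSC matches the SNR/(SNR+1) closed form at per-shell SNR 1", {
  set.seed(42)
  N <- 32
  sig <- array(rnorm(N^3), dim = rep(N, 3))
  # two half-maps: same signal, independent noise of equal per-voxel power
  va <- canonical_volume(sig + array(rnorm(N^3), dim = rep(N, 3)), 1)
  vb <- canonical_volume(sig + array(rnorm(N^3), dim = rep(N, 3)), 1)
  curve <- fsc(va, vb)
  mid <- curve$shell >= 3 & curve$shell <= 14   # well-populated shells
  expect_lt(abs(mean(curve$fsc[mid]) - 0.5), 0.05)
})

test_that("FSC is symmetric and scale-invariant", {
  set.seed(43)
  a <- blob_volume()
  b <- canonical_volume(a$data + array(rnorm(16^3, sd = 0.1), rep(16, 3)), 2)
  c1 <- fsc(a, b); c2 <- fsc(b, a)
  expect_equal(c1$fsc, c2$fsc, tolerance = 1e-12)
  c3 <- fsc(canonical_volume(3.7 * a$data, 2), b)
  expect_equal(c1$fsc, c3$fsc, tolerance = 1e-12)
})

test_that("Cn symmetrization averages rotated copies and is idempotent", {
  vol <- blob_volume()
  expect_identical(symmetrize_cn(vol, 1)$data, vol$data)
  # n = 2 equals the hand-computed average with the half-turn rotation
  s2 <- symmetrize_cn(vol, 2)
  R <- tetraflex:::rotation_about_axis(c(0, 0, 1), pi)
  byhand <- 0.5 * (vol$data + tetraflex:::cpp_rotate_volume(vol$data, R))
  expect_lt(max(abs(s2$data - byhand)), 1e-12)
  # a C4-symmetric volume is left unchanged within resampling tolerance
  N <- 32
  g <- seq(0, N - 1) - N / 2
  r2 <- outer(g^2, g^2, "+")
  ring <- exp(-(sqrt(r2) - 6)^2 / 4)
  vsym <- canonical_volume(array(outer(c(ring), exp(-g^2 / 18)), rep(N, 3)), 1)
  s4 <- symmetrize_cn(vsym, 4)
  expect_lt(sqrt(sum((s4$data - vsym$data)^2) / sum(vsym$data^2)), 1e-6)
  # idempotence within resampling tolerance
  s44 <- symmetrize_cn(s4, 4)
  expect_lt(sqrt(sum((s44$data - s4$data)^2) / sum(s4$data^2)), 1e-2)
})

test_that("reconstruction returns zero for zero images", {
  vol <- blob_volume()
  pp <- tiny_particles(vol, M = 4)
  pp$images[] <- 0
  rec <- reconstruct_highres(pp, NULL, NULL, NULL, 16, max_iters = 5)
  expect_true(all(rec$data == 0))
})

test_that("L-BFGS solves the quadratic to the same point as a CG oracle", {
  set.seed(44)
  vol <- blob_volume()
  pp <- tiny_particles(vol, M = 8, sigma = 0.05)
  ridge <- 5
  rec <- reconstruct_highres(pp, NULL, NULL, NULL, 16, max_iters = 60,
                             grad_tol = 1e6, ridge = ridge)
  # independent conjugate-gradient solver on the same normal equations
  ctfs <- tetraflex:::ctf_cache(pp)
  ctfs2 <- lapply(ctfs, function(C) C * C)
  op <- tetraflex:::recon_operator(pp, NULL, NULL, 0L, ctfs2)
  b <- op$rhs(ctfs)
  x <- array(0, dim = dim(b)); r <- b; p <- r
  rs <- sum(r^2)
  for (it in 1:80) {
    Hp <- op$apply_H(p) + ridge * p
    alpha <- rs / sum(p * Hp)
    x <- x + alpha * p
    r <- r - alpha * Hp
    rs_new <- sum(r^2)
    if (sqrt(rs_new) < 1e-10 * sqrt(sum(b^2))) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  expect_lt(sqrt(sum((rec$data - x)^2) / sum(x^2)), 1e-4)
})

test_that("a rigid noiseless fixture is recovered accurately inside the mask", {
  set.seed(45)
  N <- 24
  vol <- blob_volume(N = N, voxel = 2,
                     blobs = list(c(9, 12, 12, 1.6, 1), c(15, 11, 12, 1.4, 0.9),
                                  c(12, 15, 10, 1.1, 0.7),
                                  c(12, 9, 14, 0.9, 0.6)))
  pp <- tiny_particles(vol, M = 500, sigma = 0)
  rec <- reconstruct_highres(pp, NULL, NULL, NULL, N, max_iters = 40,
                             grad_tol = 1e5)
  mask <- vol$data > 0.02 * max(vol$data)
  rel <- sqrt(sum((rec$data[mask] - vol$data[mask])^2) /
                sum(vol$data[mask]^2))
  expect_lt(rel, 0.05)
})

test_that("convected series reproduces the map at zero flow and moves mass", {
  st_vol <- blob_volume()
  m <- array(0, dim = c(16, 16, 16)); m[4:13, 4:13, 4:13] <- 1
  mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
  th0 <- init_generator(K = 1, n_v = nrow(mesh$vertices), seed = 2,
                        init_scale = 0)
  ser <- convected_series(st_vol, th0, mesh, matrix(c(-1, 0, 1), 3, 1))
  for (w in ser) expect_identical(w$data, st_vol$data)
  th <- init_generator(K = 1, n_v = nrow(mesh$vertices), n_layers = 3,
                       hidden = 8, seed = 3, init_scale = 1)
  ser2 <- convected_series(st_vol, th, mesh, matrix(c(-1, 1), 2, 1))
  expect_identical(ser2[[1]]$data,
                   convected_series(st_vol, th, mesh,
                                    matrix(-1, 1, 1))[[1]]$data)
  com <- function(W) {
    w <- pmax(W, 0); g <- seq(0, 15)
    c(sum(apply(w, 1, sum) * g), sum(apply(w, 2, sum) * g)) / sum(w)
  }
  expect_gt(sum(abs(com(ser2[[1]]$data) - com(ser2[[2]]$data))), 1e-3)
})

test_that("FSC curves serialize to CSV with resolution attributes", {
  vol <- blob_volume()
  curve <- fsc(vol, vol)
  expect_true(is.na(attr(curve, "resolution_0.143")))   # never crosses
  path <- tempfile(fileext = ".csv")
  write_fsc(curve, path)
  back <- read.csv(path)
  expect_equal(back$fsc, curve$fsc)
  expect_equal(names(back), c("shell", "frequency", "fsc"))
})
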