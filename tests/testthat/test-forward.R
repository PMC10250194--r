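test_that("convection with zero flow is the exact identity", {
  vol <- blob_volume()
  N <- box_size(vol)
  zf <- list(dx = array(0, dim = rep(N, 3)), dy = array(0, dim = rep(N, 3)),
             dz = array(0, dim = rep(N, 3)))
  expect_identical(convect(vol, zf)$data, vol$data)
  expect_identical(convect(vol, zf, kernel = "tricubic")$data, vol$data)
})

test_that("uniform one-voxel shift moves the map by one voxel", {
  vol <- blob_volume()
  N <- box_size(vol)
  fl <- list(dx = array(1, dim = rep(N, 3)), dy = array(0, dim = rep(N, 3)),
             dz = array(0, dim = rep(N, 3)))
  W <- convect(vol, fl)$data
  expect_equal(W[2:N, , ], vol$data[1:(N - 1), , ], tolerance = 1e-14)
  # only the boundary slab can lose mass
  expect_equal(sum(W), sum(vol$data) - sum(vol$data[N, , ]),
               tolerance = 1e-12)
})

test_that("convection conserves mass and matches the splat oracle", {
  set.seed(12)
  N <- 16
  V <- array(rnorm(N^3)^2, dim = rep(N, 3))
  sup <- array(0, dim = rep(N, 3)); sup[4:13, 4:13, 4:13] <- 1
  vol <- canonical_volume(V * sup, 1.5)
  for (s in 1:4) {
    fl <- smooth_flow(N, amp = 1.3, seed = s)
    W <- convect(vol, fl)
    expect_lt(abs(sum(W$data) - sum(vol$data)) / sum(vol$data), 1e-9)
    expect_lt(max(abs(W$data - splat_oracle(vol$data, fl))), 1e-9)
  }
  # tricubic kernel also reproduces constants, hence conserves in-grid mass
  flc <- smooth_flow(N, amp = 1.0, seed = 5)
  Wc <- convect(vol, flc, kernel = "tricubic")
  expect_lt(abs(sum(Wc$data) - sum(vol$data)) / sum(vol$data), 1e-9)
  # divergent displacements are flagged
  bad <- list(dx = array(N, dim = rep(N, 3)), dy = fl$dy * 0, dz = fl$dz * 0)
  expect_error(convect(vol, bad), "divergent")
})

test_that("projection has the declared normalization and symmetry", {
  N <- 16
  V <- array(0, dim = rep(N, 3)); V[5:12, 5:12, 5:12] <- 1   # side-8 cube
  vol <- canonical_volume(V, 1)
  img <- project(vol, diag(3))
  expect_equal(img[9, 9], 8)
  # 90 degree in-plane rotation rotates the projection
  set.seed(13)
  vb <- blob_volume()
  i0 <- project(vb, diag(3))
  i90 <- project(vb, euler_to_matrix(0, 0, 90))
  # out(x, y) = in(y, N - x) for rotation about the center voxel N/2
  ref <- i0 * 0
  c0 <- N / 2
  for (a in 0:(N - 1)) for (b in 0:(N - 1)) {
    xi <- b; yi <- -(a - c0) + c0
    if (yi >= 0 && yi <= N - 1) ref[a + 1, b + 1] <- i0[xi + 1, yi + 1]
  }
  expect_lt(max(abs(i90 - ref)), 1e-6 * max(abs(i0)))
  expect_error(project(vb, diag(3) * 2), "orthonormal")
})

test_that("projection is linear in the volume", {
  set.seed(14)
  v1 <- blob_volume()
  v2 <- canonical_volume(array(rnorm(16^3), dim = rep(16, 3)), 2)
  R <- euler_to_matrix(25, 40, 65)
  pa <- project(canonical_volume(2 * v1$data - 3 * v2$data, 2), R, c(.3, -.7))
  pb <- 2 * project(v1, R, c(.3, -.7)) - 3 * project(v2, R, c(.3, -.7))
  expect_lt(max(abs(pa - pb)), 1e-12 * max(abs(pa)))
})

test_that("real-space projection agrees with central Fourier-slice extraction", {
  # oracle: exact (separable) DTFT of the volume evaluated on the rotated
  # central plane; the high-order projector must match within 1e-3, and the
  # trilinear projector within its kernel's frequency response (a few %)
  vol <- blob_volume(N = 32, voxel = 1,
                     blobs = list(c(14, 16, 17, 2.5, 1),
                                  c(18, 15, 15, 3.0, 0.7)))
  N <- 32; c0 <- N / 2
  R <- euler_to_matrix(30, 50, 20)
  img <- project(vol, R, interp = "tricubic")
  img_tri <- project(vol, R)
  k1 <- (0:(N - 1)); k1[k1 >= N / 2] <- k1[k1 >= N / 2] - N
  Fimg <- fft(img)
  Vr <- vol$data; dim(Vr) <- c(N * N, N)
  xs <- (0:(N - 1)) - c0
  num <- 0; den <- 0
  for (a in 1:N) for (b in 1:N) {
    k <- c(k1[a], k1[b])
    q <- drop(t(R) %*% c(k, 0)) / N          # cycles per sample, q_z = 0 slice
    az <- exp(-2i * pi * q[3] * xs)
    ay <- exp(-2i * pi * q[2] * xs)
    ax <- exp(-2i * pi * q[1] * xs)
    t1 <- Vr %*% az; dim(t1) <- c(N, N)
    acc <- sum((t1 %*% ay) * ax)             # exact centered DTFT at R^T k
    fi <- Fimg[a, b] * exp(2i * pi * (k[1] + k[2]) * c0 / N)
    num <- num + Mod(fi - acc)^2
    den <- den + Mod(fi)^2
  }
  expect_lt(sqrt(num / den), 1e-3)
  expect_lt(sqrt(sum((img_tri - img)^2) / sum(img^2)), 0.05)
})

test_that("CTF follows the weak-phase model", {
  N <- 32
  # pure amplitude contrast: CTF = -1 everywhere
  c1 <- ctf_params(defocus_u = 0, defocus_v = 0, voltage = 300, cs = 0,
                   amplitude_contrast = 1, pixel_size = 2)
  arr <- ctf_array(c1, N)
  expect_equal(max(abs(arr + 1)), 0, tolerance = 1e-12)
  img <- matrix(rnorm(N^2), N, N)
  expect_equal(apply_ctf(img, c1), -img, tolerance = 1e-12)
  # pure phase contrast: first zero where chi(s) = pi (root-finding oracle)
  cp <- ctf_params(defocus_u = 15000, voltage = 300, cs = 2.7,
                   amplitude_contrast = 0, pixel_size = 1)
  lambda <- electron_wavelength(300)
  chi <- function(s) pi * lambda * s^2 * 15000 -
    (pi / 2) * 2.7e7 * lambda^3 * s^4
  s_root <- uniroot(function(s) chi(s) - pi, c(1e-4, 0.1), tol = 1e-12)$root
  ctf_1d <- function(s) -sin(chi(s))
  expect_lt(abs(ctf_1d(s_root)), 1e-6)
  s_grid <- seq(0, s_root * 1.05, length.out = 2000)
  vals <- ctf_1d(s_grid)
  first_flip <- s_grid[min(which(diff(sign(vals[-1])) != 0)) + 1]
  expect_lt(abs(first_flip - s_root) / s_root, 1e-2)
  # applying twice multiplies the spectrum by CTF^2 >= 0
  ci <- ctf_params(defocus_u = 12000, pixel_size = 1.5)
  twice <- apply_ctf(apply_ctf(img, ci), ci)
  F2 <- fft(twice) / fft(img)
  expect_gt(min(Re(F2[Mod(fft(img)) > 1e-6])), -1e-10)
})

test_that("electron wavelength matches known reference values", {
  expect_equal(electron_wavelength(300), 0.0197, tolerance = 1e-2)
  expect_equal(electron_wavelength(200), 0.0251, tolerance = 1e-2)
})

test_that("predict_image composes the pipeline exactly", {
  vol <- blob_volume()
  m <- array(0, dim = c(16, 16, 16)); m[5:12, 5:12, 5:12] <- 1
  mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
  th <- init_generator(K = 1, n_v = nrow(mesh$vertices), n_layers = 3,
                       hidden = 12, seed = 20, init_scale = 0.4)
  R <- euler_to_matrix(15, 75, -30)
  ct <- ctf_params(defocus_u = 11000, pixel_size = 2)
  # zero generator: exactly the rigid CTF-projection pipeline
  th0 <- th; th0$W_out[] <- 0
  p0 <- predict_image(vol, th0, 0.7, mesh, R, c(0.4, -0.2), ct)
  expect_identical(p0, apply_ctf(project(vol, R, c(0.4, -0.2)), ct))
  # fused and explicit convection paths agree to machine precision
  pf <- predict_image(vol, th, 0.7, mesh, R, c(0.4, -0.2), ct, fused = TRUE)
  pe <- predict_image(vol, th, 0.7, mesh, R, c(0.4, -0.2), ct, fused = FALSE)
  expect_lt(max(abs(pf - pe)), 1e-9)
  # deterministic
  expect_identical(pf, predict_image(vol, th, 0.7, mesh, R, c(0.4, -0.2), ct))
  # compose-by-hand oracle: interpolate flow, convect, project, modulate
  vd <- generate_flows(th, 0.7)[1, , ]
  fl <- interpolate_flow(mesh, vd)
  by_hand <- apply_ctf(project(convect(vol, fl), R, c(0.4, -0.2)),
                       ctf_array(ct, 16))
  expect_lt(max(abs(pf - by_hand)), 1e-9)
})

test_that("data energy is the half summed squared residual and additive", {
  vol <- blob_volume()
  m <- array(0, dim = c(16, 16, 16)); m[5:12, 5:12, 5:12] <- 1
  mesh <- generate_regular_mesh(mask_volume(m), 8, 2)
  th0 <- init_generator(K = 1, n_v = nrow(mesh$vertices), seed = 1,
                        init_scale = 0)
  pp <- tiny_particles(vol, M = 3)
  z <- matrix(0, 3, 1)
  # images generated by the same rigid pipeline: energy is exactly zero
  expect_equal(data_energy(pp, vol, th0, z, mesh), 0)
  # constant image vs zero model: E = 0.5 * sum(I^2)
  pz <- pp
  pz$images[] <- 1
  zerovol <- canonical_volume(vol$data * 0, vol$voxel_size)
  expect_equal(data_energy(pz, zerovol, th0, z, mesh), 0.5 * 3 * 16^2)
  # batch additivity
  e12 <- data_energy(tetraflex:::subset_particles(pp, 1:2), vol, th0,
                     z[1:2, , drop = FALSE], mesh)
  e3 <- data_energy(tetraflex:::subset_particles(pp, 3), vol, th0,
                    z[3, , drop = FALSE], mesh)
  pp$images[, , 1] <- pp$images[, , 1] + 0.5
  e_all <- data_energy(pp, vol, th0, z, mesh)
  expect_equal(e_all, e12 + e3 + 0.5 * 0.5^2 * 16^2, tolerance = 1e-8)
})

test_that("full loss gradients pass finite-difference checks", {
  set.seed(21)
  N <- 12
  vol <- blob_volume(N = N, voxel = 2,
                     blobs = list(c(4, 6, 6, 1.2, 1), c(8, 6, 6, 1.0, 0.8),
                                  c(6, 8, 5, 0.9, 0.6)))
  m <- array(0, dim = rep(N, 3)); m[3:10, 3:10, 3:10] <- 1
  mesh <- generate_regular_mesh(mask_volume(m), 6, 2)
  mesh <- compute_element_weights(mesh, vol)
  th <- init_generator(K = 2, n_v = nrow(mesh$vertices), n_layers = 3,
                       hidden = 16, seed = 5, init_scale = 0.3)
  pp <- tiny_particles(vol, M = 3, sigma = 0.1)
  z <- matrix(rnorm(6) * 0.5, 3, 2)
  out <- loss_and_gradients(pp, vol, th, z, mesh, lambda = 2)
  tot <- function(v, t, zz)
    loss_and_gradients(pp, v, t, zz, mesh, lambda = 2,
                       want = character(0))$total
  h <- 1e-5
  for (t in 1:5) {
    i <- sample(N^3, 1)
    vp <- vol; vp$data[i] <- vp$data[i] + h
    vm <- vol; vm$data[i] <- vm$data[i] - h
    fd <- (tot(vp, th, z) - tot(vm, th, z)) / (2 * h)
    if (abs(fd) > 1e-5)
      expect_lt(abs(fd - out$gV[i]) / abs(fd), 1e-3)
  }
  for (i in 1:3) for (k in 1:2) {
    zp <- z; zp[i, k] <- zp[i, k] + h
    zm <- z; zm[i, k] <- zm[i, k] - h
    fd <- (tot(vol, th, zp) - tot(vol, th, zm)) / (2 * h)
    expect_lt(abs(fd - out$gz[i, k]) / max(abs(fd), 1e-4), 1e-3)
  }
  for (t in 1:5) {
    i <- sample(length(th$W_out), 1)
    tp <- th; tp$W_out[i] <- tp$W_out[i] + h
    tm <- th; tm$W_out[i] <- tm$W_out[i] - h
    fd <- (tot(vol, tp, z) - tot(vol, tm, z)) / (2 * h)
    if (abs(fd) > 1e-5)
      expect_lt(abs(fd - out$gtheta$W_out[i]) / abs(fd), 1e-3)
  }
})
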