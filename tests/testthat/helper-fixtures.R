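# Small shared fixtures, built in code.  Heavyweight study objects are cached
# per session through lazy accessors (see helper-study.R).

# deterministic blobby test volume
blob_volume <- function(N = 16, voxel = 2,
                        blobs = list(c(6, 8, 8, 1.3, 1),
                                     c(10, 8, 7, 1.0, 0.8),
                                     c(8, 10, 9, 0.9, 0.6))) {
  V <- array(0, dim = c(N, N, N))
  g <- seq(0, N - 1)
  for (b in blobs) {
    gx <- exp(-(g - b[1])^2 / (2 * b[4]^2))
    gy <- exp(-(g - b[2])^2 / (2 * b[4]^2))
    gz <- exp(-(g - b[3])^2 / (2 * b[4]^2))
    V <- V + b[5] * outer(outer(gx, gy), gz)
  }
  canonical_volume(V, voxel)
}

# a smooth periodic flow field, scaled to max amplitude `amp`, zero within
# `margin` voxels of the boundary so mass cannot leave the grid
smooth_flow <- function(N, amp = 1.2, seed = 1, margin = 0) {
  set.seed(seed)
  ph <- runif(6, 0, 2 * pi)
  g <- seq(0, N - 1)
  f1 <- outer(outer(sin(2 * pi * g / N + ph[1]), cos(2 * pi * g / N + ph[2])),
              sin(2 * pi * g / N + ph[3]))
  f2 <- outer(outer(cos(2 * pi * g / N + ph[4]), sin(2 * pi * g / N + ph[5])),
              cos(2 * pi * g / N + ph[6]))
  f3 <- outer(outer(sin(4 * pi * g / N + ph[2]), sin(2 * pi * g / N + ph[6])),
              cos(4 * pi * g / N + ph[1]))
  out <- list(dx = amp * f1, dy = amp * f2, dz = amp * f3)
  if (margin > 0) {
    w <- array(0, dim = c(N, N, N))
    idx <- (margin + 1):(N - margin)
    w[idx, idx, idx] <- 1
    out <- lapply(out, function(a) a * w)
  }
  out
}

# brute-force triple-loop splat oracle for convection (trilinear)
splat_oracle <- function(V, fl) {
  N <- dim(V)[1]
  W <- array(0, dim = dim(V))
  for (iz in 0:(N - 1)) for (iy in 0:(N - 1)) for (ix in 0:(N - 1)) {
    val <- V[ix + 1, iy + 1, iz + 1]
    if (val == 0) next
    u <- c(ix + fl$dx[ix + 1, iy + 1, iz + 1],
           iy + fl$dy[ix + 1, iy + 1, iz + 1],
           iz + fl$dz[ix + 1, iy + 1, iz + 1])
    i0 <- floor(u); f <- u - i0
    for (c in 0:1) for (b in 0:1) for (a in 0:1) {
      p <- i0 + c(a, b, c)
      if (any(p < 0) || any(p > N - 1)) next
      w <- prod(ifelse(c(a, b, c) == 1, f, 1 - f))
      W[p[1] + 1, p[2] + 1, p[3] + 1] <-
        W[p[1] + 1, p[2] + 1, p[3] + 1] + val * w
    }
  }
  W
}

# tiny particle set rendered through the package's own rigid forward model
tiny_particles <- function(vol, M = 4, seed = 3, sigma = 0,
                           defocus = c(9000, 15000)) {
  set.seed(seed)
  N <- box_size(vol)
  poses <- array(0, dim = c(3, 3, M))
  for (i in seq_len(M)) poses[, , i] <- tetraflex:::random_rotation()
  shifts <- matrix(runif(2 * M, -1, 1) * vol$voxel_size, M, 2)
  ctf <- data.frame(defocus_u = runif(M, defocus[1], defocus[2]),
                    defocus_v = runif(M, defocus[1], defocus[2]),
                    astig_angle = runif(M, 0, 180), voltage = 300, cs = 2.7,
                    amplitude_contrast = 0.07, phase_shift = 0)
  imgs <- array(0, dim = c(N, N, M))
  for (i in seq_len(M)) {
    row <- ctf[i, ]; row$pixel_size <- vol$voxel_size
    img <- project(vol, poses[, , i], shifts[i, ] / vol$voxel_size)
    imgs[, , i] <- apply_ctf(img, ctf_array(row, N)) +
      if (sigma > 0) matrix(rnorm(N^2, sd = sigma), N, N) else 0
  }
  particle_set(imgs, poses, shifts, ctf, vol$voxel_size)
}
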