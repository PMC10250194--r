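# Synthetic flexible-particle datasets with fully known ground truth: a toy
# two-domain molecule whose mobile domain swings about a hinge axis, rendered
# through the same image-formation model the package fits (poses, CTF, white
# noise), with the true canonical map, deformation field and latents retained.

#' Toy flexible molecule specification
#'
#' A static domain and a mobile domain of Gaussian blobs joined by a
#' connector; the mobile domain rotates rigidly about a hinge axis, blended
#' to zero across the connector, driven by a scalar latent coordinate.  Blob
#' layouts are fixed deterministic tables; sizes mix coarse (domain-scale)
#' and fine (secondary-structure-scale) blobs so that the map carries signal
#' well beyond typical training band limits.
#'
#' @param N training box size (default 32).
#' @param voxel_size voxel edge in Angstrom (default 3).
#' @param max_angle_deg hinge swing reached at latent `|z| = 3` (default 20;
#'   at most 45).
#' @param K_true latent dimension of the true motion (1: hinge angle).
#' @param n_fine fine blobs per domain (default 20).
#' @return A `toy_molecule_spec`.
#' @export
toy_molecule_spec <- function(N = 32L, voxel_size = 3, max_angle_deg = 20,
                              K_true = 1L, n_fine = 20L) {
  stopifnot(max_angle_deg <= 45, K_true == 1L)
  c0 <- N / 2
  s <- N / 32  # blob layout defined at box 32, scaled to N
  rng <- local({ set.seed(42)  # fixed layout table, not a tunable
    function(n, lo, hi) stats::runif(n, lo, hi) })
  # The static domain is a coarse anchor; the mobile domain carries the
  # molecule's fine (secondary-structure-scale) features and sits on a long
  # lever arm 4-11 voxels off the hinge axis, so the 20-degree swing moves
  # it by several voxels -- the regime where rigid averaging destroys the
  # fine detail that motion correction can recover.
  static_blobs <- cbind(rng(6, 7, 13), rng(6, 12, 20), rng(6, 12, 20),
                        sigma = rng(6, 1.3, 1.8), amp = rng(6, 0.7, 1.0))
  mobile_blobs <- rbind(
    cbind(rng(2, 21, 26), rng(2, 13, 19), rng(2, 13, 19),
          sigma = rng(2, 1.3, 1.6), amp = rng(2, 0.5, 0.7)),
    cbind(rng(n_fine, 20, 27), rng(n_fine, 12, 20), rng(n_fine, 11, 21),
          sigma = rng(n_fine, 0.72, 0.95), amp = rng(n_fine, 0.9, 1.3)))
  connector <- c(16, 16, 16, 1.6, 0.9)
  blobs <- rbind(static_blobs, mobile_blobs, connector)
  colnames(blobs) <- c("x", "y", "z", "sigma", "amp")
  blobs[, 1:3] <- blobs[, 1:3] * s
  blobs[, "sigma"] <- blobs[, "sigma"] * s
  spec <- structure(list(
    N = as.integer(N), voxel_size = voxel_size,
    blobs = blobs,
    n_static = nrow(static_blobs),
    hinge_point = c(c0, c0, c0),
    hinge_axis = c(0, 0, 1),
    blend_x = c(15, 19) * s,   # smoothstep band across the connector
    max_angle = max_angle_deg * pi / 180,
    K_true = as.integer(K_true)), class = "toy_molecule_spec")
  margin <- 3 * spec$blobs[, "sigma"]
  if (any(spec$blobs[, 1:3] < margin) ||
      any(spec$blobs[, 1:3] > N - 1 - margin))
    stop("blob outside the box with < 3 sigma margin")
  spec
}

#' Render the toy molecule's canonical map
#'
#' Sum of isotropic Gaussians on the voxel grid; values below `1e-8` of the
#' peak are clamped to zero so downstream splatting can skip empty space.
#'
#' @param spec a [toy_molecule_spec()].
#' @param oversample render at `oversample * N` with proportionally smaller
#'   voxels (same physical extent).
#' @return A [canonical_volume].
#' @export
make_toy_volume <- function(spec, oversample = 1) {
  N <- spec$N * oversample
  vox <- spec$voxel_size / oversample
  grid1 <- seq_len(N) - 1
  V <- array(0, dim = c(N, N, N))
  for (bi in seq_len(nrow(spec$blobs))) {
    b <- spec$blobs[bi, ]
    ctr <- b[1:3] * oversample
    sg <- b["sigma"] * oversample
    lo <- pmax(floor(ctr - 5 * sg), 0); hi <- pmin(ceiling(ctr + 5 * sg), N - 1)
    ix <- (lo[1]:hi[1]); iy <- (lo[2]:hi[2]); iz <- (lo[3]:hi[3])
    gx <- exp(-((ix - ctr[1])^2) / (2 * sg^2))
    gy <- exp(-((iy - ctr[2])^2) / (2 * sg^2))
    gz <- exp(-((iz - ctr[3])^2) / (2 * sg^2))
    V[ix + 1, iy + 1, iz + 1] <- V[ix + 1, iy + 1, iz + 1] +
      b["amp"] * outer(outer(gx, gy), gz)
  }
  V[V < 1e-8 * max(V)] <- 0
  canonical_volume(V, vox)
}

#' True hinge deformation field
#'
#' Displacement at arbitrary canonical-frame points for latent value `z`:
#' rigid rotation of the mobile domain about the hinge axis by
#' `z * max_angle / 3`, blended to zero across the connector by a smoothstep
#' weight in the hinge-normal coordinate.  The static domain does not move
#' and the mobile core moves exactly rigidly.
#'
#' @param spec a [toy_molecule_spec()].
#' @param z_scalar latent value, `|z| <= 3`.
#' @param points `n x 3` matrix of positions in (0-based) voxel units of the
#'   spec's box.
#' @return `n x 3` matrix of displacements (voxel units).
#' @export
true_deformation <- function(spec, z_scalar, points) {
  stopifnot(abs(z_scalar) <= 3)
  points <- matrix(points, ncol = 3)
  angle <- z_scalar * spec$max_angle / 3
  R <- rotation_about_axis(spec$hinge_axis, angle)
  rel <- sweep(points, 2, spec$hinge_point)
  disp <- rel %*% (t(R) - diag(3))
  tt <- (points[, 1] - spec$blend_x[1]) / diff(spec$blend_x)
  tt <- pmin(pmax(tt, 0), 1)
  w <- tt^2 * (3 - 2 * tt)
  disp * w
}

# dense true displacement field on an oversampled grid (internal)
true_deformation_grid <- function(spec, z_scalar, oversample) {
  N <- spec$N * oversample
  g1 <- (seq_len(N) - 1) / oversample
  pts <- cbind(rep(g1, times = N * N),
               rep(rep(g1, each = N), times = N),
               rep(g1, each = N * N))
  d <- true_deformation(spec, z_scalar, pts) * oversample
  list(dx = array(d[, 1], dim = c(N, N, N)),
       dy = array(d[, 2], dim = c(N, N, N)),
       dz = array(d[, 3], dim = c(N, N, N)))
}

# uniform random rotation matrices via unit quaternions
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Recover ZYZ Euler angles (degrees) from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; used when writing metadata.
#'
#' @param R 3 x 3 rotation matrix.
#' @return c(rot, tilt, psi) in degrees.
#' @export
matrix_to_euler <- function(R) {
  tilt <- acos(min(max(R[3, 3], -1), 1))
  if (abs(sin(tilt)) < 1e-9) {
    rot <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(rot, tilt, psi) * 180 / pi
}

#' Simulate a flexible-particle dataset with known ground truth
#'
#' Latents are standard normal (clamped to `[-3, 3]`), poses uniform over
#' SO(3) (or restricted), defoci uniform in `ctf_range`.  Clean images are
#' rendered through the true analytic deformation (not the mesh
#' approximation) at twice the training box and Fourier-cropped down, so the
#' fitted discretization never exactly matches the simulator's.  White
#' Gaussian noise is scaled so that the ratio of masked clean-signal variance
#' to noise variance at the training box equals `snr`.
#'
#' @param spec a [toy_molecule_spec()].
#' @param M number of particles.
#' @param snr target signal-to-noise ratio at the training box.
#' @param ctf_range defocus range in Angstrom (underfocus positive).
#' @param pose_mode `"uniform"` over SO(3), or `"equatorial"` (tilt fixed at
#'   90 degrees; side views that keep the hinge swing in-plane).
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @param shift_range_A in-plane shifts drawn uniformly within this radius.
#' @param voltage,cs,amplitude_contrast microscope parameters.
#' @return A `simulated_dataset`: `particles` (training box), `particles_full`
#'   (2x box), `truth` (canonical maps, true latents, noise sigma, spec) and
#'   `euler` (the metadata angles).
#' @export
generate_dataset <- function(spec, M = 2000L, snr = 0.5,
                             ctf_range = c(8000, 20000),
                             pose_mode = c("uniform", "equatorial"),
                             seed = 1L, shift_range_A = 2,
                             voltage = 300, cs = 2.7,
                             amplitude_contrast = 0.07) {
  stopifnot(M >= 1, snr > 0)
  pose_mode <- match.arg(pose_mode)
  set.seed(seed)
  os <- 2L
  N_lo <- spec$N
  N_hi <- os * N_lo
  vox_hi <- spec$voxel_size / os
  V_sim <- make_toy_volume(spec, oversample = os)
  z_true <- matrix(pmin(pmax(stats::rnorm(M * spec$K_true), -3), 3),
                   M, spec$K_true)
  euler <- matrix(0, M, 3)
  poses <- array(0, dim = c(3, 3, M))
  for (i in seq_len(M)) {
    R <- if (pose_mode == "uniform") random_rotation() else
      euler_to_matrix(stats::runif(1, 0, 360), 90, stats::runif(1, 0, 360))
    euler[i, ] <- matrix_to_euler(R)
    poses[, , i] <- euler_to_matrix(euler[i, 1], euler[i, 2], euler[i, 3])
  }
  shifts <- matrix(stats::runif(2 * M, -shift_range_A, shift_range_A), M, 2)
  du <- stats::runif(M, ctf_range[1], ctf_range[2])
  ctf <- data.frame(defocus_u = du,
                    defocus_v = pmax(du - stats::runif(M, 0, 500), 1),
                    astig_angle = stats::runif(M, 0, 180),
                    voltage = voltage, cs = cs,
                    amplitude_contrast = amplitude_contrast, phase_shift = 0)
  clean_hi <- array(0, dim = c(N_hi, N_hi, M))
  clean_lo <- array(0, dim = c(N_lo, N_lo, M))
  for (i in seq_len(M)) {
    fl <- true_deformation_grid(spec, z_true[i, 1], os)
    W <- cpp_convect(V_sim$data, fl$dx, fl$dy, fl$dz, 0L)
    img <- cpp_project(W, poses[, , i], shifts[i, 1] / vox_hi,
                       shifts[i, 2] / vox_hi)
    row <- ctf[i, ]; row$pixel_size <- vox_hi
    img <- apply_ctf(img, ctf_array(row, N_hi))
    clean_hi[, , i] <- img
    clean_lo[, , i] <- fourier_crop(img, N_lo)
  }
  # noise calibration: masked clean-signal variance at the training box
  sig_var <- mean(vapply(seq_len(M), function(i) {
    im <- clean_lo[, , i]
    m <- abs(im) > 0.02 * max(abs(im))
    if (sum(m) < 10) stats::var(c(im)) else stats::var(im[m])
  }, numeric(1)))
  sigma_lo <- sqrt(sig_var / snr)
  # Fourier cropping N_hi -> N_lo maps white noise of s.d. sigma to white-ish
  # noise of s.d. sigma * (N_lo - 1) / N_hi exactly (Nyquist edges zeroed)
  sigma_hi <- sigma_lo * N_hi / (N_lo - 1)
  imgs_hi <- clean_hi
  imgs_lo <- clean_lo
  for (i in seq_len(M)) {
    eta <- matrix(stats::rnorm(N_hi^2, sd = sigma_hi), N_hi, N_hi)
    imgs_hi[, , i] <- clean_hi[, , i] + eta
    imgs_lo[, , i] <- fourier_crop(imgs_hi[, , i], N_lo)
  }
  particles <- particle_set(imgs_lo, poses, shifts, ctf, spec$voxel_size)
  particles_full <- particle_set(imgs_hi, poses, shifts, ctf, vox_hi)
  structure(list(
    particles = particles, particles_full = particles_full, euler = euler,
    truth = list(volume = make_toy_volume(spec), volume_sim = V_sim,
                 z_true = z_true, noise_sigma = sigma_lo,
                 noise_sigma_full = sigma_hi, spec = spec, seed = seed,
                 clean_var = sig_var)),
    class = "simulated_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits the same MRCS + metadata formats the readers consume, plus a
#' ground-truth sidecar (true latents as CSV, canonical map as MRC).
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_particles(ds$particles, file.path(dir, "particles.csv"), ds$euler,
                  stack_path = file.path(dir, "particles.mrcs"))
  write_volume(ds$truth$volume, file.path(dir, "ground_truth_map.mrc"))
  write_latents(ds$truth$z_true, file.path(dir, "ground_truth_latents.csv"))
  jsonlite::write_json(list(noise_sigma = ds$truth$noise_sigma,
                            seed = ds$truth$seed,
                            N = ds$truth$spec$N,
                            voxel_size = ds$truth$spec$voxel_size),
                       file.path(dir, "ground_truth_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
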