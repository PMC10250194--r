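# The differentiable generative pipeline: convect the canonical map by a
# dense flow, project along a pose, CTF-modulate, and evaluate the white-noise
# data likelihood.  Adjoints of every stage give exact gradients with respect
# to the map, the generator parameters and the latents.

KERNELS <- c(trilinear = 0L, tricubic = 1L)

# sparse per-voxel displacement from per-vertex displacement
flow_sparse <- function(mesh, vertex_displacements) {
  dd <- as.matrix(mesh$P %*% vertex_displacements)
  list(idx0 = as.integer(mesh$assignment$voxel_index - 1L), d = dd)
}

#' Convect a canonical map by a dense displacement field
#'
#' Forward splatting: every source voxel `y` deposits its density at
#' `u(y) = y + d(y)` through the interpolation kernel, which conserves total
#' mass whenever all mapped positions stay inside the grid (exactly so for
#' the trilinear kernel).
#'
#' @param volume a [canonical_volume].
#' @param flow list of `N^3` arrays `dx`, `dy`, `dz` (voxel units), e.g. from
#'   [interpolate_flow()].
#' @param kernel `"trilinear"` (default; exactly mass-conserving) or
#'   `"tricubic"` (Keys a = -0.5; smoother gradients).
#' @return The convected [canonical_volume].
#' @export
convect <- function(volume, flow, kernel = c("trilinear", "tricubic")) {
  kernel <- KERNELS[[match.arg(kernel)]]
  N <- box_size(volume)
  mx <- max(abs(flow$dx), abs(flow$dy), abs(flow$dz))
  if (mx > N / 2)
    stop("divergent model: displacement magnitude ", round(mx, 2),
         " exceeds N/2")
  W <- cpp_convect(volume$data, flow$dx, flow$dy, flow$dz, kernel)
  canonical_volume(W, volume$voxel_size, bandlimit = volume$bandlimit)
}

#' Project a volume along a pose
#'
#' Real-space rotate-then-sum: the volume is resampled into the microscope
#' frame (trilinear, zero outside the grid), summed along the optical axis,
#' and shifted in-plane.  A constant volume of value `c` projects to `N c`
#' per interior pixel.
#'
#' @param volume a [canonical_volume] or a raw N x N x N array.
#' @param rotation 3 x 3 rotation matrix mapping canonical to microscope
#'   coordinates.
#' @param shift_px length-2 in-plane shift in pixels.
#' @param interp resampling interpolant: `"trilinear"` (default; pairs
#'   exactly with the backprojection adjoint used in training) or
#'   `"tricubic"` (Keys; much flatter frequency response, for
#'   spectral-fidelity work).
#' @return N x N image matrix (first index along +x).
#' @export
project <- function(volume, rotation, shift_px = c(0, 0),
                    interp = c("trilinear", "tricubic")) {
  W <- if (inherits(volume, "canonical_volume")) volume$data else volume
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("pose is not orthonormal")
  if (match.arg(interp) == "tricubic")
    cpp_project_cubic(W, rotation, shift_px[1], shift_px[2])
  else cpp_project(W, rotation, shift_px[1], shift_px[2])
}

#' Predict one particle image under the generative model
#'
#' Composition `apply_ctf( project( convect( V, flow(z) ) ) )` where the flow
#' is the mesh interpolation of the generator output at `z`.  With
#' `fused = TRUE` (default) convection and projection run as a single
#' operator and the convected map is never materialized; both paths give
#' identical results.
#'
#' @param volume canonical map.
#' @param theta flow generator.
#' @param z latent coordinate vector.
#' @param mesh tetra mesh.
#' @param rotation,shift_px pose (see [project()]).
#' @param ctf [ctf_params()] record or precomputed CTF array.
#' @param kernel convection kernel.
#' @param fused use the fused convect-project operator.
#' @param zero_mask_vertices optional logical vector marking vertices whose
#'   displacement is forced to zero.
#' @return N x N predicted image.
#' @export
predict_image <- function(volume, theta, z, mesh, rotation,
                          shift_px = c(0, 0), ctf = NULL,
                          kernel = c("trilinear", "tricubic"), fused = TRUE,
                          zero_mask_vertices = NULL) {
  kern <- KERNELS[[match.arg(kernel)]]
  vd <- generate_flows(theta, z)[1, , ]
  if (!is.null(zero_mask_vertices)) vd[zero_mask_vertices, ] <- 0
  sp <- flow_sparse(mesh, vd)
  img <- if (fused) {
    cpp_predict_sparse(volume$data, sp$idx0, sp$d, rotation,
                       shift_px[1], shift_px[2], kern)
  } else {
    W <- cpp_convect_sparse(volume$data, sp$idx0, sp$d, kern)
    cpp_project(W, rotation, shift_px[1], shift_px[2])
  }
  if (!is.null(ctf)) img <- apply_ctf(img, ctf)
  img
}

#' White-noise data energy of a particle batch
#'
#' `E_data = 0.5 * sum_i || I_i - C_i P(phi_i) D(f_theta(z_i), V) ||^2`.
#'
#' @param particles a [particle_set] (slice).
#' @param volume canonical map.
#' @param theta flow generator.
#' @param z_batch `M x K` latent matrix.
#' @param mesh tetra mesh.
#' @inheritParams predict_image
#' @return Scalar energy.
#' @export
data_energy <- function(particles, volume, theta, z_batch, mesh,
                        kernel = "trilinear", zero_mask_vertices = NULL) {
  M <- n_particles(particles)
  ctfs <- ctf_cache(particles)
  E <- 0
  for (i in seq_len(M)) {
    pred <- predict_image(volume, theta, z_batch[i, , drop = FALSE], mesh,
                          particles$poses[, , i],
                          particles$shifts[i, ] / particles$pixel_size,
                          ctfs[[i]], kernel = kernel,
                          zero_mask_vertices = zero_mask_vertices)
    E <- E + 0.5 * sum((particles$images[, , i] - pred)^2)
  }
  E
}

# precompute per-particle CTF arrays
ctf_cache <- function(particles) {
  N <- dim(particles$images)[1]
  lapply(seq_len(n_particles(particles)), function(i) {
    row <- particles$ctf[i, ]
    row$pixel_size <- particles$pixel_size
    ctf_array(row, N)
  })
}

#' Full loss and exact gradients for a particle batch
#'
#' Evaluates `L = E_data + lambda E_rigid + E_prior` and its analytic
#' gradients with respect to the canonical map `V`, the generator parameters
#' and the latent coordinates, by hand-derived backpropagation through CTF
#' (self-adjoint), projection (backprojection adjoint), convection (kernel
#' adjoint) and the mesh interpolation and MLP.
#'
#' @inheritParams data_energy
#' @param lambda rigidity regularization weight.
#' @param want character subset of `c("V", "theta", "z")` selecting which
#'   gradients to compute.
#' @param ctfs optional precomputed list of CTF arrays (from the internal
#'   cache) to avoid recomputation across calls.
#' @param base_projs optional list of cached rigid projections `P(V)` per
#'   particle (valid while `V` is fixed); activates an exact fast path when
#'   the map gradient is not requested.
#' @param kernel convection kernel name.
#' @return list with energies (`E_data`, `E_rigid`, `E_prior`, `total`) and
#'   requested gradients (`gV` array, `gtheta` list, `gz` matrix).
#' @export
loss_and_gradients <- function(particles, volume, theta, z_batch, mesh,
                               lambda = 2, kernel = "trilinear",
                               want = c("V", "theta", "z"),
                               zero_mask_vertices = NULL, ctfs = NULL,
                               base_projs = NULL) {
  kern <- KERNELS[[match.arg(kernel, c("trilinear", "tricubic"))]]
  M <- n_particles(particles)
  n_v <- nrow(mesh$vertices)
  if (is.null(ctfs)) ctfs <- ctf_cache(particles)
  need_theta <- "theta" %in% want
  need_V <- "V" %in% want
  need_z <- "z" %in% want
  need_disp <- need_theta || need_z
  ff <- flow_forward(theta, z_batch)
  disp <- array(ff$out, dim = c(M, n_v, 3))
  if (!is.null(zero_mask_vertices)) disp[, zero_mask_vertices, ] <- 0
  E_data <- 0
  gV <- if (need_V) array(0, dim = dim(volume$data)) else NULL
  gdisp <- if (need_disp) array(0, dim = c(M, n_v, 3)) else NULL
  shifts_px <- particles$shifts / particles$pixel_size
  idx0 <- as.integer(mesh$assignment$voxel_index - 1L)
  # With a cached base projection P(V) the forward pass only projects the
  # sparse convection correction, and (when the map gradient is not needed)
  # backprojection can be clipped to the mesh support: the convection
  # adjoint only reads the backprojected field there.  Both are exact.
  use_base <- !is.null(base_projs) && !need_V
  if (use_base) {
    lo_box <- mesh$support_lo; hi_box <- mesh$support_hi
    if (is.null(lo_box)) { lo_box <- rep(0, 3); hi_box <- rep(mesh$N - 1, 3) }
  }
  for (i in seq_len(M)) {
    sp_d <- as.matrix(mesh$P %*% disp[i, , ])
    R <- particles$poses[, , i]
    if (use_base) {
      pad <- ceiling(max(abs(sp_d), 1)) + 2
      lo <- pmax(lo_box - pad, 0); hi <- pmin(hi_box + pad, mesh$N - 1)
      delta <- cpp_delta_splat(volume$data, idx0, sp_d, kern)
      pred <- base_projs[[i]] +
        cpp_project_box(delta, R, shifts_px[i, 1], shifts_px[i, 2], lo, hi)
    } else {
      pred <- cpp_predict_sparse(volume$data, idx0, sp_d, R,
                                 shifts_px[i, 1], shifts_px[i, 2], kern)
    }
    pred <- apply_ctf(pred, ctfs[[i]])
    r <- pred - particles$images[, , i]
    E_data <- E_data + 0.5 * sum(r^2)
    g_img <- apply_ctf(r, ctfs[[i]])          # CTF is self-adjoint
    gW <- if (use_base) {
      cpp_backproject_box(g_img, R, shifts_px[i, 1], shifts_px[i, 2],
                          box_size(volume), lo, hi)
    } else {
      cpp_backproject(g_img, R, shifts_px[i, 1], shifts_px[i, 2],
                      box_size(volume))
    }
    adj <- cpp_convect_adjoint_sparse(gW, idx0, sp_d, volume$data,
                                      need_V, need_disp, kern)
    if (need_V) gV <- gV + adj$gV
    if (need_disp) {
      gvert <- as.matrix(Matrix::crossprod(mesh$P, adj$gd))
      gdisp[i, , ] <- gvert
    }
  }
  rig <- rigidity_energy(mesh, disp, gradient = need_disp)
  E_prior <- latent_prior_energy(z_batch)
  out <- list(E_data = E_data, E_rigid = rig$energy,
              E_prior = E_prior,
              total = E_data + lambda * rig$energy + E_prior,
              cell_nonrigidity = rig$cell_nonrigidity)
  if (need_disp) {
    gd_total <- gdisp + lambda * rig$grad
    if (!is.null(zero_mask_vertices)) gd_total[, zero_mask_vertices, ] <- 0
    g_out <- gd_total
    dim(g_out) <- c(M, 3L * n_v)
    bw <- flow_backward(theta, ff, g_out)
    if (need_theta) out$gtheta <- list(layers = bw$layers, W_out = bw$W_out)
    if (need_z) out$gz <- bw$Z + z_batch   # + prior gradient
  }
  if (need_V) out$gV <- gV
  out
}
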