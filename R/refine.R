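# High-resolution canonical-map recovery under frozen motion, Fourier shell
# correlation, Cn symmetrization and convected-map series.

# scale a mesh (vertices, grid) by an integer or rational factor, e.g. from
# the training box N_L to the full box N_H; displacements in voxel units
# scale by the same factor (the physical deformation is scale-invariant).
rescale_mesh <- function(mesh, factor) {
  tetra_mesh(mesh$vertices * factor, mesh$cells,
             as.integer(round(mesh$N * factor)), mesh$voxel_size / factor,
             element_weights = mesh$element_weights)
}

# one application of H = sum_i S_i' P_i' C_i^2 P_i S_i  (the normal operator
# of the frozen-motion least-squares problem), plus the RHS builder.
recon_operator <- function(particles, vd_list, mesh, kern, ctfs2) {
  N <- dim(particles$images)[1]
  shifts_px <- particles$shifts / particles$pixel_size
  idx0 <- as.integer(mesh$assignment$voxel_index - 1L)
  M <- n_particles(particles)
  apply_H <- function(x) {
    out <- array(0, dim = c(N, N, N))
    for (i in seq_len(M)) {
      sp_d <- if (is.null(vd_list)) NULL else
        as.matrix(mesh$P %*% vd_list[[i]])
      R <- particles$poses[, , i]
      Wx <- if (is.null(sp_d)) x else cpp_convect_sparse(x, idx0, sp_d, kern)
      img <- cpp_project(Wx, R, shifts_px[i, 1], shifts_px[i, 2])
      img <- Re(stats::fft(stats::fft(img) * ctfs2[[i]], inverse = TRUE)) / N^2
      bp <- cpp_backproject(img, R, shifts_px[i, 1], shifts_px[i, 2], N)
      out <- out + if (is.null(sp_d)) bp else
        cpp_convect_adjoint_sparse(bp, idx0, sp_d, x, TRUE, FALSE, kern)$gV
    }
    out
  }
  rhs <- function(ctfs1) {
    out <- array(0, dim = c(N, N, N))
    for (i in seq_len(M)) {
      R <- particles$poses[, , i]
      img <- particles$images[, , i]
      img <- Re(stats::fft(stats::fft(img) * ctfs1[[i]], inverse = TRUE)) / N^2
      bp <- cpp_backproject(img, R, shifts_px[i, 1], shifts_px[i, 2], N)
      out <- out + if (is.null(vd_list)) bp else {
        sp_d <- as.matrix(mesh$P %*% vd_list[[i]])
        cpp_convect_adjoint_sparse(bp, idx0, sp_d, bp, TRUE, FALSE, kern)$gV
      }
    }
    out
  }
  list(apply_H = apply_H, rhs = rhs)
}

#' High-resolution half-map reconstruction by full-batch L-BFGS
#'
#' With the flow generator and latents frozen, the data energy is exactly
#' quadratic in the canonical map `V`.  Starting from `V = 0`, limited-memory
#' BFGS (memory 10) minimizes
#' `sum_i 0.5 || I_i - C_i P(phi_i) D(f_theta(z_i), V) ||^2`
#' in real space over a particle half-set; because the objective is
#' quadratic, each iteration uses the exact line search
#' `alpha = -g.p / p.Hp`, costing one operator pass over the data.
#' Iterations stop when the gradient norm has dropped by `grad_tol` (1e3 by
#' default) or at `max_iters`.
#'
#' @param particles [particle_set] at the full box size `N_H` (a half-set).
#' @param theta frozen flow generator, trained at box `N_L`; pass `NULL` for
#'   a rigid reconstruction.
#' @param z frozen `M x K` latents (ignored when `theta` is `NULL`).
#' @param mesh the training mesh at box `N_L`; it is rescaled to `N_H`
#'   internally.
#' @param N_L training box size (to derive the mesh/flow rescaling factor).
#' @param max_iters L-BFGS iteration cap (default 200).
#' @param grad_tol stop when `||g||` has dropped by this factor.
#' @param ridge optional Tikhonov damping: adds `0.5 * ridge * ||V||^2` to
#'   the objective, making the minimizer unique when the views cannot
#'   determine every frequency (default 0).
#' @param kernel convection kernel.
#' @param zero_mask_vertices vertices pinned to zero displacement.
#' @param verbose print iteration diagnostics.
#' @return A [canonical_volume] half-map.
#' @export
reconstruct_highres <- function(particles, theta, z, mesh, N_L,
                                max_iters = 200L, grad_tol = 1e3,
                                kernel = "trilinear", ridge = 0,
                                zero_mask_vertices = NULL, verbose = FALSE) {
  kern <- KERNELS[[match.arg(kernel, c("trilinear", "tricubic"))]]
  N <- dim(particles$images)[1]
  factor <- N / N_L
  M <- n_particles(particles)
  rigid <- is.null(theta)
  vd_list <- NULL
  mesh_h <- mesh
  if (!rigid) {
    mesh_h <- if (factor != 1) rescale_mesh(mesh, factor) else mesh
    flows <- generate_flows(theta, z)
    vd_list <- lapply(seq_len(M), function(i) {
      vd <- flows[i, , ] * factor
      if (!is.null(zero_mask_vertices)) vd[zero_mask_vertices, ] <- 0
      vd
    })
  }
  ctfs <- ctf_cache(particles)
  ctfs2 <- lapply(ctfs, function(C) C * C)
  op <- recon_operator(particles, vd_list, mesh_h, kern, ctfs2)
  b <- op$rhs(ctfs)
  # L-BFGS two-loop recursion with exact quadratic step
  V <- array(0, dim = c(N, N, N))
  g <- -b                       # gradient of 0.5 V'HV - b'V at V = 0
  g0n <- sqrt(sum(g^2))
  if (g0n == 0) return(canonical_volume(V, particles$pixel_size))
  S <- list(); Y <- list(); rho <- numeric(0)
  mem <- 10L
  for (it in seq_len(max_iters)) {
    q <- g
    k <- length(S)
    alpha <- numeric(k)
    if (k > 0) {
      for (j in k:1) {
        alpha[j] <- rho[j] * sum(S[[j]] * q)
        q <- q - alpha[j] * Y[[j]]
      }
      gamma <- sum(S[[k]] * Y[[k]]) / sum(Y[[k]] * Y[[k]])
      q <- gamma * q
      for (j in 1:k) {
        beta <- rho[j] * sum(Y[[j]] * q)
        q <- q + (alpha[j] - beta) * S[[j]]
      }
    }
    p <- -q
    Hp <- op$apply_H(p)
    if (ridge > 0) Hp <- Hp + ridge * p
    pHp <- sum(p * Hp)
    if (pHp <= 0) break                     # flat/null direction: done
    step <- -sum(g * p) / pHp               # exact minimizer along p
    if (!is.finite(step) || step == 0) break
    s <- step * p
    y <- step * Hp
    V <- V + s
    g <- g + y
    if (length(S) == mem) { S <- S[-1]; Y <- Y[-1]; rho <- rho[-1] }
    S <- c(S, list(s)); Y <- c(Y, list(y))
    rho <- c(rho, 1 / sum(s * y))
    gn <- sqrt(sum(g^2))
    if (verbose)
      message(sprintf("  lbfgs iter %3d  |g|/|g0| = %.3e", it, gn / g0n))
    if (gn <= g0n / grad_tol) break
  }
  if (any(!is.finite(V))) stop("non-finite objective in reconstruction")
  canonical_volume(V, particles$pixel_size)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the spectra; optionally both
#' volumes are multiplied by a real-space mask first.  Resolutions are the
#' first crossings of the 0.5 and 0.143 thresholds (linear interpolation
#' between shells).
#'
#' @param V_a,V_b [canonical_volume]s of identical shape and voxel size.
#' @param mask optional [mask_volume].
#' @return Data frame (class `fsc_curve`) with `shell`, `frequency` (1/A)
#'   and `fsc`; resolution estimates are attached as attributes
#'   `resolution_0.5` and `resolution_0.143` (Angstrom, `Inf` if never
#'   crossed... `NA` if crossed nowhere in band).
#' @export
fsc <- function(V_a, V_b, mask = NULL) {
  if (!all(dim(V_a$data) == dim(V_b$data)))
    stop("volume shape mismatch")
  N <- box_size(V_a)
  a <- V_a$data; b <- V_b$data
  if (!is.null(mask)) { a <- a * mask$data; b <- b * mask$data }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  shell <- as.integer(round(freq_radius_grid(N)))
  keep <- shell <= N / 2
  num <- Re(Fa * Conj(Fb))
  pa <- Mod(Fa)^2; pb <- Mod(Fb)^2
  sn <- tapply(num[keep], shell[keep], sum)
  sa <- tapply(pa[keep], shell[keep], sum)
  sb <- tapply(pb[keep], shell[keep], sum)
  s <- as.integer(names(sn))
  corr <- ifelse(sa > 0 & sb > 0, sn / sqrt(sa * sb), NA_real_)
  df <- data.frame(shell = s, frequency = s / (N * V_a$voxel_size),
                   fsc = as.numeric(corr))
  df <- df[order(df$shell), ]
  attr(df, "resolution_0.5") <- fsc_resolution(df, 0.5)
  attr(df, "resolution_0.143") <- fsc_resolution(df, 0.143)
  class(df) <- c("fsc_curve", "data.frame")
  df
}

# first crossing of the threshold, linearly interpolated between shells
fsc_resolution <- function(df, threshold) {
  v <- df$fsc; f <- df$frequency
  ok <- !is.na(v)
  v <- v[ok]; f <- f[ok]
  below <- which(v < threshold)
  below <- below[below > 1]
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  f_cross <- f[i - 1] + (f[i] - f[i - 1]) *
    (v[i - 1] - threshold) / (v[i - 1] - v[i])
  1 / f_cross
}

#' Write an FSC curve as CSV
#' @param curve an `fsc_curve`.
#' @param path output CSV.
#' @export
write_fsc <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Cn symmetrization of a volume
#'
#' Averages the map over the n-fold rotation group about an axis through the
#' box center (trilinear resampling).  Used post hoc on half-maps when the
#' canonical density is symmetric and only the motion breaks symmetry.
#'
#' @param volume a [canonical_volume].
#' @param n symmetry order (n >= 1).
#' @param axis rotation axis (default z).
#' @return The symmetrized [canonical_volume].
#' @export
symmetrize_cn <- function(volume, n, axis = c(0, 0, 1)) {
  stopifnot(n >= 1)
  if (n == 1) return(volume)
  axis <- axis / sqrt(sum(axis^2))
  acc <- volume$data
  for (k in seq_len(n - 1)) {
    R <- rotation_about_axis(axis, 2 * pi * k / n)
    acc <- acc + cpp_rotate_volume(volume$data, R)
  }
  canonical_volume(acc / n, volume$voxel_size, bandlimit = volume$bandlimit)
}

# Rodrigues rotation matrix
rotation_about_axis <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Convected-map series along latent points
#'
#' Materializes the convected density `W = D(f_theta(z), V)` at each
#' requested latent point (the explicit-W path), e.g. for rendering a motion
#' trajectory across the conformational landscape.
#'
#' @param volume canonical map.
#' @param theta flow generator.
#' @param mesh tetra mesh.
#' @param z_points rows = latent points.
#' @param kernel convection kernel.
#' @param zero_mask_vertices vertices pinned to zero displacement.
#' @return List of [canonical_volume]s, one per latent point.
#' @export
convected_series <- function(volume, theta, mesh, z_points,
                             kernel = "trilinear",
                             zero_mask_vertices = NULL) {
  z_points <- if (is.null(dim(z_points))) matrix(z_points, ncol = theta$K)
              else as.matrix(z_points)
  kern <- KERNELS[[match.arg(kernel, c("trilinear", "tricubic"))]]
  idx0 <- as.integer(mesh$assignment$voxel_index - 1L)
  lapply(seq_len(nrow(z_points)), function(i) {
    vd <- generate_flows(theta, z_points[i, , drop = FALSE])[1, , ]
    if (!is.null(zero_mask_vertices)) vd[zero_mask_vertices, ] <- 0
    sp_d <- as.matrix(mesh$P %*% vd)
    W <- cpp_convect_sparse(volume$data, idx0, sp_d, kern)
    canonical_volume(W, volume$voxel_size)
  })
}
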