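# Model fitting: minibatch block coordinate descent over the canonical map V,
# the flow generator theta and per-particle latents z, with auto-decoder
# latent inference, frequency marching and latent noise injection.

#' Training configuration
#'
#' @param lambda_rigid weight of the local-rigidity penalty (default 2.0,
#'   useful range roughly 0.5-5).
#' @param batch_size minibatch size; at least 500 is recommended because of
#'   the high image noise (a warning is issued below that).
#' @param optimizer `"adam"` or `"sgd_nesterov"` for the generator update.
#' @param lr_theta learning rate for the generator.
#' @param theta_steps_per_batch gradient steps on theta per minibatch visit.
#' @param lr_V learning rate for the map update, relative to the standard
#'   deviation of the initial map (the absolute rate is `lr_V * sd(V0)`).
#' @param V_steps_per_batch gradient steps on the map per minibatch visit
#'   during map-update epochs.
#' @param n_epochs total epoch budget.
#' @param warmup_epochs epochs of (theta, z) updates with V fixed (theta-only
#'   if latents were supplied externally); default 5.
#' @param freq_start,freq_end,freq_ramp frequency-marching schedule: band
#'   limit shell at epoch 0, final shell, and the number of epochs over which
#'   the limit ramps linearly.  Defaults: `N/8`, `N/2`, half of `n_epochs`.
#' @param latent_method `"coordinate_descent"` (default) or `"gradient"`.
#' @param cd_cycles,cd_steps coordinate-descent cycles per inference and
#'   golden-section steps per latent dimension.
#' @param latent_noise_start,latent_noise_end noise-injection s.d. at the
#'   first and last epoch (linear decay); applied only during generator
#'   updates.
#' @param K,n_layers,hidden,init_scale flow generator architecture.
#' @param kernel convection kernel.
#' @param early_stop_tol,early_stop_patience stop when the relative epoch
#'   loss improvement is below `early_stop_tol` this many times in a row.
#' @param seed RNG seed; fits are fully reproducible given the seed.
#' @export
train_config <- function(lambda_rigid = 2, batch_size = 500,
                         optimizer = c("adam", "sgd_nesterov"),
                         lr_theta = 3e-3, theta_steps_per_batch = 4L,
                         lr_V = 0.1, V_steps_per_batch = 4L,
                         n_epochs = 40L, warmup_epochs = 5L,
                         freq_start = NULL, freq_end = NULL, freq_ramp = NULL,
                         latent_method = c("coordinate_descent", "gradient"),
                         cd_cycles = 2L, cd_steps = 8L,
                         latent_noise_start = 0.1, latent_noise_end = 0.02,
                         K = 2L, n_layers = 6L, hidden = 64L,
                         init_scale = 1e-2, kernel = "trilinear",
                         early_stop_tol = 1e-4, early_stop_patience = 3L,
                         seed = 1L) {
  stopifnot(lambda_rigid > 0, batch_size >= 1)
  if (batch_size < 500)
    warning("batch_size below 500; gradient estimates may be noisy")
  list(lambda_rigid = lambda_rigid, batch_size = as.integer(batch_size),
       optimizer = match.arg(optimizer), lr_theta = lr_theta,
       theta_steps_per_batch = as.integer(theta_steps_per_batch),
       lr_V = lr_V, V_steps_per_batch = as.integer(V_steps_per_batch),
       n_epochs = as.integer(n_epochs),
       warmup_epochs = as.integer(warmup_epochs),
       freq_start = freq_start, freq_end = freq_end, freq_ramp = freq_ramp,
       latent_method = match.arg(latent_method),
       cd_cycles = as.integer(cd_cycles), cd_steps = as.integer(cd_steps),
       latent_noise_start = latent_noise_start,
       latent_noise_end = latent_noise_end,
       K = as.integer(K), n_layers = as.integer(n_layers),
       hidden = as.integer(hidden), init_scale = init_scale,
       kernel = kernel, early_stop_tol = early_stop_tol,
       early_stop_patience = as.integer(early_stop_patience),
       seed = as.integer(seed))
}

#' Frequency-marching schedule
#'
#' Linear coarse-to-fine ramp of the Fourier band-limit shell: `start` at
#' epoch 0, `end` from `ramp_epochs` onward, non-decreasing in between.
#'
#' @param epoch 0-based epoch index.
#' @param schedule list with `start`, `end`, `ramp_epochs`.
#' @return Integer shell radius.
#' @export
frequency_march <- function(epoch, schedule) {
  stopifnot(schedule$end >= schedule$start, schedule$ramp_epochs >= 0)
  frac <- if (schedule$ramp_epochs == 0) 1 else
    min(1, max(0, epoch / schedule$ramp_epochs))
  as.integer(round(schedule$start + (schedule$end - schedule$start) * frac))
}

# per-image objective used by latent inference.  Projection is linear, so
# the prediction splits as P(V) + P(Delta(z)) with P(V) cached per image and
# the flow-dependent correction Delta supported only around the mesh.
latent_objective <- function(img, volume, theta, mesh, z, R, shift_px, ctf,
                             kern, zero_mask, base_proj = NULL) {
  vd <- matrix(flow_forward(theta, matrix(z, 1))$out, ncol = 3)
  if (!is.null(zero_mask)) vd[zero_mask, ] <- 0
  sp_d <- as.matrix(mesh$P %*% vd)
  idx0 <- as.integer(mesh$assignment$voxel_index - 1L)
  pred <- if (is.null(base_proj)) {
    cpp_predict_sparse(volume$data, idx0, sp_d, R, shift_px[1], shift_px[2],
                       kern)
  } else {
    delta <- cpp_delta_splat(volume$data, idx0, sp_d, kern)
    pad <- ceiling(max(abs(sp_d))) + 2
    lo <- mesh$support_lo
    hi <- mesh$support_hi
    if (is.null(lo)) { lo <- rep(0, 3); hi <- rep(mesh$N - 1, 3) }
    base_proj + cpp_project_box(delta, R, shift_px[1], shift_px[2],
                                pmax(lo - pad, 0), pmin(hi + pad, mesh$N - 1))
  }
  pred <- apply_ctf(pred, ctf)
  0.5 * sum((img - pred)^2) + 0.5 * sum(z^2)
}

#' Auto-decoder latent inference
#'
#' Optimizes each image's latent coordinates against the frozen generative
#' model (`V`, `theta` fixed), minimizing
#' `0.5 ||I - predict(z)||^2 + 0.5 ||z||^2`.  Coordinate descent runs a
#' cyclic per-dimension golden-section line search on `[-4, 4]`; the gradient
#' method runs fixed-step descent with backtracking.  The objective never
#' increases: a candidate is accepted only if it improves on the current
#' point.
#'
#' @param particles [particle_set] slice to infer.
#' @param volume,theta,mesh frozen model.
#' @param z_init `M x K` starting latents.
#' @param method `"coordinate_descent"` or `"gradient"`.
#' @param cycles,steps coordinate-descent cycles and golden-section steps
#'   (or gradient steps for the gradient method).
#' @param ctfs optional precomputed CTF arrays.
#' @param kernel convection kernel name.
#' @param zero_mask_vertices vertices pinned to zero displacement.
#' @return `M x K` matrix of refined latents.
#' @export
infer_latents <- function(particles, volume, theta, mesh, z_init,
                          method = "coordinate_descent", cycles = 2L,
                          steps = 8L, ctfs = NULL, kernel = "trilinear",
                          zero_mask_vertices = NULL) {
  kern <- KERNELS[[match.arg(kernel, c("trilinear", "tricubic"))]]
  M <- n_particles(particles)
  K <- ncol(z_init)
  if (is.null(ctfs)) ctfs <- ctf_cache(particles)
  z <- as.matrix(z_init)
  shifts_px <- particles$shifts / particles$pixel_size
  gr <- (sqrt(5) - 1) / 2
  for (i in seq_len(M)) {
    img <- particles$images[, , i]
    R <- particles$poses[, , i]
    base_proj <- cpp_project(volume$data, R, shifts_px[i, 1], shifts_px[i, 2])
    obj <- function(zz) latent_objective(img, volume, theta, mesh, zz, R,
                                         shifts_px[i, ], ctfs[[i]], kern,
                                         zero_mask_vertices, base_proj)
    zi <- z[i, ]
    fi <- obj(zi)
    if (!is.finite(fi)) stop("non-finite latent objective for image ", i)
    if (method == "coordinate_descent") {
      for (cyc in seq_len(cycles)) {
        for (k in seq_len(K)) {
          a <- -4; b <- 4
          x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
          zk <- function(v) { zz <- zi; zz[k] <- v; zz }
          f1 <- obj(zk(x1)); f2 <- obj(zk(x2))
          best_v <- if (f1 < f2) x1 else x2
          best_f <- min(f1, f2)
          for (s in seq_len(steps)) {
            if (f1 < f2) {
              b <- x2; x2 <- x1; f2 <- f1
              x1 <- b - gr * (b - a); f1 <- obj(zk(x1))
            } else {
              a <- x1; x1 <- x2; f1 <- f2
              x2 <- a + gr * (b - a); f2 <- obj(zk(x2))
            }
            if (min(f1, f2) < best_f) {
              best_f <- min(f1, f2)
              best_v <- if (f1 < f2) x1 else x2
            }
          }
          if (best_f < fi) { zi[k] <- best_v; fi <- best_f }
        }
      }
    } else {
      lr <- 0.5
      for (s in seq_len(cycles * steps)) {
        g <- num_latent_grad(obj, zi, fi)
        step_ok <- FALSE
        for (bt in 1:8) {
          cand <- zi - lr * g
          fc <- obj(cand)
          if (fc < fi) { zi <- cand; fi <- fc; step_ok <- TRUE; break }
          lr <- lr / 2
        }
        if (!step_ok) break
      }
    }
    z[i, ] <- zi
  }
  z
}

# small central-difference gradient for the latent line search
num_latent_grad <- function(obj, z, fz, h = 1e-3) {
  g <- numeric(length(z))
  for (k in seq_along(z)) {
    zp <- z; zp[k] <- z[k] + h
    zm <- z; zm[k] <- z[k] - h
    g[k] <- (obj(zp) - obj(zm)) / (2 * h)
  }
  g
}

# vertices whose (rounded) positions fall inside a zero-deformation mask
zero_mask_from_volume <- function(mesh, zero_def_mask) {
  if (is.null(zero_def_mask)) return(NULL)
  v <- round(mesh$vertices)
  N <- dim(zero_def_mask$data)[1]
  v <- pmin(pmax(v, 0), N - 1)
  inside <- zero_def_mask$data[v[, 1] + 1 + N * (v[, 2] + N * v[, 3])] > 0.5
  if (!any(inside)) NULL else inside
}

#' Fit the deformation model to particle data
#'
#' Block coordinate descent on
#' `L = E_data + lambda E_rigid` (plus the unit-variance latent prior):
#' warmup epochs update the generator and latents with `V` fixed (generator
#' only if latents were supplied), then epochs alternate between updating `V`
#' and updating (generator, latents).  The map is kept low-pass under a
#' coarse-to-fine frequency-marching schedule, and the solvent mask (if any)
#' is re-applied after every map update.  Latent inference precedes every
#' gradient step (auto-decoder); noise is injected into the inferred latents
#' during generator updates only.
#'
#' @param particles a [particle_set] with known poses and CTFs.
#' @param V0 initial canonical map (typically a consensus reconstruction;
#'   it is low-passed to the starting band limit).
#' @param mesh a `tetra_mesh` with element weights.
#' @param config a [train_config()].
#' @param solvent_mask optional [mask_volume] multiplied into `V` after each
#'   update.
#' @param zero_def_mask optional [mask_volume]; mesh vertices inside it are
#'   pinned to zero displacement throughout.
#' @param z_init optional `M x K` initial latents (e.g. imported from a
#'   linear-subspace analysis); if given, warmup updates the generator only.
#' @param theta_init optional pre-trained generator to warm-start from (e.g.
#'   to continue a fit at a higher band limit); default is a fresh random
#'   initialization.
#' @param verbose print per-epoch losses.
#' @return A `flex_fit` object: `theta`, `latents`, `volume`, `loss_trace`
#'   data frame, `mesh`, `config`.
#' @export
train_flex <- function(particles, V0, mesh, config = train_config(),
                       solvent_mask = NULL, zero_def_mask = NULL,
                       z_init = NULL, theta_init = NULL, verbose = FALSE) {
  set.seed(config$seed)
  M <- n_particles(particles)
  N <- box_size(V0)
  stopifnot(dim(particles$images)[1] == N)
  sched <- list(start = if (is.null(config$freq_start)) max(2L, N %/% 8L)
                        else config$freq_start,
                end = if (is.null(config$freq_end)) N %/% 2L
                      else config$freq_end,
                ramp_epochs = if (is.null(config$freq_ramp))
                  max(1L, config$n_epochs %/% 2L) else config$freq_ramp)
  theta <- if (is.null(theta_init)) {
    init_generator(config$K, nrow(mesh$vertices),
                   n_layers = config$n_layers, hidden = config$hidden,
                   seed = config$seed, init_scale = config$init_scale)
  } else theta_init
  z_external <- !is.null(z_init) && is.null(theta_init)
  z <- if (!is.null(z_init)) as.matrix(z_init) else matrix(0, M, config$K)
  zero_mask <- zero_mask_from_volume(mesh, zero_def_mask)
  ctfs <- ctf_cache(particles)
  lr_V_abs <- config$lr_V * stats::sd(V0$data)
  ad_theta <- adam_init(theta_params(theta))
  ad_V <- list(m = array(0, dim(V0$data)), v = array(0, dim(V0$data)), t = 0L)
  mom_theta <- NULL  # Nesterov momentum buffer
  V <- bandlimit_volume(V0, frequency_march(0L, sched))
  trace <- data.frame()
  best <- list(theta = theta, z = z, V = V)
  stall <- 0L
  n_batches <- ceiling(M / config$batch_size)
  for (epoch in seq_len(config$n_epochs)) {
    shell <- frequency_march(epoch - 1L, sched)
    V <- bandlimit_volume(V, shell)
    warm <- epoch <= config$warmup_epochs
    phase <- if (warm) "theta_z"
             else if ((epoch - config$warmup_epochs) %% 2L == 1L) "V"
             else "theta_z"
    sigma <- config$latent_noise_start +
      (config$latent_noise_end - config$latent_noise_start) *
        (epoch - 1) / max(1, config$n_epochs - 1)
    ord <- sample.int(M)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, M)]
      batch <- subset_particles(particles, idx)
      bctfs <- ctfs[idx]
      if (phase == "theta_z") {
        shifts_px <- batch$shifts / batch$pixel_size
        base_projs <- lapply(seq_along(idx), function(k)
          cpp_project(V$data, batch$poses[, , k], shifts_px[k, 1],
                      shifts_px[k, 2]))
        if (!(warm && z_external)) {
          z[idx, ] <- infer_latents(batch, V, theta, mesh,
                                    z[idx, , drop = FALSE],
                                    method = config$latent_method,
                                    cycles = config$cd_cycles,
                                    steps = config$cd_steps, ctfs = bctfs,
                                    kernel = config$kernel,
                                    zero_mask_vertices = zero_mask)
        }
        for (s in seq_len(config$theta_steps_per_batch)) {
          zn <- inject_latent_noise(z[idx, , drop = FALSE], sigma)
          gr <- loss_and_gradients(batch, V, theta, zn, mesh,
                                   lambda = config$lambda_rigid,
                                   kernel = config$kernel, want = "theta",
                                   zero_mask_vertices = zero_mask,
                                   ctfs = bctfs, base_projs = base_projs)
          if (!is.finite(gr$total)) return(abort_fit(best, trace, epoch))
          if (config$optimizer == "adam") {
            st <- adam_step(theta_params(theta), gr$gtheta, ad_theta,
                            config$lr_theta)
            theta <- theta_restore(theta, st$params)
            ad_theta <- st$state
          } else {
            if (is.null(mom_theta))
              mom_theta <- rapply(gr$gtheta, function(x) x * 0,
                                  how = "replace", classes = "ANY")
            upd <- sgd_nesterov_step(theta_params(theta), gr$gtheta,
                                     mom_theta, config$lr_theta)
            theta <- theta_restore(theta, upd$params)
            mom_theta <- upd$mom
          }
        }
      } else {
        for (s in seq_len(config$V_steps_per_batch)) {
          gr <- loss_and_gradients(batch, V, theta, z[idx, , drop = FALSE],
                                   mesh, lambda = config$lambda_rigid,
                                   kernel = config$kernel, want = "V",
                                   zero_mask_vertices = zero_mask,
                                   ctfs = bctfs)
          if (!is.finite(gr$total)) return(abort_fit(best, trace, epoch))
          ad_V$t <- ad_V$t + 1L
          ad_V$m <- 0.9 * ad_V$m + 0.1 * gr$gV
          ad_V$v <- 0.999 * ad_V$v + 0.001 * gr$gV^2
          mh <- ad_V$m / (1 - 0.9^ad_V$t)
          vh <- ad_V$v / (1 - 0.999^ad_V$t)
          Vd <- V$data - lr_V_abs * mh / (sqrt(vh) + 1e-8)
          if (!is.null(solvent_mask)) Vd <- Vd * solvent_mask$data
          V <- canonical_volume(Vd, V$voxel_size)
          V <- bandlimit_volume(V, shell)
        }
      }
    }
    # full-dataset loss trace at the epoch's end state
    E <- epoch_energies(particles, V, theta, z, mesh, config, ctfs, zero_mask)
    trace <- rbind(trace, data.frame(
      epoch = epoch, phase = phase, shell = shell,
      E_data = E$E_data, E_rigid = E$E_rigid, E_prior = E$E_prior,
      total = E$E_data + config$lambda_rigid * E$E_rigid + E$E_prior))
    if (verbose)
      message(sprintf("epoch %2d [%7s, shell %2d] E_data=%.4g E_rigid=%.4g",
                      epoch, phase, shell, E$E_data, E$E_rigid))
    if (!is.finite(E$E_data)) return(abort_fit(best, trace, epoch))
    best <- list(theta = theta, z = z, V = V)
    nt <- nrow(trace)
    if (nt >= 2) {
      rel <- (trace$total[nt - 1] - trace$total[nt]) /
        abs(trace$total[nt - 1])
      stall <- if (rel < config$early_stop_tol) stall + 1L else 0L
      if (stall >= config$early_stop_patience && epoch > config$warmup_epochs)
        break
    }
  }
  structure(list(theta = theta, latents = z, volume = V, loss_trace = trace,
                 mesh = mesh, config = config, zero_mask = zero_mask,
                 converged = stall >= config$early_stop_patience),
            class = "flex_fit")
}

sgd_nesterov_step <- function(params, grads, mom, lr, mu = 0.9) {
  walk <- function(p, g, m) {
    if (is.list(p)) {
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m
      }
      return(list(p = p, m = m))
    }
    m_new <- mu * m - lr * g
    list(p = p + mu * m_new - lr * g, m = m_new)  # Nesterov lookahead form
  }
  r <- walk(params, grads, mom)
  list(params = r$p, mom = r$m)
}

epoch_energies <- function(particles, V, theta, z, mesh, config, ctfs,
                           zero_mask) {
  M <- n_particles(particles)
  bs <- config$batch_size
  E_data <- 0; E_rigid <- 0
  for (bi in seq_len(ceiling(M / bs))) {
    idx <- ((bi - 1) * bs + 1):min(bi * bs, M)
    gr <- loss_and_gradients(subset_particles(particles, idx), V, theta,
                             z[idx, , drop = FALSE], mesh,
                             lambda = config$lambda_rigid,
                             kernel = config$kernel, want = character(0),
                             zero_mask_vertices = zero_mask,
                             ctfs = ctfs[idx])
    E_data <- E_data + gr$E_data
    E_rigid <- E_rigid + gr$E_rigid
  }
  list(E_data = E_data, E_rigid = E_rigid, E_prior = latent_prior_energy(z))
}

abort_fit <- function(best, trace, epoch) {
  warning("non-finite loss at epoch ", epoch,
          "; returning last finite checkpoint")
  structure(list(theta = best$theta, latents = best$z, volume = best$V,
                 loss_trace = trace, diverged = TRUE),
            class = "flex_fit")
}

#' @export
print.flex_fit <- function(x, ...) {
  nt <- nrow(x$loss_trace)
  cat(sprintf("<flex_fit> %d epochs, final E_data = %.6g, E_rigid = %.6g\n",
              nt, x$loss_trace$E_data[nt], x$loss_trace$E_rigid[nt]))
  invisible(x)
}

#' Save / load a fitted model checkpoint (JSON)
#'
#' Stores the generator weights, latents, canonical map and config; arrays
#' are written losslessly as JSON numbers.
#'
#' @param fit a `flex_fit`.
#' @param path output path.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(
    theta = list(K = fit$theta$K, n_v = fit$theta$n_v,
                 hidden = fit$theta$hidden, n_layers = fit$theta$n_layers,
                 seed = fit$theta$seed, init_scale = fit$theta$init_scale,
                 layers = lapply(fit$theta$layers, function(l)
                   list(W = as.numeric(l$W), dim_W = dim(l$W), b = l$b)),
                 W_out = as.numeric(fit$theta$W_out),
                 dim_W_out = dim(fit$theta$W_out)),
    latents = as.numeric(fit$latents), dim_latents = dim(fit$latents),
    volume = as.numeric(fit$volume$data), N = box_size(fit$volume),
    voxel_size = fit$volume$voxel_size,
    bandlimit = if (is.finite(fit$volume$bandlimit)) fit$volume$bandlimit
                else -1,
    loss_trace = fit$loss_trace, config = fit$config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  th <- j$theta
  theta <- structure(list(
    layers = lapply(th$layers, function(l)
      list(W = matrix(l$W, l$dim_W[1], l$dim_W[2]), b = l$b)),
    W_out = matrix(th$W_out, th$dim_W_out[1], th$dim_W_out[2]),
    K = th$K, n_v = th$n_v, hidden = th$hidden, n_layers = th$n_layers,
    seed = th$seed, init_scale = th$init_scale), class = "flow_generator")
  vol <- canonical_volume(array(j$volume, dim = rep(j$N, 3)), j$voxel_size,
                          bandlimit = if (j$bandlimit < 0) Inf else j$bandlimit)
  structure(list(theta = theta,
                 latents = matrix(j$latents, j$dim_latents[1],
                                  j$dim_latents[2]),
                 volume = vol,
                 loss_trace = if (length(j$loss_trace))
                   do.call(rbind, lapply(j$loss_trace, as.data.frame))
                 else NULL,
                 config = j$config), class = "flex_fit")
}
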