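# The flow generator: a small fully connected network (ReLU hidden layers,
# bias-free linear output) mapping a K-dimensional latent coordinate to one
# 3-vector displacement per mesh vertex.  Forward and backward passes are
# plain matrix algebra; gradients are hand-derived.

#' Initialize the flow generator
#'
#' An `n_layers`-layer MLP with `hidden` units per hidden layer and ReLU
#' activations; the final layer is linear without biases, and its weights are
#' scaled by `init_scale` so training starts near the identity deformation.
#' Hidden layers use He initialization.
#'
#' @param K latent dimension (>= 1; 2 by default for the conformational
#'   landscape).
#' @param n_v number of mesh vertices.
#' @param n_layers total layer count (default 6).
#' @param hidden hidden width (default 64).
#' @param seed RNG seed; identical seeds give identical parameters.
#' @param init_scale multiplier on the final-layer weights (default 1e-2).
#' @return An object of class `flow_generator`.
#' @export
init_generator <- function(K, n_v, n_layers = 6L, hidden = 64L, seed = 1L,
                           init_scale = 1e-2) {
  stopifnot(K >= 1, n_layers >= 1, hidden >= 1, n_v >= 1)
  rng <- local({ set.seed(seed)
    function(n, sd) stats::rnorm(n, sd = sd) })
  layers <- list()
  fan_in <- K
  if (n_layers > 1) {
    for (l in seq_len(n_layers - 1L)) {
      layers[[l]] <- list(W = matrix(rng(hidden * fan_in, sqrt(2 / fan_in)),
                                     hidden, fan_in),
                          b = numeric(hidden))
      fan_in <- hidden
    }
  }
  W_out <- matrix(rng(3 * n_v * fan_in, sqrt(2 / fan_in)) * init_scale,
                  3 * n_v, fan_in)
  structure(list(layers = layers, W_out = W_out, K = K, n_v = n_v,
                 hidden = hidden, n_layers = n_layers, seed = seed,
                 init_scale = init_scale),
            class = "flow_generator")
}

#' @export
print.flow_generator <- function(x, ...) {
  cat(sprintf("<flow_generator> K = %d -> %d layers x %d units -> %d vertices\n",
              x$K, x$n_layers, x$hidden, x$n_v))
  invisible(x)
}

# forward pass keeping pre-activations for backprop; Z is B x K
flow_forward <- function(theta, Z) {
  Z <- matrix(Z, ncol = theta$K)
  acts <- list(Z)
  h <- Z
  for (l in seq_along(theta$layers)) {
    h <- tcrossprod(h, theta$layers[[l]]$W) +
      rep(theta$layers[[l]]$b, each = nrow(h))
    h <- pmax(h, 0)
    acts[[l + 1L]] <- h
  }
  out <- tcrossprod(h, theta$W_out)      # B x 3 n_v
  list(out = out, acts = acts)
}

# backprop: g_out is B x 3 n_v; returns parameter grads and dE/dZ
flow_backward <- function(theta, cache, g_out) {
  nl <- length(theta$layers)
  gW_out <- crossprod(g_out, cache$acts[[nl + 1L]])
  g <- g_out %*% theta$W_out             # B x hidden (grad at last activation)
  g_layers <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    g <- g * (cache$acts[[l + 1L]] > 0)  # through ReLU
    g_layers[[l]] <- list(W = crossprod(g, cache$acts[[l]]), b = colSums(g))
    g <- g %*% theta$layers[[l]]$W
  }
  list(layers = g_layers, W_out = gW_out, Z = g)
}

#' Generate per-vertex flows from latent coordinates
#'
#' @param theta a [flow_generator][init_generator()].
#' @param z_batch `B x K` matrix (or length-K vector) of latent coordinates.
#' @return `B x n_v x 3` array of vertex displacements in voxel units.
#' @export
generate_flows <- function(theta, z_batch) {
  Z <- if (is.null(dim(z_batch))) matrix(z_batch, 1) else as.matrix(z_batch)
  if (ncol(Z) != theta$K)
    stop("latent dimension ", ncol(Z), " does not match generator K = ",
         theta$K)
  if (any(!is.finite(Z))) stop("non-finite latent coordinates")
  out <- flow_forward(theta, Z)$out
  array(out, dim = c(nrow(Z), theta$n_v, 3))
}

#' Gaussian latent prior energy
#'
#' Unit-variance isotropic prior: `0.5 * sum_i ||z_i||^2`.  Controls the
#' spread of the latent embedding and centers it at the origin.
#'
#' @param z_batch `B x K` matrix or vector.
#' @export
latent_prior_energy <- function(z_batch) {
  if (any(!is.finite(z_batch))) stop("non-finite latent coordinates")
  0.5 * sum(z_batch^2)
}

#' Inject Gaussian noise into latent point estimates
#'
#' Regularizes the latent space during generator updates (akin to a fixed-
#' covariance Gaussian variational family); never applied at evaluation.
#'
#' @param z_batch `B x K` matrix.
#' @param sigma noise standard deviation (>= 0), in latent units.
#' @export
inject_latent_noise <- function(z_batch, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(z_batch)
  z_batch + sigma * stats::rnorm(length(z_batch))
}

# ---- generic Adam over a nested list of numeric arrays --------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace",
                  classes = "ANY")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# extract/restore the trainable arrays of a flow generator
theta_params <- function(theta) list(layers = theta$layers, W_out = theta$W_out)
theta_restore <- function(theta, params) {
  theta$layers <- params$layers
  theta$W_out <- params$W_out
  theta
}
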