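# Fourier-domain utilities on cubic volumes and square images.

# unshifted integer frequency indices for length N: 0, 1, ..., N/2, -N/2+1, ..., -1
fft_freq_index <- function(N) {
  q <- seq_len(N) - 1L
  q[q > N / 2] <- q[q > N / 2] - N
  q
}

# |q| on the unshifted 3-D (or 2-D) FFT grid
freq_radius_grid <- function(N, ndim = 3L) {
  q <- fft_freq_index(N)
  if (ndim == 3L) {
    r2 <- outer(q^2, q^2, "+")
    sqrt(outer(c(r2), q^2, "+")) |> array(dim = c(N, N, N))
  } else {
    sqrt(outer(q^2, q^2, "+"))
  }
}

fftshift_nd <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift_nd <- fftshift_nd  # even sizes only: shift is its own inverse

#' Fourier-crop (or identity-crop) a volume or image
#'
#' Centered crop of the discrete spectrum to a smaller even box, the standard
#' cryo-EM down-sampling operation.  The Nyquist-edge planes of the small box
#' (whose mirror frequencies are cut off) are zeroed so the result is exactly
#' real.  The real-space mean is preserved and the voxel/pixel size rescales
#' by `N / new_N`.
#'
#' @param x a [canonical_volume], or a numeric matrix (single image), or a 3-D
#'   array interpreted as a raw volume grid.
#' @param new_N target box size; even and `<=` the current box.
#' @return Same type as the input, cropped to `new_N`.
#' @export
fourier_crop <- function(x, new_N) {
  if (inherits(x, "canonical_volume")) {
    N <- box_size(x)
    out <- fourier_resize_grid(x$data, new_N)
    return(canonical_volume(out, x$voxel_size * N / new_N,
                            bandlimit = min(x$bandlimit, new_N / 2)))
  }
  fourier_resize_grid(x, new_N)
}

#' Zero-pad a volume or image in Fourier space (upsampling)
#'
#' Inverse of [fourier_crop()] for band-limited content: the spectrum is
#' embedded centrally in a larger box.  Voxel size rescales by `N / new_N`.
#'
#' @inheritParams fourier_crop
#' @export
fourier_pad <- function(x, new_N) {
  if (inherits(x, "canonical_volume")) {
    N <- box_size(x)
    out <- fourier_resize_grid(x$data, new_N)
    return(canonical_volume(out, x$voxel_size * N / new_N,
                            bandlimit = x$bandlimit))
  }
  fourier_resize_grid(x, new_N)
}

# shared centered spectral resize; works for crop (new_N < N) and pad
fourier_resize_grid <- function(data, new_N) {
  d <- dim(data)
  N <- d[1]
  if (any(d != N)) stop("grid must be square/cubic, got ", paste(d, collapse = "x"))
  if (new_N %% 2L != 0L) stop("new box size must be even, got ", new_N)
  if (new_N == N) return(data)
  ndim <- length(d)
  F <- fftshift_nd(stats::fft(data))
  n_small <- min(N, new_N)
  lo_big <- max(N, new_N) / 2 - n_small / 2 + 1L
  idx_big <- lo_big:(lo_big + n_small - 1L)
  if (new_N < N) {
    Fc <- do.call(`[`, c(list(F), rep(list(idx_big), ndim), list(drop = FALSE)))
    # zero the non-Hermitian Nyquist-edge planes of the small box so the
    # cropped field is exactly real (its mirror frequencies were cut off)
    for (d in seq_len(ndim)) {
      ii <- rep(list(quote(expr = )), ndim)
      ii[[d]] <- 1L
      Fc <- do.call(`[<-`, c(list(Fc), ii, list(0i)))
    }
  } else {
    Fc <- array(0i, dim = rep(new_N, ndim))
    Fc <- do.call(`[<-`, c(list(Fc), rep(list(idx_big), ndim), list(F)))
  }
  out <- Re(stats::fft(ifftshift_nd(Fc), inverse = TRUE)) / new_N^ndim
  out * (new_N / N)^ndim
}

#' Low-pass a volume to a Fourier shell
#'
#' Zeroes the spectrum beyond the given shell index, with a 2-shell raised
#' cosine rolloff starting at the shell.  Re-applying at the same (or a
#' higher) recorded band-limit is the identity, so the operation is
#' idempotent on [canonical_volume] objects.
#'
#' @param volume a [canonical_volume].
#' @param shell Fourier shell index, `0 < shell <= N/2`.
#' @return The band-limited [canonical_volume] with `bandlimit = shell`.
#' @export
bandlimit_volume <- function(volume, shell) {
  N <- box_size(volume)
  if (shell <= 0 || shell > N / 2) stop("shell must be in (0, N/2]")
  if (shell >= N / 2) {  # no rolloff beyond Nyquist: nothing to remove
    volume$bandlimit <- min(volume$bandlimit, shell)
    return(volume)
  }
  if (is.finite(volume$bandlimit) && volume$bandlimit <= shell) {
    volume$bandlimit <- min(volume$bandlimit, shell)
    return(volume)
  }
  r <- freq_radius_grid(N)
  w <- array(0, dim = dim(r))
  w[r <= shell] <- 1
  roll <- r > shell & r < shell + 2
  w[roll] <- 0.5 * (1 + cos(pi * (r[roll] - shell) / 2))
  data <- Re(stats::fft(stats::fft(volume$data) * w, inverse = TRUE)) / N^3
  canonical_volume(data, volume$voxel_size, bandlimit = shell)
}

#' Mask volume container
#'
#' @param data array with values in `[0, 1]`.
#' @param role `"solvent_exclusion"` or `"zero_deformation"`.
#' @export
mask_volume <- function(data, role = c("solvent_exclusion", "zero_deformation")) {
  role <- match.arg(role)
  if (any(data < -1e-12) || any(data > 1 + 1e-12))
    stop("mask values must lie in [0, 1]")
  structure(list(data = data, role = role), class = "mask_volume")
}

#' Build a soft solvent mask from a density threshold
#'
#' Binarize at `threshold`, dilate by a Euclidean radius, then fall off to
#' zero with a raised-cosine edge.
#'
#' @param volume a [canonical_volume].
#' @param threshold density threshold; voxels strictly above it seed the mask.
#' @param dilation_vox dilation radius in voxels (Euclidean metric, >= 0).
#' @param soft_edge_vox width of the cosine falloff in voxels (>= 0).
#' @param role mask role, see [mask_volume()].
#' @return A [mask_volume].
#' @export
make_soft_mask <- function(volume, threshold, dilation_vox = 0,
                           soft_edge_vox = 0,
                           role = "solvent_exclusion") {
  stopifnot(is.finite(threshold), dilation_vox >= 0, soft_edge_vox >= 0)
  binary <- (volume$data > threshold) * 1.0
  if (sum(binary) == 0) stop("empty mask: no voxel above threshold")
  dist <- sqrt(cpp_edt_sq(binary))
  m <- array(0, dim = dim(binary))
  m[dist <= dilation_vox] <- 1
  if (soft_edge_vox > 0) {
    edge <- dist > dilation_vox & dist < dilation_vox + soft_edge_vox
    m[edge] <- 0.5 * (1 + cos(pi * (dist[edge] - dilation_vox) / soft_edge_vox))
  }
  mask_volume(m, role = role)
}
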