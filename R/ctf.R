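# Contrast transfer function: standard weak-phase-object model with
# astigmatic defocus, spherical aberration, amplitude contrast and an
# optional phase plate shift.  Sign convention: underfocus positive, CTF
# negative at low frequency.

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' CTF parameter record
#'
#' @param defocus_u,defocus_v defoci along the astigmatism axes, Angstrom
#'   (positive = underfocus).
#' @param astig_angle astigmatism axis angle, degrees.
#' @param voltage acceleration voltage, kV.
#' @param cs spherical aberration, mm.
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @param phase_shift additional phase shift, radians.
#' @param pixel_size pixel edge, Angstrom.
#' @export
ctf_params <- function(defocus_u, defocus_v = defocus_u, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                       phase_shift = 0, pixel_size = 1) {
  stopifnot(defocus_u > 0 || (defocus_u == 0 && defocus_v == 0),
            pixel_size > 0)
  list(defocus_u = defocus_u, defocus_v = defocus_v,
       astig_angle = astig_angle, voltage = voltage, cs = cs,
       amplitude_contrast = amplitude_contrast, phase_shift = phase_shift,
       pixel_size = pixel_size)
}

#' Evaluate the CTF on the FFT grid of an N x N image
#'
#' `CTF(s) = -( sqrt(1 - w^2) sin chi + w cos chi )` with aberration phase
#' `chi(s, a) = pi lambda s^2 df(a) - (pi/2) Cs lambda^3 s^4 + phase_shift`
#' and astigmatic defocus
#' `df(a) = (du + dv)/2 + (du - dv)/2 * cos(2 (a - astig_angle))`.
#'
#' @param ctf a [ctf_params()] record (or one row of a particle set's `ctf`
#'   data frame plus `pixel_size`).
#' @param N image box size.
#' @return N x N matrix of CTF values on the unshifted FFT grid.
#' @export
ctf_array <- function(ctf, N) {
  if (is.null(ctf$pixel_size) || ctf$pixel_size <= 0)
    stop("zero or missing pixel size")
  f <- fft_freq_index(N) / (N * ctf$pixel_size)   # 1/Angstrom
  fx <- matrix(f, N, N)
  fy <- matrix(f, N, N, byrow = TRUE)
  s2 <- fx^2 + fy^2
  alpha <- atan2(fy, fx)
  lambda <- electron_wavelength(ctf$voltage)
  df <- 0.5 * (ctf$defocus_u + ctf$defocus_v) +
    0.5 * (ctf$defocus_u - ctf$defocus_v) *
      cos(2 * (alpha - ctf$astig_angle * pi / 180))
  cs_A <- ctf$cs * 1e7
  chi <- pi * lambda * s2 * df - (pi / 2) * cs_A * lambda^3 * s2^2 +
    ctf$phase_shift
  w <- ctf$amplitude_contrast
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

#' Apply a CTF to an image
#'
#' Multiplies the image spectrum by the CTF and returns to real space.  The
#' operator is self-adjoint (the CTF is real and even), which the gradient
#' computations rely on.
#'
#' @param image N x N real matrix.
#' @param ctf a [ctf_params()] record, or a precomputed N x N CTF array.
#' @return Filtered N x N real matrix.
#' @export
apply_ctf <- function(image, ctf) {
  N <- nrow(image)
  C <- if (is.matrix(ctf)) ctf else ctf_array(ctf, N)
  Re(stats::fft(stats::fft(image) * C, inverse = TRUE)) / N^2
}
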