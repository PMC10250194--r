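#' Canonical volume container
#'
#' A cubic real-space voxel grid of density with a physical voxel size and a
#' current Fourier band-limit.  This is the canonical map `V` from which all
#' conformations are generated by deformation.
#'
#' @param data numeric N x N x N array, N even and >= 8, all values finite.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param bandlimit integer Fourier shell index in `0..N/2`, or `Inf` for
#'   unlimited.
#' @return An object of class `canonical_volume` with fields `data`,
#'   `voxel_size` and `bandlimit`.
#' @export
canonical_volume <- function(data, voxel_size, bandlimit = Inf) {
  d <- dim(data)
  if (length(d) != 3L || d[1] != d[2] || d[1] != d[3])
    stop("non-cubic grid: ", paste(d, collapse = "x"))
  if (d[1] %% 2L != 0L || d[1] < 8L)
    stop("box size must be even and >= 8, got ", d[1])
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  structure(list(data = data, voxel_size = voxel_size, bandlimit = bandlimit),
            class = "canonical_volume")
}

#' @export
print.canonical_volume <- function(x, ...) {
  cat(sprintf("<canonical_volume> %d^3 voxels, %.4g A/voxel, band-limit %s\n",
              dim(x$data)[1], x$voxel_size,
              if (is.finite(x$bandlimit)) x$bandlimit else "unlimited"))
  invisible(x)
}

box_size <- function(volume) dim(volume$data)[1]

# ---- minimal MRC (mode 2) reader/writer -----------------------------------
# 1024-byte standard header, 32-bit little-endian float data.

mrc_write_raw <- function(data, voxel_size, path) {
  d <- dim(data)
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], d[3])),
           con, size = 4L, endian = "little")
  writeBin(as.numeric(c(d * voxel_size, 90, 90, 90)), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con, size = 4L,
           endian = "little")
  writeBin(integer(2L), con, size = 4L, endian = "little")        # ispg, nsymbt
  writeBin(integer(25L), con, size = 4L, endian = "little")       # extra
  writeBin(numeric(3L), con, size = 4L, endian = "little")        # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(c(0x44L, 0x44L, 0x00L, 0x00L), con, size = 1L)         # machst LE
  writeBin(as.numeric(stats::sd(as.numeric(data))), con, size = 4L,
           endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")                 # nlabl
  writeBin(raw(800L), con)
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

mrc_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h_int <- readBin(con, integer(), n = 10L, size = 4L, endian = "little")
  cella <- readBin(con, numeric(), n = 6L, size = 4L, endian = "little")
  readBin(con, integer(), n = 3L, size = 4L, endian = "little")
  readBin(con, numeric(), n = 3L, size = 4L, endian = "little")
  seek(con, 1024L)
  nx <- h_int[1]; ny <- h_int[2]; nz <- h_int[3]; mode <- h_int[4]
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  mx <- h_int[8]
  if (mx <= 0L || cella[1] <= 0) stop("missing voxel size in MRC header")
  voxel <- cella[1] / mx
  n <- as.numeric(nx) * ny * nz
  data <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(data) != n) stop("truncated MRC data section")
  list(data = array(data, dim = c(nx, ny, nz)), voxel_size = voxel)
}

#' Read / write a cubic MRC volume
#'
#' Minimal MRC2014 mode-2 (32-bit float) I/O.  `read_volume()` rejects
#' non-cubic grids and files without a voxel size; `write_volume()` stores the
#' grid as little-endian float32, so a write-read round trip is bit-exact for
#' float32-representable data.
#'
#' @param path file path.
#' @return `read_volume()`: a [canonical_volume]. `write_volume()`: the path,
#'   invisibly.
#' @export
read_volume <- function(path) {
  r <- mrc_read_raw(path)
  d <- dim(r$data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("non-cubic grid: ", paste(d, collapse = "x"))
  canonical_volume(r$data, r$voxel_size)
}

#' @rdname read_volume
#' @param volume a [canonical_volume] (or mask volume).
#' @export
write_volume <- function(volume, path) {
  mrc_write_raw(volume$data, volume$voxel_size, path)
  invisible(path)
}

#' Read / write an MRCS image stack
#'
#' Particle image stacks are stored as MRC mode-2 files whose sections are the
#' individual N x N images.
#'
#' @param path file path.
#' @return `read_image_stack()`: list with `images` (N x N x M array) and
#'   `pixel_size` (Angstrom).
#' @export
read_image_stack <- function(path) {
  r <- mrc_read_raw(path)
  list(images = r$data, pixel_size = r$voxel_size)
}

#' @rdname read_image_stack
#' @param images N x N x M array of particle images.
#' @param pixel_size pixel edge length in Angstrom.
#' @export
write_image_stack <- function(images, pixel_size, path) {
  mrc_write_raw(images, pixel_size, path)
  invisible(path)
}

# round to float32 precision (what a mode-2 file can hold)
float32 <- function(x) {
  r <- writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  out <- readBin(r, numeric(), n = length(x), size = 4L, endian = "little")
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
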