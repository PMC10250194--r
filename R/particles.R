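# Particle sets: images + per-particle pose, CTF, half-set label and latent
# coordinates.  Metadata travels as RELION-31 STAR or as a flat CSV with the
# same column names; CSV is the default output dialect.

REQUIRED_META_COLS <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                        "rlnOriginXAngst", "rlnOriginYAngst",
                        "rlnDefocusU", "rlnDefocusV", "rlnDefocusAngle",
                        "rlnVoltage", "rlnSphericalAberration",
                        "rlnAmplitudeContrast")

#' Convert ZYZ intrinsic Euler angles to a rotation matrix
#'
#' Convention: `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`, angles in degrees.
#' The matrix maps canonical-frame coordinates into the microscope frame.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3 x 3 rotation matrix (orthonormal, det +1).
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(rot) %*% ry(tilt) %*% rz(psi)
}

#' Particle set container
#'
#' @param images N x N x M array of particle images (detector units).
#' @param poses 3 x 3 x M array of rotation matrices (canonical -> microscope).
#' @param shifts M x 2 matrix of in-plane shifts in Angstrom.
#' @param ctf data frame with M rows: `defocus_u`, `defocus_v` (Angstrom, > 0),
#'   `astig_angle` (deg), `voltage` (kV), `cs` (mm), `amplitude_contrast`
#'   (in `[0,1]`), `phase_shift` (rad).
#' @param pixel_size pixel edge in Angstrom.
#' @param half_set character vector of labels in `{"A","B"}`; default
#'   alternates by particle index.
#' @param latents M x K matrix of latent coordinates, or `NULL`.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(images, poses, shifts, ctf, pixel_size,
                         half_set = NULL, latents = NULL) {
  M <- dim(images)[3]
  stopifnot(dim(images)[1] == dim(images)[2])
  if (dim(poses)[3] != M || nrow(shifts) != M || nrow(ctf) != M)
    stop("metadata length does not match image count M = ", M)
  for (i in seq_len(M)) {
    R <- poses[, , i]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop("pose ", i, " is not a proper rotation matrix")
  }
  if (any(!is.finite(ctf$defocus_u)) || any(!is.finite(ctf$defocus_v)))
    stop("non-finite defocus")
  if (any(ctf$defocus_u <= 0) || any(ctf$defocus_v <= 0))
    stop("defoci must be positive")
  if (is.null(half_set))
    half_set <- rep(c("A", "B"), length.out = M)
  if (!all(half_set %in% c("A", "B"))) stop("half_set labels must be A or B")
  if (!is.null(latents)) {
    latents <- as.matrix(latents)
    if (nrow(latents) != M) stop("latent table length mismatch")
  }
  structure(list(images = images, poses = poses, shifts = shifts, ctf = ctf,
                 pixel_size = pixel_size, half_set = half_set,
                 latents = latents),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> M = %d images of %d^2 px (%.3g A/px), K = %s\n",
              dim(x$images)[3], dim(x$images)[1], x$pixel_size,
              if (is.null(x$latents)) "none" else ncol(x$latents)))
  invisible(x)
}

n_particles <- function(p) dim(p$images)[3]

# take a subset of particles (used for minibatching / half-sets)
subset_particles <- function(p, idx) {
  particle_set(p$images[, , idx, drop = FALSE],
               p$poses[, , idx, drop = FALSE],
               p$shifts[idx, , drop = FALSE],
               p$ctf[idx, , drop = FALSE],
               p$pixel_size,
               half_set = p$half_set[idx],
               latents = if (is.null(p$latents)) NULL
                         else p$latents[idx, , drop = FALSE])
}

# ---- STAR (RELION-31 dialect) ---------------------------------------------

read_star_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  li <- which(lines == "loop_")
  if (length(li) == 0) stop("no loop_ block found in STAR file")
  i <- li[length(li)] + 1L
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_", "", strsplit(lines[i], "[ #]+")[[1]][1]))
    i <- i + 1L
  }
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_")]
  if (length(rows) == 0) stop("empty STAR data block")
  mat <- do.call(rbind, strsplit(rows, "[ \t]+"))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

write_star_table <- function(df, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  rows <- apply(df, 1L, function(r) paste(format(r, trim = TRUE),
                                          collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

read_meta_table <- function(path) {
  if (grepl("\\.star$", path, ignore.case = TRUE)) read_star_table(path)
  else utils::read.csv(path, check.names = FALSE)
}

#' Read a particle set from an MRCS stack plus a metadata table
#'
#' The metadata table (STAR `.star` or flat CSV with RELION-31 column names)
#' must carry Euler angles, origin shifts in Angstrom, defoci, voltage,
#' spherical aberration and amplitude contrast.  `rlnPhaseShift` (degrees) and
#' `rlnRandomSubset` (1/2 -> A/B) are optional; absent half-set labels are
#' assigned alternating by row index.
#'
#' @param stack_path MRCS image stack.
#' @param metadata_path STAR or CSV metadata file.
#' @return A [particle_set].
#' @export
read_particles <- function(stack_path, metadata_path) {
  st <- read_image_stack(stack_path)
  meta <- read_meta_table(metadata_path)
  M <- dim(st$images)[3]
  if (nrow(meta) != M)
    stop("count mismatch: stack has ", M, " frames but metadata has ",
         nrow(meta), " rows")
  missing <- setdiff(REQUIRED_META_COLS, names(meta))
  if (length(missing) > 0)
    stop("missing required metadata columns: ", paste(missing, collapse = ", "))
  poses <- array(0, dim = c(3, 3, M))
  for (i in seq_len(M))
    poses[, , i] <- euler_to_matrix(meta$rlnAngleRot[i], meta$rlnAngleTilt[i],
                                    meta$rlnAnglePsi[i])
  shifts <- cbind(meta$rlnOriginXAngst, meta$rlnOriginYAngst)
  ctf <- data.frame(
    defocus_u = meta$rlnDefocusU,
    defocus_v = meta$rlnDefocusV,
    astig_angle = meta$rlnDefocusAngle,
    voltage = meta$rlnVoltage,
    cs = meta$rlnSphericalAberration,
    amplitude_contrast = meta$rlnAmplitudeContrast,
    phase_shift = if ("rlnPhaseShift" %in% names(meta))
      meta$rlnPhaseShift * pi / 180 else rep(0, M))
  half <- if ("rlnRandomSubset" %in% names(meta))
    c("A", "B")[meta$rlnRandomSubset] else NULL
  latents <- NULL
  zcols <- grep("^tfxLatent", names(meta), value = TRUE)
  if (length(zcols) > 0) latents <- as.matrix(meta[, zcols, drop = FALSE])
  particle_set(st$images, poses, shifts, ctf, st$pixel_size,
               half_set = half, latents = latents)
}

#' Write particle metadata (and optionally the stack)
#'
#' @param particles a [particle_set].
#' @param metadata_path output `.csv` (default dialect) or `.star` path.
#' @param euler M x 3 matrix of the Euler angles (deg) used to build the
#'   poses; required because a rotation matrix does not round-trip to a
#'   unique Euler triple.
#' @param stack_path optional MRCS output path for the images.
#' @export
write_particles <- function(particles, metadata_path, euler,
                            stack_path = NULL) {
  M <- n_particles(particles)
  df <- data.frame(
    rlnAngleRot = euler[, 1], rlnAngleTilt = euler[, 2],
    rlnAnglePsi = euler[, 3],
    rlnOriginXAngst = particles$shifts[, 1],
    rlnOriginYAngst = particles$shifts[, 2],
    rlnDefocusU = particles$ctf$defocus_u,
    rlnDefocusV = particles$ctf$defocus_v,
    rlnDefocusAngle = particles$ctf$astig_angle,
    rlnVoltage = particles$ctf$voltage,
    rlnSphericalAberration = particles$ctf$cs,
    rlnAmplitudeContrast = particles$ctf$amplitude_contrast,
    rlnPhaseShift = particles$ctf$phase_shift * 180 / pi,
    rlnRandomSubset = match(particles$half_set, c("A", "B")))
  if (!is.null(particles$latents)) {
    K <- ncol(particles$latents)
    for (k in seq_len(K)) df[[paste0("tfxLatent", k)]] <- particles$latents[, k]
  }
  if (grepl("\\.star$", metadata_path, ignore.case = TRUE))
    write_star_table(df, metadata_path)
  else utils::write.csv(df, metadata_path, row.names = FALSE)
  if (!is.null(stack_path))
    write_image_stack(particles$images, particles$pixel_size, stack_path)
  invisible(metadata_path)
}

#' Read / write latent coordinate tables
#'
#' CSV with columns `particle_index, z_1, ..., z_K`.
#'
#' @param path CSV path.
#' @return `read_latents()`: M x K numeric matrix.
#' @export
read_latents <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, grep("^z_", names(df)), drop = FALSE])
}

#' @rdname read_latents
#' @param z M x K latent matrix.
#' @export
write_latents <- function(z, path) {
  z <- as.matrix(z)
  df <- data.frame(particle_index = seq_len(nrow(z)) - 1L, z)
  names(df)[-1] <- paste0("z_", seq_len(ncol(z)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
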