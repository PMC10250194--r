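# Tetrahedral finite-element meshes over the molecule: regular lattice
# meshes, custom fused meshes built from a segmentation, linear shape-function
# interpolation of vertex flows to voxel flows, and the local-rigidity energy.

# 5-tetrahedron decomposition of the unit cube; parity-alternating mirror
# along x keeps faces of neighboring cubes compatible.
TET5_EVEN <- list(
  rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
  rbind(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0), c(1, 0, 1)),
  rbind(c(0, 1, 0), c(0, 0, 0), c(1, 1, 0), c(0, 1, 1)),
  rbind(c(0, 0, 1), c(0, 0, 0), c(1, 0, 1), c(0, 1, 1)),
  rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
TET5_ODD <- lapply(TET5_EVEN, function(m) { m[, 1] <- 1 - m[, 1]; m })

tetra_mesh <- function(vertices, cells, N, voxel_size, element_weights = NULL,
                       assignment = NULL) {
  n_c <- nrow(cells)
  if (is.null(element_weights)) element_weights <- rep(1, n_c)
  m <- structure(list(vertices = vertices, cells = cells, N = N,
                      voxel_size = voxel_size,
                      element_weights = element_weights,
                      assignment = assignment),
                 class = "tetra_mesh")
  if (is.null(assignment)) m$assignment <- assign_voxels(vertices, cells, N)
  m$P <- interp_matrix(m)
  cc <- arrayInd(m$assignment$voxel_index, rep(N, 3)) - 1L
  m$support_lo <- apply(cc, 2, min)
  m$support_hi <- apply(cc, 2, max)
  m
}

#' @export
print.tetra_mesh <- function(x, ...) {
  cat(sprintf(
    "<tetra_mesh> %d vertices, %d cells, %d assigned voxels on a %d^3 grid\n",
    nrow(x$vertices), nrow(x$cells), length(x$assignment$voxel_index), x$N))
  invisible(x)
}

# Assign every voxel center inside some tetrahedron its (cell, barycentric
# coordinates).  First containing cell wins on shared faces.
assign_voxels <- function(vertices, cells, N) {
  taken <- logical(N^3)
  vox_idx <- integer(0); cell_idx <- integer(0)
  bary <- matrix(0, 0, 4)
  for (j in seq_len(nrow(cells))) {
    vv <- vertices[cells[j, ], , drop = FALSE]       # 4 x 3
    T4 <- rbind(t(vv), rep(1, 4))                    # 4 x 4
    if (abs(det(T4)) < 1e-12) stop("degenerate mesh cell ", j)
    T4inv <- solve(T4)
    lo <- pmax(ceiling(apply(vv, 2, min) - 1e-9), 0)
    hi <- pmin(floor(apply(vv, 2, max) + 1e-9), N - 1)
    if (any(hi < lo)) next
    g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
    b <- cbind(g, 1) %*% t(T4inv)                    # n x 4 barycentric
    inside <- rowSums(b < -1e-9) == 0
    if (!any(inside)) next
    g <- g[inside, , drop = FALSE]
    b <- b[inside, , drop = FALSE]
    lin <- 1L + g[, 1] + N * (g[, 2] + N * g[, 3])
    new <- !taken[lin]
    if (!any(new)) next
    taken[lin[new]] <- TRUE
    vox_idx <- c(vox_idx, lin[new])
    cell_idx <- c(cell_idx, rep(j, sum(new)))
    bnew <- b[new, , drop = FALSE]
    bnew <- pmax(bnew, 0)
    bary <- rbind(bary, bnew / rowSums(bnew))
  }
  list(voxel_index = vox_idx, cell = cell_idx, bary = bary)
}

# sparse (n_assigned x n_v) barycentric interpolation operator
interp_matrix <- function(mesh) {
  a <- mesh$assignment
  n <- length(a$voxel_index)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 4L),
    j = as.integer(mesh$cells[a$cell, ]),
    x = as.numeric(a$bary),
    dims = c(n, nrow(mesh$vertices)))
}

#' Generate a regular tetrahedral mesh covering a mask
#'
#' An axis-aligned cubic lattice of spacing `element_size_A` covers the
#' mask's bounding region; lattice cubes overlapping no mask voxel are
#' dropped, and each kept cube is split into 5 tetrahedra with
#' parity-alternating orientation so neighboring cubes share faces.
#'
#' @param mask a [mask_volume] (nonempty).
#' @param element_size_A lattice spacing in Angstrom
#'   (`>= 2 * voxel_size_A`).
#' @param voxel_size_A voxel size of the grid the mask lives on.
#' @return A `tetra_mesh` with vertices in (0-based) voxel units.
#' @export
generate_regular_mesh <- function(mask, element_size_A, voxel_size_A) {
  if (element_size_A < 2 * voxel_size_A)
    stop("element size must be at least 2 voxels")
  lat <- mask_lattice(mask, element_size_A / voxel_size_A)
  build_lattice_mesh(lat, cube_group = rep(1L, nrow(lat$cubes)),
                     voxel_size = voxel_size_A)
}

# lattice bookkeeping shared by regular and fused meshes
mask_lattice <- function(mask, h) {
  sel <- which(mask$data > 0.5)
  if (length(sel) == 0) stop("empty mask")
  N <- dim(mask$data)[1]
  coord <- arrayInd(sel, dim(mask$data)) - 1L       # 0-based voxel coords
  lo <- apply(coord, 2, min)
  hi <- apply(coord, 2, max)
  nc <- pmax(ceiling((hi - lo) / h), 1L)
  ci <- pmin(floor(sweep(coord, 2, lo) / h), matrix(rep(nc - 1L, each = nrow(coord)), ncol = 3))
  keys <- unique(ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3]))
  cubes <- cbind(keys %% nc[1],
                 (keys %/% nc[1]) %% nc[2],
                 keys %/% (nc[1] * nc[2]))
  list(origin = lo, h = h, nc = nc, cubes = cubes, N = N,
       voxel_coord = coord, voxel_cube = ci)
}

# Build cells from kept cubes; vertices are keyed by (lattice node, group) so
# cubes in different groups do not share vertices.
build_lattice_mesh <- function(lat, cube_group, voxel_size) {
  nn <- lat$nc + 1L
  vkey_map <- new.env(hash = TRUE)
  vertices <- matrix(0, 0, 3)
  cells <- matrix(0L, 0, 4)
  vid <- function(node, grp) {
    key <- paste0(node[1], ",", node[2], ",", node[3], "g", grp)
    id <- vkey_map[[key]]
    if (is.null(id)) {
      vertices <<- rbind(vertices, lat$origin + node * lat$h)
      id <- nrow(vertices)
      vkey_map[[key]] <- id
    }
    id
  }
  for (q in seq_len(nrow(lat$cubes))) {
    cb <- lat$cubes[q, ]
    grp <- cube_group[q]
    tets <- if ((cb[1] + cb[2] + cb[3]) %% 2 == 0) TET5_EVEN else TET5_ODD
    for (tet in tets) {
      ids <- integer(4)
      for (k in 1:4) ids[k] <- vid(cb + tet[k, ], grp)
      cells <- rbind(cells, ids)
    }
  }
  dimnames(cells) <- NULL
  tetra_mesh(vertices, cells, lat$N, voxel_size)
}

#' Segmentation label volume
#'
#' @param data integer grid; 0 = unassigned, `k >= 1` = subdomain k.
#' @param fusion_pairs two-column matrix of unordered subdomain label pairs
#'   whose interfaces are to be fused (vertices shared).
#' @export
segment_volume <- function(data, fusion_pairs = NULL) {
  if (!is.null(fusion_pairs)) fusion_pairs <- matrix(as.integer(fusion_pairs),
                                                     ncol = 2)
  structure(list(data = data, fusion_pairs = fusion_pairs),
            class = "segment_volume")
}

#' Build a custom fused mesh from a coarse segmentation
#'
#' Each voxel is first reassigned to its nearest segment (Euclidean distance),
#' one submesh per subdomain is built from the shared base lattice, and
#' vertices are duplicated at subdomain boundaries except on interfaces
#' between fused label pairs, where vertices are shared.  Cuts between
#' non-fused submeshes let adjacent domains move independently.
#'
#' @param segments a [segment_volume].
#' @param mask a [mask_volume] defining the meshed region.
#' @inheritParams generate_regular_mesh
#' @return A `tetra_mesh`.
#' @export
build_fused_mesh <- function(segments, mask, element_size_A, voxel_size_A) {
  labels <- sort(setdiff(unique(as.integer(segments$data)), 0L))
  if (length(labels) == 0) stop("segmentation has no labeled subdomain")
  fp <- segments$fusion_pairs
  if (!is.null(fp) && !all(fp %in% labels))
    stop("fusion pair references an unknown segment label")
  # expand each segment to all voxels nearest to it
  dists <- lapply(labels, function(l) cpp_edt_sq((segments$data == l) * 1.0))
  nearest <- array(labels[1], dim = dim(segments$data))
  best <- dists[[1]]
  for (k in seq_along(labels)[-1]) {
    upd <- dists[[k]] < best
    nearest[upd] <- labels[k]
    best[upd] <- dists[[k]][upd]
  }
  # merge fused labels into shared vertex groups (union-find)
  parent <- stats::setNames(labels, labels)
  find <- function(x) { while (parent[[as.character(x)]] != x)
    x <- parent[[as.character(x)]]; x }
  if (!is.null(fp)) for (r in seq_len(nrow(fp))) {
    a <- find(fp[r, 1]); b <- find(fp[r, 2])
    if (a != b) parent[[as.character(max(a, b))]] <- min(a, b)
  }
  lat <- mask_lattice(mask, element_size_A / voxel_size_A)
  # label each kept cube by the expanded segment at its center
  cube_group <- integer(nrow(lat$cubes))
  N <- lat$N
  for (q in seq_len(nrow(lat$cubes))) {
    ctr <- round(lat$origin + (lat$cubes[q, ] + 0.5) * lat$h)
    ctr <- pmin(pmax(ctr, 0), N - 1)
    cube_group[q] <- find(nearest[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
  }
  build_lattice_mesh(lat, cube_group, voxel_size_A)
}

#' Density-based per-element prior weights
#'
#' The densest element gets weight 1 and empty elements get `w_min`
#' (default 0.5), linear in mean element density between the two, so the
#' rigidity prior is strongest where there is structure and the flow is free
#' to compress or expand empty space.
#'
#' @param mesh a `tetra_mesh` whose voxel assignment was built on `volume`'s
#'   grid.
#' @param volume a [canonical_volume].
#' @param w_min weight of empty elements, in `(0, 1]`.
#' @return The mesh with `element_weights` set.
#' @export
compute_element_weights <- function(mesh, volume, w_min = 0.5) {
  n_c <- nrow(mesh$cells)
  score <- numeric(n_c)
  a <- mesh$assignment
  dens <- volume$data[a$voxel_index]
  sums <- tapply(dens, factor(a$cell, levels = seq_len(n_c)), mean)
  score <- unname(pmax(ifelse(is.na(sums), 0, as.numeric(sums)), 0))
  if (max(score) > 0) {
    mesh$element_weights <- w_min + (1 - w_min) * score / max(score)
  } else {
    mesh$element_weights <- rep(w_min, n_c)
  }
  mesh
}

#' Interpolate per-vertex flow to a dense voxel displacement field
#'
#' Linear finite-element shape functions: the displacement at a voxel center
#' is the barycentric-weighted sum of its cell's four vertex displacements;
#' voxels outside every cell do not move.
#'
#' @param mesh a `tetra_mesh`.
#' @param vertex_displacements `n_v x 3` matrix (voxel units).
#' @return list of three `N^3` arrays `dx`, `dy`, `dz`.
#' @export
interpolate_flow <- function(mesh, vertex_displacements) {
  if (any(!is.finite(vertex_displacements)))
    stop("non-finite vertex displacement")
  if (nrow(vertex_displacements) != nrow(mesh$vertices))
    stop("displacement array does not match vertex count")
  P <- mesh$P
  if (is.null(P)) P <- interp_matrix(mesh)
  dd <- as.matrix(P %*% vertex_displacements)
  N <- mesh$N
  out <- lapply(1:3, function(k) {
    a <- array(0, dim = c(N, N, N))
    a[mesh$assignment$voxel_index] <- dd[, k]
    a
  })
  names(out) <- c("dx", "dy", "dz")
  out
}

#' Local-rigidity energy of deformation fields
#'
#' For each particle `i` and element `j` the affine deformation
#' `u(x) = A x + b` is solved exactly from the four vertex rest and deformed
#' positions, and the nonrigidity is the squared deviation of the singular
#' values of `A` from 1:
#' `E_rigid = sum_i sum_j w_j sum_l (s_ij^l - 1)^2`.
#'
#' @param mesh a `tetra_mesh` (weights from [compute_element_weights()]).
#' @param vertex_displacements `n_v x 3` matrix or `B x n_v x 3` array.
#' @param gradient also return the analytic gradient.
#' @return list with `energy` (scalar), `cell_nonrigidity` (per-element
#'   `sum_l (s-1)^2` summed over the batch) and, if requested, `grad` with
#'   the same shape as the input.
#' @export
rigidity_energy <- function(mesh, vertex_displacements, gradient = FALSE) {
  d <- vertex_displacements
  single <- length(dim(d)) != 3L
  if (single) {
    cube <- array(as.matrix(d), dim = c(nrow(mesh$vertices), 3, 1))
  } else {
    cube <- aperm(d, c(2, 3, 1))  # B x n_v x 3  ->  n_v x 3 x B
  }
  res <- cpp_rigidity(mesh$vertices, mesh$cells - 1L, mesh$element_weights,
                      cube, gradient)
  if (gradient && !single) res$grad <- aperm(res$grad, c(3, 1, 2))
  if (gradient && single) res$grad <- res$grad[, , 1]
  res
}

#' Serialize a mesh to / from JSON
#'
#' Stores vertices (voxel units), cells, element weights, grid size and voxel
#' size; the voxel assignment is rebuilt on read.
#'
#' @param mesh a `tetra_mesh`.
#' @param path JSON file path.
#' @export
write_mesh <- function(mesh, path) {
  jsonlite::write_json(list(vertices = mesh$vertices, cells = mesh$cells,
                            element_weights = mesh$element_weights,
                            N = mesh$N, voxel_size = mesh$voxel_size),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tetra_mesh(matrix(j$vertices, ncol = 3), matrix(as.integer(j$cells), ncol = 4),
             as.integer(j$N), j$voxel_size,
             element_weights = as.numeric(j$element_weights))
}
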