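#' Regular volumetric source grid
#'
#' Builds a regular grid of candidate source locations with an in-head mask
#' (voxels strictly inside the conductor sphere). The default is a
#' 24 x 24 x 24 region at 3 mm isotropic spacing centred on the head centre,
#' covering deep structures (including hippocampal depth) with margin; pass a
#' larger `dim` for a whole-head grid. With even dimensions no voxel falls
#' exactly on the sphere centre, where a dipole would be externally silent.
#'
#' @param head A [sphere_head()].
#' @param spacing Isotropic voxel spacing in metres (default 0.003).
#' @param dim Grid dimensions, length 3 (default `c(24, 24, 24)`).
#' @param center Grid centre in metres (default: head centre).
#' @return An object of class `source_grid` with fields `origin` (metres),
#'   `spacing`, `dim` and logical `mask` array.
#' @export
source_grid <- function(head = sphere_head(), spacing = 0.003,
                        dim = c(24, 24, 24), center = head$center) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (spacing <= 0) abort("`spacing` must be positive")
  dim <- as.integer(dim)
  origin <- center - spacing * (dim - 1) / 2
  co <- grid_all_coords(origin, spacing, dim)
  d <- sqrt(rowSums(sweep(co, 2, head$center)^2))
  mask <- array(d < head$radius, dim)
  structure(list(origin = origin, spacing = spacing, dim = dim,
                 mask = mask, head = head),
            class = "source_grid")
}

grid_all_coords <- function(origin, spacing, dim) {
  ijk <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  sweep((ijk - 1) * spacing, 2, origin, `+`)
}

#' Grid coordinate mappings
#'
#' `grid_coords` returns the world coordinates (metres) of all voxels (or of
#' the in-mask voxels); `grid_index_to_world` and `grid_world_to_index` map
#' between voxel indices `(i, j, k)` (1-based) and world coordinates; the two
#' are mutually inverse on grid points.
#'
#' @param grid A [source_grid()].
#' @param masked If `TRUE`, only in-mask voxels (in linear-index order).
#' @return `grid_coords`: an n x 3 matrix in metres.
#' @export
grid_coords <- function(grid, masked = FALSE) {
  co <- grid_all_coords(grid$origin, grid$spacing, grid$dim)
  if (masked) co[as.vector(grid$mask), , drop = FALSE] else co
}

#' @rdname grid_coords
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @export
grid_index_to_world <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep((ijk - 1) * grid$spacing, 2, grid$origin, `+`)
}

#' @rdname grid_coords
#' @param world n x 3 matrix (or length-3 vector) of world coordinates in
#'   metres.
#' @export
grid_world_to_index <- function(grid, world) {
  world <- rbind(world)
  ijk <- round(sweep(world, 2, grid$origin) / grid$spacing) + 1
  storage.mode(ijk) <- "integer"
  ijk
}

# linear index (1-based, column-major) of voxel (i,j,k)
grid_linear_index <- function(grid, ijk) {
  ijk <- rbind(ijk)
  as.integer(ijk[, 1] + grid$dim[1] * (ijk[, 2] - 1) +
               grid$dim[1] * grid$dim[2] * (ijk[, 3] - 1))
}

#' External magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form field of a current dipole embedded in a homogeneous
#' conducting sphere, evaluated at points outside the conductor. Radial
#' dipoles (and any dipole at the sphere centre) are externally silent and
#' return a zero field; the field is linear in the dipole moment.
#'
#' All of `dipole_pos`, `moment` and `obs_pos` may be n x 3 matrices
#' (recycled against each other row-wise).
#'
#' @param dipole_pos Dipole location(s) in metres, strictly inside the sphere.
#' @param moment Dipole moment(s) in ampere-metres.
#' @param obs_pos Observation point(s) in metres, strictly outside the sphere.
#' @param head A [sphere_head()].
#' @return An n x 3 matrix of magnetic field vectors in tesla.
#' @export
dipole_field_sphere <- function(dipole_pos, moment, obs_pos,
                                head = sphere_head()) {
  r0 <- rbind(dipole_pos)
  q <- rbind(moment)
  r <- rbind(obs_pos)
  n <- max(nrow(r0), nrow(q), nrow(r))
  expand <- function(m) if (nrow(m) == n) m else m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
  r0 <- expand(r0); q <- expand(q); r <- expand(r)
  r0 <- sweep(r0, 2, head$center)
  r <- sweep(r, 2, head$center)
  if (any(sqrt(rowSums(r0^2)) >= head$radius)) {
    abort("dipole position(s) must lie strictly inside the head sphere")
  }
  if (any(sqrt(rowSums(r^2)) <= head$radius)) {
    abort("observation point(s) must lie strictly outside the head sphere")
  }
  sarvas_field(r0, q, r)
}

# Sarvas closed form, sphere centred at the origin; row-vectorised.
sarvas_field <- function(r0, q, r) {
  a <- r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  a_dot_r <- rowSums(a * r)
  r0_dot_r <- rowSums(r0 * r)
  F <- an * (rn * an + rn^2 - r0_dot_r)
  c1 <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + a_dot_r / an
  gF <- c1 * r - c2 * r0
  qxr0 <- cross3_mat(q, r0)
  MU0 / (4 * pi * F^2) * (F * qxr0 - rowSums(qxr0 * r) * gF)
}

#' Tangential orthonormal basis at source locations
#'
#' Returns, for each source, two orthonormal vectors spanning the dipole
#' orientations tangential to the sphere radius (the radial direction is
#' externally silent and excluded by construction).
#'
#' @param pos n x 3 matrix of source positions (metres).
#' @param head A [sphere_head()].
#' @return A list with n x 3 matrices `t1` and `t2`.
#' @export
tangential_basis <- function(pos, head = sphere_head()) {
  pos <- rbind(pos)
  rad <- sweep(pos, 2, head$center)
  rn <- sqrt(rowSums(rad^2))
  if (any(rn < 1e-12)) {
    abort("tangential basis undefined at the sphere centre")
  }
  rad <- rad / rn
  # t1 = z-hat x r-hat, falling back to x-hat near the poles
  t1 <- cbind(-rad[, 2], rad[, 1], 0)
  t1n <- sqrt(rowSums(t1^2))
  polar <- t1n < 1e-8
  if (any(polar)) {
    alt <- cbind(0, rad[polar, 3], -rad[polar, 2])  # x-hat x r-hat
    t1[polar, ] <- alt
    t1n[polar] <- sqrt(rowSums(rbind(alt)^2))
  }
  t1 <- t1 / t1n
  t2 <- cross3_mat(rad, t1)
  list(t1 = t1, t2 = t2)
}

#' Lead-field matrices over the tangential basis
#'
#' For every in-mask grid voxel, computes the sensors x 2 lead-field matrix
#' whose columns are the forward fields of unit dipoles along the two
#' tangential basis vectors, each projected onto the sensors' sensitive axes.
#'
#' @param scalp A scalp `sensor_array`.
#' @param grid A [source_grid()]; all in-mask voxels must lie inside the
#'   sphere.
#' @param head A [sphere_head()] (default: the grid's head model).
#' @return An object of class `lead_field_set`: list with `L1`, `L2`
#'   (n_sources x n_sensors matrices for basis columns 1 and 2), `basis`
#'   (the tangential vectors), `sources` (n x 3 positions), `voxel` (linear
#'   indices into the grid) and `grid`.
#' @export
lead_field_matrix <- function(scalp, grid, head = grid$head) {
  src <- grid_coords(grid, masked = TRUE)
  lead_field_points(scalp, src, head, grid = grid,
                    voxel = which(as.vector(grid$mask)))
}

# Lead field at arbitrary source points (used for ground-truth topographies).
lead_field_points <- function(scalp, src, head, grid = NULL, voxel = NULL) {
  src <- rbind(src)
  rel <- sweep(src, 2, head$center)
  if (any(sqrt(rowSums(rel^2)) >= head$radius)) {
    abort("source position(s) must lie strictly inside the head sphere")
  }
  bas <- tangential_basis(src, head)
  pos <- sensor_positions(scalp)
  ori <- sensor_orientations(scalp)
  n_src <- nrow(src)
  n_sens <- nrow(pos)
  L1 <- matrix(0, n_src, n_sens)
  L2 <- matrix(0, n_src, n_sens)
  for (s in seq_len(n_sens)) {
    obs <- matrix(pos[s, ], n_src, 3, byrow = TRUE)
    B1 <- dipole_field_sphere(src, bas$t1, obs, head)
    B2 <- dipole_field_sphere(src, bas$t2, obs, head)
    L1[, s] <- B1 %*% ori[s, ]
    L2[, s] <- B2 %*% ori[s, ]
  }
  structure(list(L1 = L1, L2 = L2, basis = bas, sources = src,
                 voxel = voxel, grid = grid, head = head,
                 channel_names = scalp$name),
            class = "lead_field_set")
}

# sensors x 2 lead field of a single entry of a lead_field_set
lead_field_of <- function(lf, i) {
  cbind(lf$L1[i, ], lf$L2[i, ])
}
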