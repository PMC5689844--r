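#' Image volume on a regular 3D grid
#'
#' Lightweight container for a scalar volume: a 3D numeric array plus the
#' voxel spacing and world origin (both in mm) and a unit tag. World
#' coordinates are axis-aligned: voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * spacing`. The third axis is craniocaudal
#' (increasing k = superior).
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @param unit one of `"HU"`, `"Gy"`, `"unitless"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         unit = c("unitless", "HU", "Gy")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, unit %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              x$unit))
  rng <- range(x$values, finite = TRUE)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Displacement vector field on the exhale grid
#'
#' Per-voxel 3-vectors (mm) defined on the exhale grid. The field maps an
#' exhale-phase world position `x` to its corresponding inhale-phase world
#' position `x + u(x)`.
#'
#' @param u numeric 4D array `c(nx, ny, nz, 3)` of displacements in mm.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("'u' must be a 4D array with 3 components on the last axis")
  if (any(!is.finite(u))) stop("displacement field must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("bad spacing")
  structure(list(u = u, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  mags <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d voxels, max |u| = %.3f mm\n",
              d[1], d[2], d[3], max(mags)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "displacement_field")) dim(a$u)[1:3] else dim(a$values)
  db <- if (inherits(b, "displacement_field")) dim(b$u)[1:3] else dim(b$values)
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxel centre world coordinates
#'
#' @param vol an [image_volume()] or [displacement_field()].
#' @return An `n x 3` matrix of world coordinates (mm), voxels in R array
#'   (column-major) order.
#' @export
voxel_coords <- function(vol) {
  d <- if (inherits(vol, "displacement_field")) dim(vol$u)[1:3] else dim(vol$values)
  ijk <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (n x 3 matrix). Returns list(values, valid); out-of-bounds
# points are invalid and NA. Fully vectorised.
trilinear_at <- function(a, p) {
  d <- dim(a)
  n <- nrow(p)
  valid <- p[, 1] >= 1 & p[, 1] <= d[1] &
           p[, 2] >= 1 & p[, 2] <= d[2] &
           p[, 3] >= 1 & p[, 3] <= d[3]
  valid[is.na(valid)] <- FALSE
  out <- rep(NA_real_, n)
  if (any(valid)) {
    q <- p[valid, , drop = FALSE]
    i0 <- pmin(floor(q[, 1]), d[1] - 1L); i0 <- pmax(i0, 1)
    j0 <- pmin(floor(q[, 2]), d[2] - 1L); j0 <- pmax(j0, 1)
    k0 <- pmin(floor(q[, 3]), d[3] - 1L); k0 <- pmax(k0, 1)
    fx <- q[, 1] - i0; fy <- q[, 2] - j0; fz <- q[, 3] - k0
    base <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
    v000 <- a[base(i0,     j0,     k0)]
    v100 <- a[base(i0 + 1, j0,     k0)]
    v010 <- a[base(i0,     j0 + 1, k0)]
    v110 <- a[base(i0 + 1, j0 + 1, k0)]
    v001 <- a[base(i0,     j0,     k0 + 1)]
    v101 <- a[base(i0 + 1, j0,     k0 + 1)]
    v011 <- a[base(i0,     j0 + 1, k0 + 1)]
    v111 <- a[base(i0 + 1, j0 + 1, k0 + 1)]
    out[valid] <-
      v000 * (1 - fx) * (1 - fy) * (1 - fz) +
      v100 * fx       * (1 - fy) * (1 - fz) +
      v010 * (1 - fx) * fy       * (1 - fz) +
      v110 * fx       * fy       * (1 - fz) +
      v001 * (1 - fx) * (1 - fy) * fz +
      v101 * fx       * (1 - fy) * fz +
      v011 * (1 - fx) * fy       * fz +
      v111 * fx       * fy       * fz
  }
  list(values = out, valid = valid)
}

# World (mm) -> continuous 1-based voxel coordinates of a grid.
world_to_voxel <- function(xyz, vol) {
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Sample an image volume at world positions
#'
#' Trilinear interpolation at arbitrary world coordinates; positions outside
#' the grid are flagged invalid and returned as `NA`.
#'
#' @param vol an [image_volume()].
#' @param xyz `n x 3` matrix of world coordinates in mm.
#' @return list with `values` (numeric n) and `valid` (logical n).
#' @export
sample_volume <- function(vol, xyz) {
  stopifnot(inherits(vol, "image_volume"))
  trilinear_at(vol$values, world_to_voxel(xyz, vol))
}

#' Resample a dose grid onto a reference grid
#'
#' Trilinear resampling of a dose volume onto the reference (exhale) grid.
#' Voxels of the reference grid falling outside the dose field of view are
#' assigned 0 Gy.
#'
#' @param dose an [image_volume()] with unit `"Gy"` (finite values).
#' @param reference an [image_volume()] defining the target grid.
#' @return An [image_volume()] on the reference grid.
#' @export
resample_dose <- function(dose, reference) {
  stopifnot(inherits(dose, "image_volume"), inherits(reference, "image_volume"))
  if (any(!is.finite(dose$values))) stop("dose must be finite")
  # reject disjoint fields of view
  lo_d <- dose$origin
  hi_d <- dose$origin + (dim(dose$values) - 1) * dose$spacing
  lo_r <- reference$origin
  hi_r <- reference$origin + (dim(reference$values) - 1) * reference$spacing
  if (any(hi_d < lo_r) || any(lo_d > hi_r))
    stop("dose grid does not overlap the reference grid")
  if (same_grid(dose, reference)) {
    return(image_volume(dose$values, reference$spacing, reference$origin, "Gy"))
  }
  s <- sample_volume(dose, voxel_coords(reference))
  v <- s$values
  v[!s$valid] <- 0
  out <- array(v, dim(reference$values))
  image_volume(out, reference$spacing, reference$origin, "Gy")
}

# Mask helper: coerce to logical array matching a volume's grid.
as_mask <- function(m) {
  if (inherits(m, "image_volume")) m <- m$values
  if (!is.array(m) || length(dim(m)) != 3L) stop("mask must be a 3D array")
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}
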