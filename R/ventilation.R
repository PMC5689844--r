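#' Warp the inhale volume onto the exhale grid
#'
#' For every exhale voxel, samples the inhale volume at the displaced world
#' position `x + u(x)` by trilinear interpolation. Samples falling outside
#' the inhale field of view are returned as `NA` and flagged in the
#' `valid` attribute.
#'
#' @param inhale inhale-phase [image_volume()].
#' @param dvf [displacement_field()] on the exhale grid (exhale -> inhale,
#'   mm).
#' @return An [image_volume()] on the exhale grid with a logical `valid`
#'   array attached as attribute `"valid"`.
#' @export
warp_to_exhale <- function(inhale, dvf) {
  stopifnot(inherits(inhale, "image_volume"),
            inherits(dvf, "displacement_field"))
  d <- dim(dvf$u)[1:3]
  x <- voxel_coords(dvf)
  disp <- cbind(as.vector(dvf$u[, , , 1]),
                as.vector(dvf$u[, , , 2]),
                as.vector(dvf$u[, , , 3]))
  s <- sample_volume(inhale, x + disp)
  out <- image_volume(array(s$values, d), dvf$spacing, dvf$origin, inhale$unit)
  attr(out, "valid") <- array(s$valid, d)
  out
}

#' Ventilation map from the HU density-change model
#'
#' Computes the per-voxel fractional air-volume change between exhale and
#' (registered) inhale CT,
#' \deqn{\frac{V_{in} - V_{ex}}{V_{ex}} =
#'       1000\,\frac{HU_{in} - HU_{ex}}{HU_{ex}\,(1000 + HU_{in})},}
#' evaluated inside the lung mask. The expression is singular at
#' \eqn{HU_{ex} = 0} and \eqn{HU_{in} = -1000}; voxels with either
#' denominator factor within `eps_den` HU of zero are excluded from the
#' valid mask rather than propagated as non-finite values.
#'
#' @param hu_exhale exhale-phase [image_volume()] in HU.
#' @param hu_inhale_warped inhale-phase HU volume already resampled onto the
#'   exhale grid (see [warp_to_exhale()]). May carry a `"valid"` attribute;
#'   invalid voxels are excluded.
#' @param lung_mask logical 3D array (or image_volume) of lung voxels.
#' @param eps_den denominator guard in HU (default 10).
#' @return A `vent_map`: list with `raw` ([image_volume()], unitless
#'   \eqn{\Delta V / V} masked to `NA` outside the lungs), `valid_mask`
#'   (logical array of evaluable lung voxels) and, after
#'   [normalize_ventilation()], `normalized`.
#' @export
compute_ventilation <- function(hu_exhale, hu_inhale_warped, lung_mask,
                                eps_den = 10) {
  stopifnot(inherits(hu_exhale, "image_volume"),
            inherits(hu_inhale_warped, "image_volume"))
  if (!same_grid(hu_exhale, hu_inhale_warped))
    stop("exhale and warped inhale volumes must share one grid")
  lung <- as_mask(lung_mask)
  if (!identical(dim(lung), dim(hu_exhale$values)))
    stop("lung mask grid mismatch")
  if (!any(lung)) stop("empty lung mask")

  ex <- hu_exhale$values
  inw <- hu_inhale_warped$values
  warp_valid <- attr(hu_inhale_warped, "valid")
  valid <- lung & is.finite(ex) & is.finite(inw) &
    abs(ex) >= eps_den & abs(1000 + inw) >= eps_den
  if (!is.null(warp_valid)) valid <- valid & warp_valid

  raw <- array(NA_real_, dim(ex))
  raw[valid] <- 1000 * (inw[valid] - ex[valid]) /
    (ex[valid] * (1000 + inw[valid]))

  structure(list(
    raw = image_volume(raw, hu_exhale$spacing, hu_exhale$origin, "unitless"),
    normalized = NULL,
    valid_mask = valid
  ), class = "vent_map")
}

#' @export
print.vent_map <- function(x, ...) {
  nv <- sum(x$valid_mask)
  rng <- range(x$raw$values[x$valid_mask])
  cat(sprintf("<vent_map> %d valid lung voxels, raw range [%.3f, %.3f]%s\n",
              nv, rng[1], rng[2],
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Percentile-normalise a ventilation map to [0, 1]
#'
#' Clips raw ventilation at the within-lung 1st and 99th percentiles and
#' rescales linearly to `[0, 1]`. The result is invariant under positive
#' affine transformations of the raw values and monotone in them. A constant
#' raw map normalises to 0.5 everywhere by convention (with a warning).
#'
#' @param vmap a `vent_map` from [compute_ventilation()].
#' @param probs lower/upper clip percentiles (default `c(0.01, 0.99)`).
#' @return The `vent_map` with its `normalized` field populated.
#' @export
normalize_ventilation <- function(vmap, probs = c(0.01, 0.99)) {
  stopifnot(inherits(vmap, "vent_map"))
  if (!any(vmap$valid_mask)) stop("valid mask is empty")
  raw <- vmap$raw$values
  q <- stats::quantile(raw[vmap$valid_mask], probs = probs, names = FALSE,
                       type = 7)
  norm <- array(NA_real_, dim(raw))
  if (q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2]))) {
    warning("constant ventilation map; normalized set to 0.5 by convention")
    norm[vmap$valid_mask] <- 0.5
  } else {
    v <- pmin(pmax(raw[vmap$valid_mask], q[1]), q[2])
    norm[vmap$valid_mask] <- (v - q[1]) / (q[2] - q[1])
  }
  vmap$normalized <- image_volume(norm, vmap$raw$spacing, vmap$raw$origin,
                                  "unitless")
  vmap
}

#' QA report for a displacement field
#'
#' Computes the Jacobian determinant of the mapping `x -> x + u(x)` by
#' central differences (one-sided at the grid faces) and summarises folding:
#' a non-positive determinant means the deformation locally inverts, which a
#' registration reviewer would flag as a discontinuity.
#'
#' @param dvf a [displacement_field()].
#' @return list of class `dvf_qa` with `min_jacobian`, `median_jacobian`,
#'   `folding_fraction` (det <= 0) and `max_displacement_mm`.
#' @export
qa_displacement_field <- function(dvf) {
  stopifnot(inherits(dvf, "displacement_field"))
  u <- dvf$u
  d <- dim(u)[1:3]
  sp <- dvf$spacing

  # d(u_c)/d(axis) by central differences, voxel units scaled by spacing
  grad <- function(comp, axis) {
    a <- u[, , , comp]
    n <- d[axis]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idx_p - idx_m) * sp[axis]
    if (axis == 1L) {
      g <- (a[idx_p, , , drop = FALSE] - a[idx_m, , , drop = FALSE]) /
        array(denom, d)
    } else if (axis == 2L) {
      g <- (a[, idx_p, , drop = FALSE] - a[, idx_m, , drop = FALSE]) /
        aperm(array(denom, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      g <- (a[, , idx_p, drop = FALSE] - a[, , idx_m, drop = FALSE]) /
        aperm(array(denom, d[c(3, 1, 2)]), c(2, 3, 1))
    }
    g
  }
  # J = I + du/dx
  j11 <- 1 + grad(1, 1); j12 <- grad(1, 2); j13 <- grad(1, 3)
  j21 <- grad(2, 1); j22 <- 1 + grad(2, 2); j23 <- grad(2, 3)
  j31 <- grad(3, 1); j32 <- grad(3, 2); j33 <- 1 + grad(3, 3)
  det <- j11 * (j22 * j33 - j23 * j32) -
         j12 * (j21 * j33 - j23 * j31) +
         j13 * (j21 * j32 - j22 * j31)

  mags <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  structure(list(
    min_jacobian = min(det),
    median_jacobian = stats::median(det),
    folding_fraction = mean(det <= 0),
    max_displacement_mm = max(mags),
    jacobian = det
  ), class = "dvf_qa")
}

#' @export
print.dvf_qa <- function(x, ...) {
  cat(sprintf(paste0("<dvf_qa> min|median Jacobian det %.3f | %.3f, ",
                     "folding %.2f%%, max displacement %.2f mm\n"),
              x$min_jacobian, x$median_jacobian, 100 * x$folding_fraction,
              x$max_displacement_mm))
  invisible(x)
}
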