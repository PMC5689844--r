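# 3D binary morphology with a radius-1 6-connected ball (cross), by array
# shifting. Erosion pads with FALSE (so the volume never grows at the
# boundary); dilation is its dual.
shift3 <- function(m, dx, dy, dz, pad) {
  d <- dim(m)
  out <- array(pad, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  tx <- sx - dx; ty <- sy - dy; tz <- sz - dz
  okx <- tx >= 1 & tx <= d[1]; oky <- ty >= 1 & ty <= d[2]
  okz <- tz >= 1 & tz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- m[tx[okx], ty[oky], tz[okz]]
  out
}

cross_offsets <- rbind(c(0, 0, 0),
                       c(1, 0, 0), c(-1, 0, 0),
                       c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))

erode3 <- function(m) {
  out <- m
  for (i in seq_len(nrow(cross_offsets))) {
    o <- cross_offsets[i, ]
    out <- out & shift3(m, o[1], o[2], o[3], FALSE)
  }
  out
}

dilate3 <- function(m) {
  out <- m
  for (i in seq_len(nrow(cross_offsets))) {
    o <- cross_offsets[i, ]
    out <- out | shift3(m, o[1], o[2], o[3], FALSE)
  }
  out
}

open3 <- function(m) dilate3(erode3(m))

#' Auto-segment the functional-avoid structure
#'
#' Thresholds the normalised ventilation map inside the lungs at the given
#' fraction, subtracts the gross and internal target volumes, and applies a
#' morphological opening with a 1-voxel-radius ball to remove isolated
#' speckle. The result is the high-function lung region a functional plan
#' should spare.
#'
#' @param vmap a `vent_map` with its `normalized` field populated (see
#'   [normalize_ventilation()]).
#' @param lung_left,lung_right lung masks.
#' @param gtv_mask,itv_mask target masks subtracted from the structure.
#' @param threshold fraction in (0, 1); lung voxels with normalised
#'   ventilation >= threshold are functional. A threshold of 0 is accepted
#'   and selects all lung.
#' @param opening apply the 1-voxel morphological opening (default TRUE).
#' @return An object of class `avoid_structure`: `mask` (logical array),
#'   `threshold`, `volume_cm3`, `provenance`.
#' @export
segment_functional_avoid <- function(vmap, lung_left, lung_right,
                                     gtv_mask, itv_mask, threshold = 0.15,
                                     opening = TRUE) {
  stopifnot(inherits(vmap, "vent_map"))
  if (is.null(vmap$normalized))
    stop("ventilation map has not been normalised; run normalize_ventilation()")
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  lung <- as_mask(lung_left) | as_mask(lung_right)
  tgt <- as_mask(gtv_mask) | as_mask(itv_mask)
  norm <- vmap$normalized$values

  mask <- lung & vmap$valid_mask & !is.na(norm) & norm >= threshold & !tgt
  if (opening) mask <- open3(mask) & !tgt
  if (!any(mask))
    warning("functional-avoid structure is empty at threshold ", threshold)

  vox_cm3 <- prod(vmap$raw$spacing) / 1000
  structure(list(mask = mask, threshold = threshold,
                 volume_cm3 = sum(mask) * vox_cm3,
                 provenance = list(opening = opening,
                                   opening_radius_voxels = if (opening) 1L else 0L,
                                   targets_subtracted = c("gtv", "itv"))),
            class = "avoid_structure")
}

#' @export
print.avoid_structure <- function(x, ...) {
  cat(sprintf("<avoid_structure> %d voxels (%.1f cm^3) at threshold %.2f\n",
              sum(x$mask), x$volume_cm3, x$threshold))
  invisible(x)
}
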