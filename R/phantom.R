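#' Specification of a digital thorax phantom
#'
#' Describes one synthetic case: grid geometry, two ellipsoidal lungs, a
#' spherical tumor placed in a lung third, an optional ventilation defect
#' (Gaussian profile, multiplicative severity), a smooth craniocaudal
#' breathing deformation, and HU noise. All downstream stages (ventilation,
#' eligibility, avoidance, dose-function) can be validated against the
#' ground truth the phantom carries.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 16).
#' @param spacing mm per voxel along each axis.
#' @param lung_geometry list with `left`/`right`, each holding
#'   `center_frac` and `semiaxes_frac` (fractions of the physical field of
#'   view) for an ellipsoidal lung.
#' @param tumor list: `third` (1-6, see [partition_thirds()] labelling:
#'   1-3 = left upper/middle/lower, 4-6 = right upper/middle/lower) and
#'   `radius_mm`.
#' @param defect list: `present`, `third` (defaults to the tumor third),
#'   `severity` in \[0, 1\] (1 = no ventilation at the defect centre),
#'   `extent_mm` (Gaussian sigma = extent/2).
#' @param deformation_mm peak craniocaudal displacement amplitude (>= 0).
#' @param noise_sd additive Gaussian HU noise applied independently to the
#'   exhale and inhale volumes.
#' @param background_vent uniform baseline \eqn{\Delta V/V} inside the lungs.
#' @param exhale_air_fraction lung air fraction at exhale; lung HU is
#'   `-1000 * air fraction`.
#' @param prescription_gy PTV prescription used by [synthesize_dose()].
#' @param seed integer RNG seed; the phantom is bit-reproducible given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing = c(5, 5, 5),
                         lung_geometry = default_lung_geometry(),
                         tumor = list(third = 3, radius_mm = 14),
                         defect = list(present = TRUE, third = NULL,
                                       severity = 0.8, extent_mm = 35),
                         deformation_mm = 10,
                         noise_sd = 0,
                         background_vent = 0.3,
                         exhale_air_fraction = 0.85,
                         prescription_gy = 60,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must have 3 entries, each >= 16")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (deformation_mm < 0) stop("deformation amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  defect <- utils::modifyList(
    list(present = TRUE, third = NULL, severity = 0.8, extent_mm = 35),
    defect)
  if (is.null(defect$third)) defect$third <- tumor$third
  if (defect$severity < 0 || defect$severity > 1)
    stop("defect severity must lie in [0, 1]")
  if (!tumor$third %in% 1:6 || !defect$third %in% 1:6)
    stop("tumor and defect thirds must be in 1..6")
  if (background_vent <= 0) stop("background_vent must be positive")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 lung_geometry = lung_geometry, tumor = tumor,
                 defect = defect, deformation_mm = deformation_mm,
                 noise_sd = noise_sd, background_vent = background_vent,
                 exhale_air_fraction = exhale_air_fraction,
                 prescription_gy = prescription_gy,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_lung_geometry <- function() {
  list(left  = list(center_frac = c(0.31, 0.48, 0.52),
                    semiaxes_frac = c(0.15, 0.23, 0.34), z_exponent = 4),
       right = list(center_frac = c(0.69, 0.48, 0.52),
                    semiaxes_frac = c(0.15, 0.23, 0.34), z_exponent = 4))
}

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Superellipsoid: quadratic in-plane, optionally flatter (blunt apex/base)
# along z with a higher exponent, which is closer to real lung shape than a
# pure ellipsoid.
ellipsoid_mask <- function(xyz, center, semiaxes, d, z_exponent = 2) {
  r2 <- ((xyz[, 1] - center[1]) / semiaxes[1])^2 +
        ((xyz[, 2] - center[2]) / semiaxes[2])^2 +
        abs((xyz[, 3] - center[3]) / semiaxes[3])^z_exponent
  array(r2 <= 1, d)
}

sphere_mask <- function(xyz, center, radius, d) {
  r2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2
  array(r2 <= radius^2, d)
}

cylinder_mask <- function(xyz, cx, cy, radius, zlim, d) {
  r2 <- (xyz[, 1] - cx)^2 + (xyz[, 2] - cy)^2
  array(r2 <= radius^2 & xyz[, 3] >= zlim[1] & xyz[, 3] <= zlim[2], d)
}

# Centroid (world mm) of the lung voxels belonging to a given third label,
# computed from analytic lung geometry before any partition object exists.
third_centroid <- function(xyz, lung_l, lung_r, third) {
  lung <- if (third <= 3) lung_l else lung_r
  z <- xyz[, 3][lung]
  zr <- range(z)
  h <- (zr[2] - zr[1]) / 3
  band <- switch(((third - 1) %% 3) + 1,
                 c(zr[2] - h, zr[2]),      # upper
                 c(zr[1] + h, zr[2] - h),  # middle
                 c(zr[1], zr[1] + h))      # lower
  sel <- lung & xyz[, 3] >= band[1] & xyz[, 3] <= band[2]
  colMeans(xyz[sel, , drop = FALSE])
}

# Closed-form inversion of the density-change model: the inhale HU that
# yields ventilation v at exhale HU `hu_ex`. Clamped to [-1000, 0].
invert_hu_model <- function(hu_ex, v) {
  hu_in <- 1000 * hu_ex * (1 + v) / (1000 - v * hu_ex)
  pmin(pmax(hu_in, -1000), 0)
}

#' Generate one digital thorax phantom case
#'
#' Builds the full synthetic case: exhale HU volume (lung HU = -1000 x air
#' fraction), ground-truth ventilation `vent_true`, a fold-free analytic
#' craniocaudal displacement field `dvf_true`, and an inhale HU volume
#' constructed so that warping it back through `dvf_true` and applying the
#' density-change model recovers `vent_true` up to interpolation error.
#' Structure masks (lungs, GTV/ITV/PTV, cord, heart, esophagus) and paired
#' clinical/functional analytic dose distributions are attached.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `hu_exhale`,
#'   `hu_inhale`, `dvf_true`, `vent_true`, `masks` (named list of logical
#'   arrays), `defect_label`, `dose_clinical`, `dose_functional`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  fov <- (d - 1) * sp
  geom <- image_volume(array(0, d), sp, c(0, 0, 0))
  xyz <- voxel_coords(geom)

  lg <- spec$lung_geometry
  # anatomical lung parenchyma (drives HU and ventilation ground truth)
  zexp_l <- if (is.null(lg$left$z_exponent)) 2 else lg$left$z_exponent
  zexp_r <- if (is.null(lg$right$z_exponent)) 2 else lg$right$z_exponent
  lung_hu_l <- ellipsoid_mask(xyz, lg$left$center_frac * fov,
                              lg$left$semiaxes_frac * fov, d, zexp_l)
  lung_hu_r <- ellipsoid_mask(xyz, lg$right$center_frac * fov,
                              lg$right$semiaxes_frac * fov, d, zexp_r)
  lung <- lung_hu_l | lung_hu_r
  # segmented lung masks: eroded inside the parenchyma so that, as in
  # clinical lung segmentation, partial-volume voxels at the pleural
  # interface are excluded from analysis
  lung_l <- lung_hu_l; lung_r <- lung_hu_r
  for (it in seq_len(2)) { lung_l <- erode3(lung_l); lung_r <- erode3(lung_r) }
  if (!any(lung_l) || !any(lung_r))
    stop("degenerate lung geometry: an empty lung mask was produced")

  # body: elliptic cylinder enclosing both lungs
  body <- ellipsoid_mask(cbind(xyz[, 1:2], 0.5 * fov[3]),
                         c(0.5, 0.5, 0.5) * fov,
                         c(0.46, 0.40, 10) * fov, d) &
    array(xyz[, 3] >= 0.06 * fov[3] & xyz[, 3] <= 0.97 * fov[3], d)
  body <- body | lung

  # ground-truth ventilation: uniform background, optional defect
  vent <- array(0, d)
  vent[lung] <- spec$background_vent
  if (isTRUE(spec$defect$present) && spec$defect$severity > 0) {
    dc <- third_centroid(xyz, lung_l, lung_r, spec$defect$third)
    sigma <- spec$defect$extent_mm / 2
    r2 <- (xyz[, 1] - dc[1])^2 + (xyz[, 2] - dc[2])^2 + (xyz[, 3] - dc[3])^2
    g <- array(exp(-r2 / (2 * sigma^2)), d)
    vent[lung] <- vent[lung] * (1 - spec$defect$severity * g[lung])
  }

  # exhale HU: lungs at -1000 * air fraction, soft tissue 40 HU, air outside
  hu_ex <- array(-1000, d)
  hu_ex[body] <- 40
  hu_ex[lung] <- -1000 * spec$exhale_air_fraction

  # warped-inhale HU on the exhale grid, by exact model inversion in lung
  hu_in_warped <- hu_ex
  hu_in_warped[lung] <- invert_hu_model(hu_ex[lung], vent[lung])

  # craniocaudal deformation: u_z = -A sin(pi (z - z0)/L) over the lung
  # extent, zero outside; fold-free iff A pi / L < 1
  zlung <- range(xyz[, 3][lung])
  z0 <- zlung[1] - 2 * sp[3]
  L <- (zlung[2] + 2 * sp[3]) - z0
  amp <- spec$deformation_mm
  if (amp * pi / L >= 0.95)
    stop("deformation amplitude too large for a fold-free field")
  uz_of <- function(z) {
    s <- (z - z0) / L
    ifelse(s > 0 & s < 1, -amp * sin(pi * s), 0)
  }
  u <- array(0, c(d, 3L))
  u[, , , 3] <- array(uz_of(xyz[, 3]), d)
  dvf <- displacement_field(u, sp, c(0, 0, 0))

  # inhale volume I with I(x + u(x)) = hu_in_warped(x): invert the monotone
  # 1D map phi(z) = z + u_z(z) on a dense table, then resample each column
  zw <- (seq_len(d[3]) - 1) * sp[3]
  zt <- seq(min(zw) - sp[3], max(zw) + sp[3], length.out = 4096)
  phi <- zt + uz_of(zt)
  zsrc <- stats::approx(phi, zt, xout = zw, rule = 2)$y
  kf <- zsrc / sp[3] + 1  # continuous slice index into hu_in_warped
  k0 <- pmin(pmax(floor(kf), 1), d[3] - 1)
  fz <- kf - k0
  hu_in <- array(0, d)
  for (k in seq_len(d[3])) {
    hu_in[, , k] <- hu_in_warped[, , k0[k]] * (1 - fz[k]) +
                    hu_in_warped[, , k0[k] + 1] * fz[k]
  }

  if (spec$noise_sd > 0) {
    hu_ex <- hu_ex + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    hu_in <- hu_in + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  }

  # target volumes: GTV sphere at the tumor-third centroid, ITV/PTV margins
  tc <- third_centroid(xyz, lung_l, lung_r, spec$tumor$third)
  gtv <- sphere_mask(xyz, tc, spec$tumor$radius_mm, d)
  itv <- sphere_mask(xyz, tc, spec$tumor$radius_mm + 3, d)
  ptv <- sphere_mask(xyz, tc, spec$tumor$radius_mm + 8, d)
  if (!any(gtv)) stop("tumor radius below grid resolution")

  # OARs: geometric primitives placed deterministically
  cord <- cylinder_mask(xyz, 0.5 * fov[1], 0.80 * fov[2], 6,
                        c(0, fov[3]), d)
  heart <- ellipsoid_mask(xyz, c(0.46, 0.40, 0.35) * fov,
                          c(0.13, 0.12, 0.14) * fov, d)
  esophagus <- cylinder_mask(xyz, 0.52 * fov[1], 0.62 * fov[2], 5,
                             c(0.1, 0.9) * fov[3], d)

  masks <- list(lung_L = lung_l, lung_R = lung_r, gtv = gtv, itv = itv,
                ptv = ptv, cord = cord, heart = heart,
                esophagus = esophagus, body = body)

  case <- structure(list(
    hu_exhale = image_volume(hu_ex, sp, c(0, 0, 0), "HU"),
    hu_inhale = image_volume(hu_in, sp, c(0, 0, 0), "HU"),
    dvf_true = dvf,
    vent_true = image_volume(vent, sp, c(0, 0, 0), "unitless"),
    masks = masks,
    defect_label = as.integer(isTRUE(spec$defect$present) &&
                                spec$defect$severity > 0),
    spec = spec
  ), class = "phantom_case")

  case$dose_clinical <- synthesize_dose(case, "clinical")
  case$dose_functional <- synthesize_dose(case, "functional")
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$hu_exhale$values)
  cat(sprintf(paste0("<phantom_case> %d x %d x %d @ %s mm, defect=%d, ",
                     "tumor third %d, Rx %.0f Gy\n"),
              d[1], d[2], d[3],
              paste(format(x$spec$spacing), collapse = "x"),
              x$defect_label, x$spec$tumor$third, x$spec$prescription_gy))
  invisible(x)
}

#' Analytic paired dose synthesis
#'
#' Superposes Gaussian-profile divergent beams aimed at the PTV centroid
#' with a linear depth falloff. The `"clinical"` style weights all beams
#' equally. The `"functional"` style emulates favorable-arc selection:
#' each beam is scored by its functional-lung burden per unit of PTV dose
#' (the ventilation-weighted dose its kernel deposits in lung divided by
#' the dose it delivers to the PTV), the `n_select` lowest-burden beams
#' keep full weight, and the rest are down-weighted to `floor_weight` —
#' mirroring how a planner restricts arcs to directions traversing poorly
#' ventilated lung. When the ventilation map carries no spatial signal
#' (path-mean ventilation identical for every beam, e.g. a uniform map) the
#' tie rule keeps all weights equal and the functional plan reproduces the
#' clinical plan exactly. Both styles are scaled so the PTV mean dose
#' equals the prescription, hence PTV mean doses match across styles by
#' construction.
#'
#' @param case a `phantom_case` (the dose fields need not be present yet).
#' @param style `"clinical"` or `"functional"`.
#' @param n_beams number of equispaced coplanar beam angles.
#' @param n_select number of favorable beams retained at full weight.
#' @param floor_weight residual weight of de-selected beams (keeps every
#'   direction deliverable, as partial arcs do).
#' @return An [image_volume()] in Gy on the case grid.
#' @export
synthesize_dose <- function(case, style = c("clinical", "functional"),
                            n_beams = 9, n_select = 3, floor_weight = 0.15) {
  style <- match.arg(style)
  masks <- case$masks
  if (!any(masks$ptv)) stop("PTV is empty")
  vol <- case$hu_exhale
  d <- dim(vol$values)
  xyz <- voxel_coords(vol)
  ptv_idx <- which(masks$ptv)
  cen <- colMeans(xyz[ptv_idx, , drop = FALSE])
  ptv_r <- max(sqrt(rowSums(sweep(xyz[ptv_idx, , drop = FALSE], 2, cen)^2)))
  sigma0 <- ptv_r + 4

  lung <- masks$lung_L | masks$lung_R
  v <- pmax(case$vent_true$values, 0)
  vbar <- mean(v[lung])

  angles <- 2 * pi * (seq_len(n_beams) - 1) / n_beams
  wx <- xyz[, 1] - cen[1]; wy <- xyz[, 2] - cen[2]; wz <- xyz[, 3] - cen[3]
  total <- numeric(prod(d))
  kernels <- vector("list", n_beams)
  burden <- numeric(n_beams)    # ventilation-weighted lung dose per PTV dose
  enrich <- numeric(n_beams)    # path-mean ventilation relative to lung mean
  for (b in seq_len(n_beams)) {
    e <- c(cos(angles[b]), sin(angles[b]), 0)
    t <- wx * e[1] + wy * e[2]
    r2 <- wx^2 + wy^2 + wz^2 - t^2
    sig <- sigma0 * (1000 + t) / 1000   # divergence from a 1 m source
    depth <- t + 150                     # mm past a nominal entry plane
    k <- exp(-r2 / (2 * sig^2)) * pmax(0, 1 - depth / 600)
    kernels[[b]] <- k
    sk <- sum(k[lung]); sp_ptv <- sum(k[ptv_idx])
    burden[b] <- if (sp_ptv > 0) sum(k[lung] * v[lung]) / sp_ptv else Inf
    enrich[b] <- if (sk > 0 && vbar > 0) sum(k[lung] * v[lung]) / (vbar * sk) else 1
  }
  w <- rep(1, n_beams)
  if (style == "functional" && diff(range(enrich)) > 1e-9) {
    keep <- order(burden)[seq_len(min(n_select, n_beams))]
    w[-keep] <- floor_weight
  }
  for (b in seq_len(n_beams)) total <- total + w[b] * kernels[[b]]
  scale <- case$spec$prescription_gy / mean(total[ptv_idx])
  image_volume(array(scale * total, d), vol$spacing, vol$origin, "Gy")
}

#' Generate a cohort of phantom cases
#'
#' Draws per-patient defect status from a Bernoulli distribution at the
#' requested prevalence, with defect severity uniform on `severity_range`,
#' a uniformly random tumor third, and the defect placed in the tumor third
#' or (with probability 0.4) one of its adjacent thirds — emulating a stage
#' III cohort in which defects sit near the primary tumor. Per-case seeds
#' are derived deterministically from the cohort seed.
#'
#' @param n_patients number of cases (>= 1).
#' @param defect_prevalence fraction in \[0, 1\].
#' @param severity_range length-2 numeric, uniform severity range for
#'   defect-positive cases.
#' @param seed cohort RNG seed.
#' @param grid_shape,spacing per-case grid geometry.
#' @param noise_sd HU noise per case.
#' @param deformation_mm breathing amplitude per case.
#' @param defect_extent_mm defect Gaussian extent; the default produces
#'   lobar-scale ("major") defects that substantially empty their third.
#' @return An object of class `phantom_cohort`: list with `cases` (list of
#'   `phantom_case`) and `labels` (data.frame patient_id, defect_label,
#'   seed).
#' @export
generate_cohort <- function(n_patients, defect_prevalence,
                            severity_range = c(0.6, 0.95), seed = 1L,
                            grid_shape = c(32, 32, 32),
                            spacing = c(7.5, 7.5, 7.5),
                            noise_sd = 5, deformation_mm = 10,
                            defect_extent_mm = 70) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (defect_prevalence < 0 || defect_prevalence > 1)
    stop("defect_prevalence must lie in [0, 1]")
  draws <- with_seed(as.integer(seed), {
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      defect_label = as.integer(stats::runif(n_patients) < defect_prevalence),
      severity = stats::runif(n_patients, severity_range[1], severity_range[2]),
      tumor_third = sample.int(6, n_patients, replace = TRUE),
      defect_at_tumor = stats::runif(n_patients) < 0.6,
      adj_pick = stats::runif(n_patients),
      seed = (as.integer(seed) + 7919L * seq_len(n_patients)) %% 2147483647L
    )
  })
  cases <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    tt <- draws$tumor_third[i]
    adj <- third_neighbours(tt)
    dt <- if (draws$defect_at_tumor[i]) tt
          else adj[1 + floor(draws$adj_pick[i] * length(adj))]
    sev <- if (draws$defect_label[i] == 1L) draws$severity[i] else 0
    spec <- phantom_spec(
      grid_shape = grid_shape, spacing = spacing,
      tumor = list(third = tt, radius_mm = 14),
      defect = list(present = draws$defect_label[i] == 1L, third = dt,
                    severity = sev, extent_mm = defect_extent_mm),
      deformation_mm = deformation_mm, noise_sd = noise_sd,
      seed = draws$seed[i])
    cases[[i]] <- generate_phantom(spec)
  }
  structure(list(cases = cases,
                 labels = draws[, c("patient_id", "defect_label", "seed")]),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, %d with defects\n",
              length(x$cases), sum(x$labels$defect_label)))
  invisible(x)
}

# Thirds directly superior, inferior, or contralateral-same-level to a
# third label (1-3 left upper/middle/lower, 4-6 right).
third_neighbours <- function(third) {
  lungbase <- if (third <= 3) 0L else 3L
  level <- third - lungbase            # 1 upper, 2 middle, 3 lower
  out <- integer(0)
  if (level > 1) out <- c(out, lungbase + level - 1L)   # superior
  if (level < 3) out <- c(out, lungbase + level + 1L)   # inferior
  out <- c(out, (if (lungbase == 0L) 3L else 0L) + level)  # contralateral
  sort(out)
}
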