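# Cumulative DVH of a dose vector at fixed bin width (Gy). Returns
# data.frame(dose, volume_pct): percent of voxels with dose >= bin edge.
cumulative_dvh <- function(doses, bin_gy = 0.1) {
  if (length(doses) == 0) stop("empty structure")
  top <- max(doses, 0)
  edges <- seq(0, top + bin_gy, by = bin_gy)
  vol <- vapply(edges, function(e) mean(doses >= e) * 100, numeric(1))
  data.frame(dose = edges, volume_pct = vol)
}

# Dx: dose (Gy) exceeded by x% of the structure volume, linearly
# interpolated between DVH bins.
dvh_dx <- function(dvh, x) {
  v <- dvh$volume_pct
  d <- dvh$dose
  if (x >= v[1]) return(d[1])
  i <- max(which(v >= x))
  if (i == length(v) || v[i] == v[i + 1]) return(d[i])
  d[i] + (d[i + 1] - d[i]) * (v[i] - x) / (v[i] - v[i + 1])
}

vx_pct <- function(doses, x) mean(doses >= x) * 100

#' Standard dose-volume metrics for a plan
#'
#' Computes PTV coverage statistics, homogeneity index (HI = D90%/D5% of
#' the PTV), conformity index (CI = prescription-isodose volume / PTV
#' volume), mean lung dose over lungs-minus-GTV, lung V20, and the OAR
#' summary doses used by RTOG-0617-style thoracic constraints. Dx values
#' are read off a 0.1 Gy-binned cumulative DVH with linear interpolation.
#'
#' @param dose an [image_volume()] in Gy on the structure grid.
#' @param masks named list with `ptv`, `lung_L`, `lung_R`, `gtv`, and
#'   optionally `cord`, `heart`, `esophagus` (missing structures yield `NA`
#'   metrics).
#' @param prescription_gy prescription dose defining the CI isodose.
#' @param exclude_gtv_from_lung use lungs-minus-GTV for MLD/V20 (default
#'   TRUE, the RTOG total-lung convention).
#' @param bin_gy DVH bin width (default 0.1 Gy).
#' @return list of class `dose_summary`.
#' @export
dose_volume_metrics <- function(dose, masks, prescription_gy,
                                exclude_gtv_from_lung = TRUE,
                                bin_gy = 0.1) {
  stopifnot(inherits(dose, "image_volume"))
  dv <- dose$values
  get_doses <- function(name) {
    m <- masks[[name]]
    if (is.null(m) || !any(m <- as_mask(m))) return(NULL)
    dv[m]
  }
  ptv_d <- get_doses("ptv")
  if (is.null(ptv_d)) stop("PTV is empty or missing")
  lung <- as_mask(masks$lung_L) | as_mask(masks$lung_R)
  if (exclude_gtv_from_lung && !is.null(masks$gtv))
    lung <- lung & !as_mask(masks$gtv)
  lung_d <- dv[lung]

  dvh_ptv <- cumulative_dvh(ptv_d, bin_gy)
  d90 <- dvh_dx(dvh_ptv, 90)
  d5 <- dvh_dx(dvh_ptv, 5)
  hi <- if (d5 > 0) d90 / d5 else NA_real_
  ci <- sum(dv >= prescription_gy) / length(ptv_d)

  oar_mean <- function(name) {
    x <- get_doses(name); if (is.null(x)) NA_real_ else mean(x)
  }
  structure(list(
    ptv_min = min(ptv_d), ptv_max = max(ptv_d), ptv_mean = mean(ptv_d),
    hi = hi, ci = ci,
    mld = mean(lung_d), lung_v20 = vx_pct(lung_d, 20),
    esophagus_mean = oar_mean("esophagus"),
    heart_mean = oar_mean("heart"),
    cord_max = { x <- get_doses("cord"); if (is.null(x)) NA_real_ else max(x) },
    prescription_gy = prescription_gy
  ), class = "dose_summary")
}

#' @export
print.dose_summary <- function(x, ...) {
  cat(sprintf(paste0("<dose_summary> PTV [%.1f, %.1f] Gy, HI %.3f, CI %.2f, ",
                     "MLD %.2f Gy, lung V20 %.1f%%\n"),
              x$ptv_min, x$ptv_max, x$hi, x$ci, x$mld, x$lung_v20))
  if (!is.null(x$sf_mld))
    cat(sprintf("  SfMLD %.2f Gy, SfV5/V10/V20 %.1f/%.1f/%.1f%%\n",
                x$sf_mld, x$sf_v["5"], x$sf_v["10"], x$sf_v["20"]))
  if (!is.null(x$imf_mld))
    cat(sprintf("  ImfMLD %.2f Gy, ImfV5/V10/V20 %.1f/%.1f/%.1f%%\n",
                x$imf_mld, x$imf_v["5"], x$imf_v["10"], x$imf_v["20"]))
  invisible(x)
}

#' Structure-based dose-function metrics
#'
#' Mean dose to the functional-avoid structure (SfMLD) and the percentage
#' of the structure receiving at least x Gy (SfVx) for x in
#' {5, 10, 20, 30, 40}.
#'
#' @param dose an [image_volume()] in Gy.
#' @param avoid an `avoid_structure` (see [segment_functional_avoid()]).
#' @param levels Gy thresholds for the Vx family.
#' @return list with `sf_mld` and named vector `sf_v`; all `NA` when the
#'   avoid structure is empty.
#' @export
structure_dose_function_metrics <- function(dose, avoid,
                                            levels = c(5, 10, 20, 30, 40)) {
  stopifnot(inherits(dose, "image_volume"), inherits(avoid, "avoid_structure"))
  if (!any(avoid$mask)) {
    sf_v <- stats::setNames(rep(NA_real_, length(levels)), levels)
    return(list(sf_mld = NA_real_, sf_v = sf_v))
  }
  d <- dose$values[avoid$mask]
  sf_v <- stats::setNames(vapply(levels, function(x) vx_pct(d, x), numeric(1)),
                          levels)
  list(sf_mld = mean(d), sf_v = sf_v)
}

#' Image-based dose-function metrics (dose-function histogram)
#'
#' Weights every lung voxel by its raw ventilation (floored at zero) and
#' computes the functionally weighted mean lung dose
#' \eqn{\mathrm{ImfMLD} = \sum_i w_i D_i / \sum_i w_i} and functional
#' \eqn{V_x = 100 \sum_i w_i 1[D_i \ge x] / \sum_i w_i} for x in
#' {5, 10, 20, 30}. The cumulative dose-function histogram is returned at
#' 0.1 Gy resolution. All metrics are invariant to positive rescaling of
#' the weights.
#'
#' @param dose an [image_volume()] in Gy.
#' @param vmap a `vent_map` (raw values are the weights).
#' @param lung_left,lung_right lung masks.
#' @param levels Gy thresholds for the fVx family.
#' @param bin_gy histogram resolution.
#' @return list with `imf_mld`, named vector `imf_v`, and `dfh`
#'   (data.frame dose, function_pct).
#' @export
image_dose_function_metrics <- function(dose, vmap, lung_left, lung_right,
                                        levels = c(5, 10, 20, 30),
                                        bin_gy = 0.1) {
  stopifnot(inherits(dose, "image_volume"), inherits(vmap, "vent_map"))
  lung <- as_mask(lung_left) | as_mask(lung_right)
  ok <- lung & vmap$valid_mask
  w <- pmax(vmap$raw$values[ok], 0)
  dd <- dose$values[ok]
  tw <- sum(w)
  if (!is.finite(tw) || tw <= 0)
    stop("total ventilation weight is zero; dose-function metrics undefined")
  imf_mld <- sum(w * dd) / tw
  imf_v <- stats::setNames(
    vapply(levels, function(x) sum(w * (dd >= x)) / tw * 100, numeric(1)),
    levels)
  edges <- seq(0, max(dd, 0) + bin_gy, by = bin_gy)
  dfh <- data.frame(
    dose = edges,
    function_pct = vapply(edges, function(e) sum(w * (dd >= e)) / tw * 100,
                          numeric(1)))
  list(imf_mld = imf_mld, imf_v = imf_v, dfh = dfh)
}

#' Full dose and dose-function summary for one plan
#'
#' Convenience wrapper combining [dose_volume_metrics()],
#' [structure_dose_function_metrics()] and [image_dose_function_metrics()]
#' into a single flat summary.
#'
#' @inheritParams dose_volume_metrics
#' @param avoid an `avoid_structure`.
#' @param vmap a `vent_map`.
#' @return A `dose_summary` with `sf_mld`, `sf_v`, `imf_mld`, `imf_v`
#'   fields added.
#' @export
plan_summary <- function(dose, masks, avoid, vmap, prescription_gy, ...) {
  out <- dose_volume_metrics(dose, masks, prescription_gy, ...)
  sf <- structure_dose_function_metrics(dose, avoid)
  imf <- image_dose_function_metrics(dose, vmap, masks$lung_L, masks$lung_R)
  out$sf_mld <- sf$sf_mld; out$sf_v <- sf$sf_v
  out$imf_mld <- imf$imf_mld; out$imf_v <- imf$imf_v
  out
}

# Flatten a dose_summary into a named numeric vector for tabulation.
summary_to_row <- function(s) {
  c(ptv_min = s$ptv_min, ptv_max = s$ptv_max, ptv_mean = s$ptv_mean,
    ci = s$ci, hi = s$hi, mld = s$mld, lung_v20 = s$lung_v20,
    esophagus_mean = s$esophagus_mean, heart_mean = s$heart_mean,
    cord_max = s$cord_max,
    sf_mld = if (is.null(s$sf_mld)) NA_real_ else s$sf_mld,
    stats::setNames(if (is.null(s$sf_v)) rep(NA_real_, 5) else s$sf_v,
                    paste0("sf_v", c(5, 10, 20, 30, 40))),
    imf_mld = if (is.null(s$imf_mld)) NA_real_ else s$imf_mld,
    stats::setNames(if (is.null(s$imf_v)) rep(NA_real_, 4) else s$imf_v,
                    paste0("imf_v", c(5, 10, 20, 30))))
}

#' Paired comparison of clinical and functional plans
#'
#' For each metric: the clinical and functional cohort means, the mean
#' paired difference (functional minus clinical) with its range, and a
#' two-sided paired t-test p-value. Metric pairs with zero variance in the
#' differences get p = 1 by convention.
#'
#' @param clinical,functional lists of `dose_summary` objects of equal
#'   length, paired by patient.
#' @return An object of class `plan_comparison`: data.frame `table` with
#'   one row per metric, plus the per-patient difference matrix `diffs`.
#' @export
compare_plans <- function(clinical, functional) {
  if (length(clinical) != length(functional))
    stop("clinical and functional summaries must be paired")
  if (length(clinical) < 2) stop("need at least 2 paired cases")
  cm <- t(vapply(clinical, summary_to_row, summary_to_row(clinical[[1]])))
  fm <- t(vapply(functional, summary_to_row, summary_to_row(functional[[1]])))
  diffs <- fm - cm
  metrics <- colnames(cm)
  rows <- lapply(metrics, function(m) {
    dc <- cm[, m]; df <- fm[, m]; dd <- diffs[, m]
    ok <- is.finite(dd)
    if (sum(ok) < 2) {
      return(data.frame(metric = m, clinical_mean = mean(dc, na.rm = TRUE),
                        functional_mean = mean(df, na.rm = TRUE),
                        mean_diff = NA_real_, min_diff = NA_real_,
                        max_diff = NA_real_, p_value = NA_real_))
    }
    dd <- dd[ok]
    p <- if (stats::sd(dd) == 0) 1
         else stats::t.test(df[ok], dc[ok], paired = TRUE)$p.value
    data.frame(metric = m, clinical_mean = mean(dc[ok]),
               functional_mean = mean(df[ok]), mean_diff = mean(dd),
               min_diff = min(dd), max_diff = max(dd), p_value = p)
  })
  structure(list(table = do.call(rbind, rows), diffs = diffs,
                 n = length(clinical)),
            class = "plan_comparison")
}

#' @export
print.plan_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<plan_comparison> %d paired plans (functional - clinical)\n",
              x$n))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
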