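#' Partition the lungs into craniocaudal thirds
#'
#' Splits each lung's craniocaudal bounding extent into three equal-height
#' slabs, the convention used for regional quantification in VQ imaging to
#' approximate lobes. Labels: 1-3 = left upper/middle/lower, 4-6 = right
#' upper/middle/lower ("upper" = superior, increasing z). Voxels falling
#' exactly on a slab boundary are assigned to the inferior slab. The third
#' containing the GTV centroid and the set of thirds directly superior,
#' inferior, or contralateral-same-level to it are recorded.
#'
#' @param lung_left,lung_right logical 3D arrays (or image_volumes).
#' @param gtv_mask logical 3D array, the gross target volume.
#' @param spacing voxel spacing in mm (used only for centroid distances).
#' @return An object of class `thirds_partition`: list with `labels`
#'   (integer array, 0 outside lung), `tumor_third`, `adjacency`,
#'   `ipsilateral` (`"left"` or `"right"`).
#' @export
partition_thirds <- function(lung_left, lung_right, gtv_mask,
                             spacing = c(1, 1, 1)) {
  ll <- as_mask(lung_left); lr <- as_mask(lung_right)
  gtv <- as_mask(gtv_mask)
  if (!any(ll) || !any(lr)) stop("both lungs must be nonempty")
  d <- dim(ll)
  labels <- array(0L, d)

  kz <- function(mask) {
    # slice index (3rd axis) of every voxel in mask
    arrayInd(which(mask), d)[, 3]
  }
  assign_lung <- function(mask, base) {
    idx <- which(mask)
    z <- arrayInd(idx, d)[, 3]
    zr <- range(z)
    h <- (zr[2] - zr[1] + 1) / 3
    # slab from the top: upper = highest z; boundary ties go inferior,
    # i.e. a voxel exactly on the cut belongs to the lower slab
    from_top <- zr[2] - z          # 0 at most-superior slice
    level <- 1L + pmin(2L, floor(from_top / h + 1e-9))
    # ties: voxel exactly at a cut (from_top/h integer > 0) -> inferior slab
    on_cut <- abs(from_top / h - round(from_top / h)) < 1e-9 & from_top > 0 &
      round(from_top / h) %in% c(1, 2)
    level[on_cut] <- round(from_top / h)[on_cut] + 1L
    labels[idx] <<- base + pmin(level, 3L)
  }
  assign_lung(ll, 0L)
  assign_lung(lr, 3L)

  # tumor third from the GTV centroid; fall back to nearest lung voxel
  if (!any(gtv)) stop("GTV mask is empty")
  ci <- colMeans(arrayInd(which(gtv), d))
  ci_near <- round(ci)
  ci_near <- pmin(pmax(ci_near, 1), d)
  lab_at <- labels[ci_near[1], ci_near[2], ci_near[3]]
  if (lab_at == 0L) {
    lung_idx <- which(labels > 0L)
    lc <- arrayInd(lung_idx, d)
    dist2 <- ((lc[, 1] - ci[1]) * spacing[1])^2 +
             ((lc[, 2] - ci[2]) * spacing[2])^2 +
             ((lc[, 3] - ci[3]) * spacing[3])^2
    lab_at <- labels[lung_idx[which.min(dist2)]]
    warning("GTV centroid outside both lungs; using nearest lung voxel")
  }
  tumor_third <- as.integer(lab_at)

  structure(list(labels = labels,
                 tumor_third = tumor_third,
                 adjacency = third_neighbours(tumor_third),
                 ipsilateral = if (tumor_third <= 3) "left" else "right"),
            class = "thirds_partition")
}

#' @export
print.thirds_partition <- function(x, ...) {
  cat(sprintf("<thirds_partition> tumor third %d (%s lung), adjacency {%s}\n",
              x$tumor_third, x$ipsilateral,
              paste(x$adjacency, collapse = ", ")))
  invisible(x)
}

#' Percent ventilation in each lung third
#'
#' Fraction of the total within-lung ventilation mass in each of the six
#' thirds, as a percentage. Negative raw values are floored at zero so the
#' quantity keeps percent-of-total semantics; the six percentages sum to
#' 100 by construction.
#'
#' @param vmap a `vent_map`.
#' @param partition a `thirds_partition`.
#' @return named numeric length 6 (`third1` .. `third6`).
#' @export
percent_ventilation_by_third <- function(vmap, partition) {
  stopifnot(inherits(vmap, "vent_map"), inherits(partition, "thirds_partition"))
  raw <- pmax(vmap$raw$values, 0)
  lab <- partition$labels
  ok <- vmap$valid_mask & lab > 0L
  tot <- sum(raw[ok])
  if (!is.finite(tot) || tot <= 0)
    stop("total ventilation is not positive; cannot form percentages")
  pct <- vapply(1:6, function(t) sum(raw[ok & lab == t]) / tot * 100,
                numeric(1))
  names(pct) <- paste0("third", 1:6)
  pct
}

#' Per-patient ventilation heterogeneity metrics
#'
#' Computes the four quantitative heterogeneity metrics used for trial
#' eligibility: `vtt` (percent ventilation in the third containing the
#' tumor), `vta` (minimum percent ventilation over that third and its
#' adjacent thirds), `ic` (ipsilateral-to-contralateral ventilation ratio)
#' and `cov` (coefficient of variation of raw ventilation over valid lung
#' voxels).
#'
#' @param vmap a `vent_map`.
#' @param partition a `thirds_partition`.
#' @param defect_label optional observer defect label (0/1).
#' @return list of class `het_metrics` with `pct_by_third`, `vtt`, `vta`,
#'   `ic`, `cov`, `defect_label`.
#' @export
compute_heterogeneity_metrics <- function(vmap, partition,
                                          defect_label = NA_integer_) {
  pct <- percent_ventilation_by_third(vmap, partition)
  tt <- partition$tumor_third
  vtt <- unname(pct[tt])
  vta <- min(pct[c(tt, partition$adjacency)])

  raw <- vmap$raw$values
  lab <- partition$labels
  ok <- vmap$valid_mask & lab > 0L
  ipsi <- if (partition$ipsilateral == "left") lab %in% 1:3 else lab %in% 4:6
  s_ipsi <- sum(pmax(raw[ok & ipsi], 0))
  s_contra <- sum(pmax(raw[ok & !ipsi & lab > 0L], 0))
  ic <- if (s_contra > 0) s_ipsi / s_contra else NA_real_

  v <- raw[ok]
  m <- mean(v)
  cov <- if (abs(m) > 0) stats::sd(v) / m else NA_real_

  structure(list(pct_by_third = pct, vtt = vtt, vta = vta, ic = ic,
                 cov = cov, defect_label = defect_label),
            class = "het_metrics")
}

#' @export
print.het_metrics <- function(x, ...) {
  cat(sprintf("<het_metrics> vtt=%.2f%% vta=%.2f%% ic=%.3f cov=%.3f label=%s\n",
              x$vtt, x$vta, x$ic, x$cov,
              ifelse(is.na(x$defect_label), "NA", x$defect_label)))
  invisible(x)
}

#' ROC and logistic-regression analysis of a heterogeneity metric
#'
#' AUC is computed through the Mann-Whitney U identity (midranks give tied
#' pairs 0.5 credit). The operating point is the threshold maximising the
#' Youden index J = sensitivity + specificity - 1 (smallest threshold on
#' ties). A univariate logistic regression of the label on the score is
#' fitted by iteratively reweighted least squares ([stats::glm()]) and the
#' Wald p-value of the slope reported.
#'
#' @param scores numeric per-patient metric values.
#' @param labels binary 0/1 observer labels; both classes must be present.
#' @param direction `">"` if larger scores indicate the positive class,
#'   `"<"` if smaller scores do (e.g. %VTA, where a low value flags a
#'   defect).
#' @return An object of class `roc_result`: `auc`, `curve` (data.frame
#'   threshold/sensitivity/specificity/youden), `threshold`, `youden`,
#'   `logistic` (slope, p-value), `direction`.
#' @export
roc_analysis <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  s <- if (direction == ">") scores else -scores
  # Mann-Whitney identity with midranks (ties -> 0.5 credit)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # threshold sweep: predict positive iff s >= thr
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[labels == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[labels == 0L] < t), numeric(1))
  youden <- sens + spec - 1
  best <- which.max(youden)          # which.max takes the first = smallest thr
  thr_internal <- thr[best]
  threshold <- if (direction == ">") thr_internal else -thr_internal

  fit <- suppressWarnings(stats::glm(labels ~ scores, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  logistic <- list(slope = unname(cf["scores", "Estimate"]),
                   p_value = unname(cf["scores", "Pr(>|z|)"]))

  curve <- data.frame(
    threshold = if (direction == ">") thr else rev(-thr),
    sensitivity = if (direction == ">") sens else rev(sens),
    specificity = if (direction == ">") spec else rev(spec))
  structure(list(auc = auc, curve = curve, threshold = threshold,
                 youden = youden[best], logistic = logistic,
                 direction = direction, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC = %.3f (%d pos / %d neg), Youden ",
                     "threshold %s %.3f (J = %.3f)\n"),
              x$auc, x$n_pos, x$n_neg, x$direction, x$threshold, x$youden))
  cat(sprintf("  logistic slope %.3f, Wald p = %.3g\n",
              x$logistic$slope, x$logistic$p_value))
  invisible(x)
}

#' Trial eligibility assessment
#'
#' A patient is eligible for functional avoidance when a low-ventilation
#' third sits at or next to the tumor: quantitatively, `vta < vta_cutoff`;
#' qualitatively, when an observer defect label of 1 is supplied. Either
#' rule suffices; the applied rule is recorded in the reason string.
#'
#' @param metrics a `het_metrics`.
#' @param vta_cutoff percent cutoff on %VTA.
#' @param use_label include the qualitative observer-label rule when a
#'   label is available (default TRUE).
#' @return list with `eligible` (logical) and `reason` (character).
#' @export
assess_eligibility <- function(metrics, vta_cutoff, use_label = TRUE) {
  stopifnot(inherits(metrics, "het_metrics"))
  quant <- is.finite(metrics$vta) && metrics$vta < vta_cutoff
  qual <- use_label && !is.na(metrics$defect_label) &&
    metrics$defect_label == 1L
  reason <- if (quant && qual)
    sprintf("vta %.2f < cutoff %.2f and observer defect", metrics$vta, vta_cutoff)
  else if (quant)
    sprintf("vta %.2f < cutoff %.2f", metrics$vta, vta_cutoff)
  else if (qual)
    "observer defect label"
  else
    sprintf("vta %.2f >= cutoff %.2f and no observer defect",
            metrics$vta, vta_cutoff)
  list(eligible = quant || qual, reason = reason)
}
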