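#' Run the full functional-avoidance virtual trial on a cohort
#'
#' Executes every stage per patient — displacement-field QA, ventilation
#' computation and normalisation, lung-thirds partition, heterogeneity
#' metrics — then selects the %VTA operating cutoff (ROC/Youden on observer
#' labels when `vta_cutoff = "auto"`), assesses eligibility, segments the
#' functional-avoid structure for eligible patients, evaluates the paired
#' clinical/functional dose distributions, and aggregates the comparison.
#' One patient's QA failure never aborts the cohort: the patient is logged
#' as `failed_qa` and the trial proceeds.
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param vta_cutoff `"auto"` (ROC-derived; requires labels) or a numeric
#'   percent cutoff on %VTA.
#' @param avoid_threshold normalised-ventilation threshold for the
#'   functional-avoid structure.
#' @param use_labels also apply the qualitative observer-label eligibility
#'   rule (default TRUE).
#' @param n_planning number of eligible patients selected (seeded simple
#'   random sample) for paired planning; `Inf` plans all eligible.
#' @param qa_max_folding maximum tolerated DVF folding fraction.
#' @param seed seed for the planning-subset sample.
#' @param out_dir optional directory; when given, `report.json` and
#'   `report.csv` are written.
#' @return An object of class `trial_report`.
#' @export
run_virtual_trial <- function(cohort, vta_cutoff = "auto",
                              avoid_threshold = 0.15, use_labels = TRUE,
                              n_planning = Inf, qa_max_folding = 0,
                              seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  n <- length(cohort$cases)
  labels <- cohort$labels$defect_label
  ids <- cohort$labels$patient_id

  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- tryCatch(
      screen_patient(cohort$cases[[i]], labels[i], qa_max_folding),
      error = function(e) list(status = "failed_qa",
                               reason = conditionMessage(e)))
  }
  ok <- vapply(per, function(p) is.null(p$status), logical(1))

  metr <- function(field) vapply(per, function(p)
    if (is.null(p$status)) p$metrics[[field]] else NA_real_, numeric(1))
  vta <- metr("vta"); vtt <- metr("vtt"); ic <- metr("ic"); cov <- metr("cov")

  # ROC/AUC table over the screened patients with both classes present
  roc_tab <- NULL; rocs <- list()
  if (use_labels && length(unique(labels[ok])) == 2L) {
    specs <- list(ic = list(ic, "<"), cov = list(cov, ">"),
                  vtt = list(vtt, "<"), vta = list(vta, "<"))
    rocs <- lapply(specs, function(s) {
      keep <- ok & is.finite(s[[1]])
      roc_analysis(s[[1]][keep], labels[keep], direction = s[[2]])
    })
    roc_tab <- data.frame(
      metric = names(rocs),
      auc = vapply(rocs, function(r) r$auc, numeric(1)),
      logistic_p = vapply(rocs, function(r) r$logistic$p_value, numeric(1)),
      threshold = vapply(rocs, function(r) r$threshold, numeric(1)))
  }

  if (identical(vta_cutoff, "auto")) {
    if (is.null(roc_tab))
      stop("vta_cutoff = \"auto\" requires observer labels with both classes")
    # inclusive operating point: the Youden threshold itself stays eligible
    cutoff <- rocs$vta$threshold * (1 + 1e-9) + 1e-12
  } else {
    cutoff <- as.numeric(vta_cutoff)
    if (!is.finite(cutoff) || cutoff <= 0) stop("invalid vta_cutoff")
  }

  status <- character(n); reason <- character(n)
  for (i in seq_len(n)) {
    if (!ok[i]) {
      status[i] <- "failed_qa"; reason[i] <- per[[i]]$reason
    } else {
      a <- assess_eligibility(per[[i]]$metrics, cutoff, use_label = use_labels)
      status[i] <- if (a$eligible) "eligible" else "ineligible"
      reason[i] <- a$reason
    }
  }
  quant_elig <- ok & is.finite(vta) & vta < cutoff
  qual_elig <- ok & !is.na(labels) & labels == 1L

  eligible_idx <- which(status == "eligible")
  plan_idx <- if (length(eligible_idx) > n_planning) {
    with_seed(as.integer(seed), sort(sample(eligible_idx, n_planning)))
  } else eligible_idx

  comparison <- NULL
  if (length(plan_idx) >= 2) {
    summaries <- lapply(plan_idx, function(i) {
      evaluate_patient_plans(cohort$cases[[i]], per[[i]], avoid_threshold)
    })
    comparison <- compare_plans(lapply(summaries, `[[`, "clinical"),
                                lapply(summaries, `[[`, "functional"))
  } else if (length(eligible_idx) == 0) {
    warning("no eligible patients; comparison section is empty")
  }

  ledger <- data.frame(patient_id = ids, defect_label = labels,
                       vtt = vtt, vta = vta, ic = ic, cov = cov,
                       status = status, reason = reason,
                       planned = seq_len(n) %in% plan_idx,
                       seed = cohort$labels$seed)

  structure(list(
    n_enrolled = n,
    eligibility_fraction_qualitative = mean(qual_elig[ok]),
    eligibility_fraction_quantitative = mean(quant_elig[ok]),
    vta_cutoff = cutoff,
    avoid_threshold = avoid_threshold,
    roc_table = roc_tab,
    comparison = comparison,
    ledger = ledger
  ), class = "trial_report")
}

# Screening stages for one patient; errors propagate to the caller, which
# records a failed_qa status.
screen_patient <- function(case, label, qa_max_folding = 0) {
  qa <- qa_displacement_field(case$dvf_true)
  if (qa$folding_fraction > qa_max_folding)
    stop(sprintf("DVF folding fraction %.3f exceeds %.3f",
                 qa$folding_fraction, qa_max_folding))
  lung_l <- case$masks$lung_L; lung_r <- case$masks$lung_R
  warped <- warp_to_exhale(case$hu_inhale, case$dvf_true)
  vmap <- compute_ventilation(case$hu_exhale, warped, lung_l | lung_r)
  vmap <- normalize_ventilation(vmap)
  part <- partition_thirds(lung_l, lung_r, case$masks$gtv,
                           spacing = case$hu_exhale$spacing)
  metrics <- compute_heterogeneity_metrics(vmap, part, defect_label = label)
  list(qa = qa, vmap = vmap, partition = part, metrics = metrics)
}

evaluate_patient_plans <- function(case, screened, avoid_threshold) {
  avoid <- segment_functional_avoid(
    screened$vmap, case$masks$lung_L, case$masks$lung_R,
    case$masks$gtv, case$masks$itv, threshold = avoid_threshold)
  rx <- case$spec$prescription_gy
  list(
    clinical = plan_summary(case$dose_clinical, case$masks, avoid,
                            screened$vmap, rx),
    functional = plan_summary(case$dose_functional, case$masks, avoid,
                              screened$vmap, rx),
    avoid = avoid)
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %d enrolled\n", x$n_enrolled))
  cat(sprintf("  eligibility: %.0f%% qualitative, %.0f%% quantitative (vta < %.2f)\n",
              100 * x$eligibility_fraction_qualitative,
              100 * x$eligibility_fraction_quantitative, x$vta_cutoff))
  if (!is.null(x$roc_table)) {
    cat("  metric AUCs:\n")
    print(cbind(x$roc_table[1],
                round(x$roc_table[c("auc", "logistic_p", "threshold")], 3)),
          row.names = FALSE)
  }
  if (!is.null(x$comparison)) {
    key <- x$comparison$table
    key <- key[key$metric %in% c("mld", "sf_mld", "imf_mld", "sf_v5", "sf_v20"), ]
    cat("  key plan differences (functional - clinical):\n")
    key[-1] <- lapply(key[-1], round, 3)
    print(key, row.names = FALSE)
  }
  invisible(x)
}

#' Write a trial report to disk
#'
#' Writes `report.json` (everything but the per-voxel data) and
#' `report.csv` (the per-patient ledger) into `dir`.
#'
#' @param report a `trial_report`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_trial_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(
    n_enrolled = report$n_enrolled,
    eligibility_fraction_qualitative = report$eligibility_fraction_qualitative,
    eligibility_fraction_quantitative = report$eligibility_fraction_quantitative,
    vta_cutoff = report$vta_cutoff,
    avoid_threshold = report$avoid_threshold,
    roc_table = report$roc_table,
    comparison = if (is.null(report$comparison)) NULL else report$comparison$table,
    ledger = report$ledger)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "report.csv")
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  utils::write.csv(report$ledger, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
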