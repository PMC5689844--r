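# NIfTI I/O for volumes, displacement fields and phantom cases (RNifti).
# World origin is carried in the sform translation; orientation is assumed
# axis-aligned (the package's grids always are).

nifti_from <- function(values, spacing, origin) {
  img <- RNifti::asNifti(values)
  nd <- length(dim(values))
  RNifti::pixdim(img) <- if (nd == 4L) c(spacing, 1) else spacing
  RNifti::sform(img) <- structure(
    rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1)), code = 2L)
  img
}

#' Write an image volume or displacement field as NIfTI
#'
#' @param x an [image_volume()] or [displacement_field()] (written as a 4D
#'   volume with 3 components, mm).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "image_volume")) {
    RNifti::writeNifti(nifti_from(x$values, x$spacing, x$origin), path)
  } else if (inherits(x, "displacement_field")) {
    RNifti::writeNifti(nifti_from(x$u, x$spacing, x$origin), path)
  } else stop("x must be an image_volume or displacement_field")
  invisible(path)
}

#' Read a NIfTI file as an image volume or displacement field
#'
#' 3D images become [image_volume()]s; 4D images with 3 components on the
#' last axis become [displacement_field()]s.
#'
#' @param path NIfTI file path.
#' @param unit unit tag for 3D volumes.
#' @return An [image_volume()] or [displacement_field()].
#' @export
read_volume <- function(path, unit = "unitless") {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # strip NIfTI header attributes
  sp <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  if (length(dim(a)) == 3L) {
    image_volume(a, sp[1:3], origin, unit)
  } else if (length(dim(a)) == 4L && dim(a)[4] == 3L) {
    displacement_field(a, sp[1:3], origin)
  } else stop("unsupported NIfTI dimensionality: ", paste(dim(a), collapse = "x"))
}

#' Write a phantom case to a directory
#'
#' Writes `hu_exhale.nii.gz`, `hu_inhale.nii.gz`, `dvf.nii.gz` (4D, 3
#' components, mm), `vent_true.nii.gz`, `dose_clinical.nii.gz`,
#' `dose_functional.nii.gz`, a `structures.nii.gz` label map with a
#' `structures.json` name-to-label sidecar, and `case.json` metadata.
#'
#' @param case a `phantom_case`.
#' @param dir output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(case$hu_exhale, file.path(dir, "hu_exhale.nii.gz"))
  write_volume(case$hu_inhale, file.path(dir, "hu_inhale.nii.gz"))
  write_volume(case$dvf_true, file.path(dir, "dvf.nii.gz"))
  write_volume(case$vent_true, file.path(dir, "vent_true.nii.gz"))
  write_volume(case$dose_clinical, file.path(dir, "dose_clinical.nii.gz"))
  write_volume(case$dose_functional, file.path(dir, "dose_functional.nii.gz"))

  # label map: later structures overwrite earlier ones where they overlap
  sp <- case$hu_exhale$spacing
  labmap <- array(0, dim(case$hu_exhale$values))
  nm <- setdiff(names(case$masks), "body")
  for (i in seq_along(nm)) labmap[case$masks[[nm[i]]]] <- i
  write_volume(image_volume(labmap, sp, case$hu_exhale$origin),
               file.path(dir, "structures.nii.gz"))
  jsonlite::write_json(as.list(stats::setNames(seq_along(nm), nm)),
                       file.path(dir, "structures.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(defect_label = case$defect_label,
                            prescription_gy = case$spec$prescription_gy,
                            seed = case$spec$seed),
                       file.path(dir, "case.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a cohort's label table as CSV
#'
#' @param cohort a `phantom_cohort`.
#' @param path CSV path (columns patient_id, defect_label, seed).
#' @return `path`, invisibly.
#' @export
write_cohort_labels <- function(cohort, path) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  utils::write.csv(cohort$labels, path, row.names = FALSE)
  invisible(path)
}

#' Read an observer defect-label CSV
#'
#' @param path CSV with columns `patient_id` and `defect_label` (0/1).
#' @return data.frame with those columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "defect_label") %in% names(df)))
    stop("labels CSV must have patient_id and defect_label columns")
  df$defect_label <- as.integer(df$defect_label)
  if (!all(df$defect_label %in% c(0L, 1L), na.rm = TRUE))
    stop("defect_label must be binary")
  df
}
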