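# File interfaces: NIfTI volumes (RNifti) with JSON sidecars for the
# acquisition times and ground truth, integer-labelled NIfTI masks with a
# JSON label dictionary, per-endplate unit tables and exclusion ledgers.

.as_nifti <- function(arr, spacing) {
  RNifti::asNifti(arr * 1, pixdim = spacing)
}

#' Write a phantom to NIfTI volumes with JSON sidecar
#'
#' Writes the multi-echo and spin-lock series as 4D NIfTI, fat/water as 3D
#' NIfTI, the tissue masks as one integer-labelled NIfTI (1 = CEP,
#' 2 = vertebra, 3 = disc) with a JSON label dictionary, and a sidecar JSON
#' with the TE/TSL lists (ms) and ground-truth regional means.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "spine_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spacing
  labels <- array(0L, dim(phantom$fat))
  labels[phantom$masks$cep] <- 1L
  labels[phantom$masks$vertebra] <- 2L
  labels[phantom$masks$disc] <- 3L
  paths <- c(
    echo = file.path(dir, "echo_series.nii.gz"),
    spinlock = file.path(dir, "spinlock_series.nii.gz"),
    fat = file.path(dir, "fat.nii.gz"),
    water = file.path(dir, "water.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    sidecar = file.path(dir, "phantom.json")
  )
  RNifti::writeNifti(.as_nifti(phantom$echo_series, c(sp, 1)), paths["echo"])
  RNifti::writeNifti(.as_nifti(phantom$spinlock_series, c(sp, 1)), paths["spinlock"])
  RNifti::writeNifti(.as_nifti(phantom$fat, sp), paths["fat"])
  RNifti::writeNifti(.as_nifti(phantom$water, sp), paths["water"])
  RNifti::writeNifti(.as_nifti(labels, sp), paths["labels"])
  jsonlite::write_json(list(
    te_ms = phantom$te_ms,
    tsl_ms = phantom$tsl_ms,
    voxel_spacing_mm = sp,
    labels = list(cep = 1, vertebra = 2, disc = 3),
    ground_truth_region_means = phantom$truth$region_means
  ), paths["sidecar"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a decay series from NIfTI + JSON times
#'
#' @param nifti_path 4D NIfTI file (last axis = time point).
#' @param times_ms acquisition times in ms, or a path to a JSON sidecar with
#'   a `te_ms` or `tsl_ms` field.
#' @param which when `times_ms` is a sidecar path, which field to use
#'   (`"te_ms"` or `"tsl_ms"`).
#' @param mask optional logical array.
#' @return a [decay_series()].
#' @export
read_decay_series <- function(nifti_path, times_ms, which = c("te_ms", "tsl_ms"),
                              mask = NULL) {
  img <- RNifti::readNifti(nifti_path)
  if (is.character(times_ms)) {
    which <- match.arg(which)
    side <- jsonlite::read_json(times_ms, simplifyVector = TRUE)
    times_ms <- side[[which]]
  }
  spacing <- attr(img, "pixdim")[1:3]
  decay_series(unclass(img)[, , , , drop = FALSE], times_ms, mask = mask,
               spacing = spacing)
}

#' Write per-endplate units to CSV
#' @param units data.frame of endplate units.
#' @param path output CSV path.
#' @export
write_units_csv <- function(units, path) {
  utils::write.csv(as.data.frame(units), path, row.names = FALSE)
  invisible(path)
}

#' Read per-endplate units from CSV
#' @param path CSV written by [write_units_csv()].
#' @return data.frame of class `endplate_units`.
#' @export
read_units_csv <- function(path) {
  units <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(units) <- c("endplate_units", "data.frame")
  units
}

#' Write an exclusion ledger to JSON
#' @param ledger an `exclusion_ledger` from [apply_exclusions()].
#' @param path output JSON path.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration set from JSON
#'
#' The JSON mirrors [calibration_set()]: named arrays `[intercept, slope]`
#' per analyte, optional `t2star_range_ms` and `source`.
#'
#' @param path JSON path.
#' @return a [calibration_set()].
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_set(
    gag_ugmg = j$gag_ugmg, water_pct = j$water_pct,
    coll_gag_ratio = j$coll_gag_ratio,
    t2star_range_ms = if (!is.null(j$t2star_range_ms)) j$t2star_range_ms
    else c(-Inf, Inf),
    source = if (!is.null(j$source)) j$source else "user-supplied"
  )
}
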