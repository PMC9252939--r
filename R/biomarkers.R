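# Per-endplate observation units and the study's exclusion bookkeeping.
# Each unit pairs one endplate with the mean CEP T2* of its central CEP,
# the mean BMFF of the adjacent hemi-vertebra, and the mean NP T1rho of the
# adjacent NP sub-region. Exclusion applies CEP damage at the subject level
# (all four endplates), the magic-angle orientation filter at the endplate
# level, and removes units with an empty (all-invalid) region.

#' Assemble per-endplate observation units
#'
#' Joins regional biomarker means with subject covariates and derives the
#' inclusion flag. A unit is included iff the subject is not damaged, the
#' CEP angle is inside the magic-angle window, and all three biomarkers are
#' present. `exclusion_reason` records the first failing rule in the order
#' damage > orientation > empty_region.
#'
#' @param measurements data.frame with one row per endplate:
#'   `subject_id`, `level`, `endplate`, `cep_t2star_ms`,
#'   `vertebral_bmff_pct`, `np_t1rho_ms` (NA = empty region),
#'   `cep_angle_deg`, `damaged`.
#' @param covariates data.frame with one row per subject: `subject_id`,
#'   `age`, `sex`, `bmi` (plus any extra columns, carried through).
#' @param angle_half_width_deg magic-angle window half-width, degrees.
#' @return data.frame of class `endplate_units` with added covariate
#'   columns, `included` and `exclusion_reason`.
#' @export
assemble_units <- function(measurements, covariates,
                           angle_half_width_deg = 15) {
  need_m <- c("subject_id", "level", "endplate", "cep_t2star_ms",
              "vertebral_bmff_pct", "np_t1rho_ms", "cep_angle_deg", "damaged")
  need_c <- c("subject_id", "age", "sex", "bmi")
  miss <- setdiff(need_m, names(measurements))
  if (length(miss)) stop("measurements lacks columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(need_c, names(covariates))
  if (length(miss)) stop("covariates lacks columns: ", paste(miss, collapse = ", "))

  orphans_m <- setdiff(measurements$subject_id, covariates$subject_id)
  orphans_c <- setdiff(covariates$subject_id, measurements$subject_id)
  if (length(orphans_m) || length(orphans_c))
    stop("subject key mismatch; in measurements only: [",
         paste(orphans_m, collapse = ", "), "]; in covariates only: [",
         paste(orphans_c, collapse = ", "), "]")

  units <- merge(measurements, covariates, by = "subject_id", sort = FALSE)
  bio <- c("cep_t2star_ms", "vertebral_bmff_pct", "np_t1rho_ms")
  present <- !Reduce(`|`, lapply(units[bio], is.na))
  if (any(stats::na.omit(unlist(units[bio])) <= 0))
    stop("biomarker values must be positive where present")
  in_window <- angle_included(units$cep_angle_deg, angle_half_width_deg)
  units$included <- !units$damaged & in_window & present
  units$exclusion_reason <- ifelse(units$damaged, "damage",
    ifelse(!in_window, "orientation",
      ifelse(!present, "empty_region", "none")))
  class(units) <- c("endplate_units", "data.frame")
  units
}

#' Apply the study exclusion rules with auditable bookkeeping
#'
#' @param units an [assemble_units()] table (or any data.frame with
#'   `subject_id`, `included`, `exclusion_reason`).
#' @param n_enrolled number of subjects enrolled.
#' @param n_complete_mri number with complete MRI (defaults to the subjects
#'   present in `units`).
#' @return list with `included` (the included units) and `ledger`, a list of
#'   class `exclusion_ledger` satisfying
#'   `n_endplates_final == (n_complete_mri - n_subjects_excluded_damage) *
#'   endplates_per_subject - n_endplates_excluded_orientation -
#'   n_endplates_excluded_other`.
#' @export
apply_exclusions <- function(units, n_enrolled = NULL, n_complete_mri = NULL) {
  subjects <- unique(units$subject_id)
  if (is.null(n_complete_mri)) n_complete_mri <- length(subjects)
  if (is.null(n_enrolled)) n_enrolled <- n_complete_mri
  ep_per_subject <- nrow(units) / length(subjects)
  if (ep_per_subject != round(ep_per_subject))
    stop("units are unbalanced across subjects")

  damaged_subjects <- unique(units$subject_id[units$exclusion_reason == "damage"])
  n_damage <- length(damaged_subjects)
  surviving <- units[!(units$subject_id %in% damaged_subjects), , drop = FALSE]
  n_orient <- sum(surviving$exclusion_reason == "orientation")
  n_other <- sum(surviving$exclusion_reason == "empty_region")
  included <- units[units$included, , drop = FALSE]

  ledger <- structure(list(
    n_enrolled = n_enrolled,
    n_complete_mri = n_complete_mri,
    endplates_per_subject = as.integer(ep_per_subject),
    n_subjects_excluded_damage = n_damage,
    n_endplates_excluded_orientation = n_orient,
    n_endplates_excluded_other = n_other,
    n_subjects_final = length(unique(included$subject_id)),
    n_endplates_final = nrow(included)
  ), class = "exclusion_ledger")

  expected <- (ledger$n_complete_mri - n_damage) * ledger$endplates_per_subject -
    n_orient - n_other
  if (ledger$n_endplates_final != expected)
    stop("exclusion ledger identity violated: ", ledger$n_endplates_final,
         " included endplates vs expected ", expected)
  list(included = included, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("<exclusion_ledger>\n")
  cat("  enrolled:", x$n_enrolled, "| complete MRI:", x$n_complete_mri, "\n")
  cat("  excluded: damage", x$n_subjects_excluded_damage, "subjects;",
      "orientation", x$n_endplates_excluded_orientation, "endplates;",
      "other", x$n_endplates_excluded_other, "endplates\n")
  cat("  final:", x$n_subjects_final, "subjects,",
      x$n_endplates_final, "endplates\n")
  invisible(x)
}

#' Intraclass correlation coefficient for repeated measurements
#'
#' Closed-form single-measurement ICC from the two-way (or one-way) ANOVA
#' mean squares of an items-by-raters table. The default, ICC(2,1), is the
#' two-way random-effects absolute-agreement form appropriate for
#' intra-rater re-segmentation reliability.
#'
#' @param ratings numeric matrix, items in rows, repeated ratings in
#'   columns (>= 2 items, >= 2 ratings).
#' @param type `"ICC2"` (two-way random, absolute agreement; default),
#'   `"ICC1"` (one-way random) or `"ICC3"` (two-way mixed, consistency).
#' @return list with `icc`, `type`, `n_items`, `k_raters`, and the ANOVA
#'   mean squares `ms` (`between`, `within`, `raters`, `error`).
#' @examples
#' r <- cbind(c(9, 6, 8, 7, 10), c(9.5, 6.1, 8.2, 7.0, 9.9))
#' intra_rater_icc(r)$icc
#' @export
intra_rater_icc <- function(ratings, type = c("ICC2", "ICC1", "ICC3")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2) stop("at least 2 items are required")
  if (k < 2) stop("at least 2 ratings per item are required")
  if (anyNA(ratings)) stop("ratings must be complete")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msb <- ss_rows / (n - 1)              # between items
  msj <- ss_cols / (k - 1)              # between raters
  mse <- ss_err / ((n - 1) * (k - 1))   # residual
  msw <- (ss_tot - ss_rows) / (n * (k - 1))  # within items (one-way)

  icc <- switch(type,
    ICC1 = (msb - msw) / (msb + (k - 1) * msw),
    ICC2 = (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n),
    ICC3 = (msb - mse) / (msb + (k - 1) * mse)
  )
  if (!is.finite(icc)) {
    # all mean squares zero: every measurement identical; the 0/0 limit is
    # reported as 0 (no between-item variance to attribute)
    warning("zero variance in ratings: ICC is a 0/0 limit; returning 0")
    icc <- 0
  } else if (ss_rows <= 1e-12 * max(ss_tot, 1)) {
    warning("zero between-item variance: ICC estimate is at its lower limit")
  }
  list(icc = icc, type = type, n_items = n, k_raters = k,
       ms = list(between = msb, within = msw, raters = msj, error = mse))
}
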