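# CEP tissue composition estimated from T2* via user-supplied linear
# calibrations. T2* correlates with glycosaminoglycan (GAG) content, water
# content and the collagen-to-GAG ratio in the CEP; the regression
# coefficients come from ex vivo calibration studies and must be supplied by
# the user -- none are built in, since hard-coding externally published
# coefficients here would amount to inventing data.

.ANALYTES <- c("gag_ugmg", "water_pct", "coll_gag_ratio")

#' Calibration linking CEP T2* to compositional analytes
#'
#' @param gag_ugmg,water_pct,coll_gag_ratio each `c(intercept, slope)` for
#'   the affine map `analyte = intercept + slope * T2*` (T2* in ms; GAG in
#'   ug/mg dry weight, water in percent, collagen-to-GAG dimensionless).
#'   Analytes may be omitted (`NULL`) if not calibrated.
#' @param t2star_range_ms valid T2* range of the calibration; values outside
#'   are flagged extrapolated.
#' @param source free-text provenance label.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(gag_ugmg = NULL, water_pct = NULL,
                            coll_gag_ratio = NULL,
                            t2star_range_ms = c(-Inf, Inf),
                            source = "user-supplied") {
  cal <- list(gag_ugmg = gag_ugmg, water_pct = water_pct,
              coll_gag_ratio = coll_gag_ratio)
  cal <- cal[!vapply(cal, is.null, logical(1))]
  if (!length(cal))
    stop("no analyte calibrations supplied; provide c(intercept, slope) ",
         "for at least one of: ", paste(.ANALYTES, collapse = ", "))
  for (nm in names(cal)) {
    v <- cal[[nm]]
    if (length(v) != 2 || !all(is.finite(v)))
      stop("calibration for ", nm, " must be c(intercept, slope), finite")
  }
  stopifnot(length(t2star_range_ms) == 2,
            t2star_range_ms[1] < t2star_range_ms[2])
  structure(list(coefficients = cal, t2star_range_ms = t2star_range_ms,
                 source = source),
            class = "calibration_set")
}

#' Estimate CEP composition from T2* values
#'
#' Applies the affine calibration per analyte and reports per-value
#' estimates plus the cohort (min, max) range of each analyte. For a
#' monotone (nonzero-slope) calibration the reported range is the affine
#' image of the T2* range.
#'
#' @param t2star_values CEP T2* values, ms (NAs dropped).
#' @param cal a [calibration_set()]; required, no defaults exist.
#' @return list with `estimates` (data.frame: `t2star_ms`, one column per
#'   analyte, `extrapolated`) and `ranges` (data.frame: `analyte`, `min`,
#'   `max`).
#' @examples
#' cal <- calibration_set(gag_ugmg = c(10, 3.5), t2star_range_ms = c(10, 30))
#' estimate_composition(c(14, 18, 24), cal)$ranges
#' @export
estimate_composition <- function(t2star_values, cal) {
  if (missing(cal) || !inherits(cal, "calibration_set"))
    stop("a calibration_set is required: supply the published regression ",
         "coefficients relating CEP T2* to each analyte")
  x <- t2star_values[is.finite(t2star_values)]
  if (!length(x)) stop("no finite T2* values supplied")
  est <- data.frame(t2star_ms = x)
  for (nm in names(cal$coefficients)) {
    co <- cal$coefficients[[nm]]
    est[[nm]] <- co[1] + co[2] * x
  }
  est$extrapolated <- x < cal$t2star_range_ms[1] | x > cal$t2star_range_ms[2]
  ranges <- do.call(rbind, lapply(names(cal$coefficients), function(nm) {
    data.frame(analyte = nm, min = min(est[[nm]]), max = max(est[[nm]]),
               stringsAsFactors = FALSE)
  }))
  list(estimates = est, ranges = ranges)
}

#' Composition ranges within a covariate subgroup
#'
#' Re-computes per-analyte (min, max) ranges over the subset of values whose
#' age falls inside `age_range` (inclusive). An unbounded range reproduces
#' the full-cohort ranges; a narrower subgroup always yields ranges nested
#' within the full ones.
#'
#' @param estimates the `estimates` data.frame from
#'   [estimate_composition()].
#' @param age per-value ages, same length as `nrow(estimates)`.
#' @param age_range `c(min, max)` filter, inclusive.
#' @return data.frame with `analyte`, `min`, `max`, `n`.
#' @export
subgroup_ranges <- function(estimates, age, age_range = c(-Inf, Inf)) {
  stopifnot(length(age) == nrow(estimates), length(age_range) == 2)
  keep <- age >= age_range[1] & age <= age_range[2]
  if (!any(keep)) stop("no values inside the requested age range")
  analytes <- intersect(.ANALYTES, names(estimates))
  out <- do.call(rbind, lapply(analytes, function(nm) {
    v <- estimates[[nm]][keep]
    data.frame(analyte = nm, min = min(v), max = max(v), n = sum(keep),
               stringsAsFactors = FALSE)
  }))
  out
}
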