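# Geometric standardisation and anatomical sub-region extraction. Segmented
# tissues are rotated about their principal axes into a standard frame with
# axes ordered (AP, LR, SI); sub-regions -- the central CEP under a
# kidney-bean template, the hemi-vertebral halves, and the central-40% NP
# region -- are defined by coordinates in that frame. The CEP orientation
# filter keeps endplates within +/-15 degrees of the magic angle
# arccos(1/sqrt(3)) = 54.7 degrees, where dipolar coupling in ordered
# collagen vanishes and T2* is not artifactually depressed.

#' The magic angle, in degrees
#'
#' `arccos(1/sqrt(3))`, the fibre orientation relative to B0 at which the
#' dipolar coupling term (3 cos^2 theta - 1) vanishes.
#'
#' @return angle in degrees (54.7356...).
#' @export
magic_angle_deg <- function() acos(1 / sqrt(3)) * 180 / pi

#' Inclusion window around the magic angle
#' @param half_width_deg half-width of the window, degrees (default 15).
#' @return `c(lower, upper)` in degrees; both ends inclusive.
#' @export
magic_angle_window <- function(half_width_deg = 15) {
  magic_angle_deg() + c(-1, 1) * half_width_deg
}

#' Is a CEP angle inside the magic-angle window?
#' @param angle_deg angle(s) in degrees in [0, 90].
#' @param half_width_deg window half-width, degrees.
#' @return logical vector; the window is inclusive at both ends.
#' @export
angle_included <- function(angle_deg, half_width_deg = 15) {
  abs(angle_deg - magic_angle_deg()) <= half_width_deg
}

#' Principal-axis standard frame of a mask
#'
#' Computes the eigenvectors of the mm-coordinate covariance of the mask
#' voxels, orders them by descending eigenvalue, fixes signs so each axis
#' has positive dot product with its assigned scanner axis, assigns axes to
#' anatomy (AP, LR, SI) by the largest absolute component along the scanner
#' axes, and returns the rotation with rows ordered (AP, LR, SI). Standard
#' coordinates of a point p are `rotation %*% (p - origin)`.
#'
#' If the determinant of the sign-fixed rotation is -1 the axis with the
#' smallest eigenvalue is flipped, preferring a proper rotation over the
#' positive-dot convention for that one axis.
#'
#' @param mask logical 3D array with at least 4 non-collinear voxels.
#' @param spacing voxel spacing in mm.
#' @param degeneracy_tol relative eigenvalue-gap tolerance below which the
#'   axes are declared ambiguous (isotropic or rank-deficient shapes).
#' @return object of class `standard_frame`: list with `rotation` (3x3,
#'   rows = AP, LR, SI axes), `origin` (centroid, mm), `axis_labels`,
#'   `eigenvalues` (descending).
#' @export
principal_axis_frame <- function(mask, spacing = c(1, 1, 1),
                                 degeneracy_tol = 0.05) {
  co <- mask_world_coords(mask, spacing)
  if (nrow(co) < 4) stop("mask must contain at least 4 voxels")
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  C <- crossprod(cc) / (nrow(cc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values  # descending
  if (ev[3] <= 1e-10 * ev[1]) {
    ax <- which.min(abs(ev - ev[3]))
    stop("degenerate covariance: principal axis ", ax,
         " has (near-)zero variance; the mask is planar or collinear")
  }
  gaps <- -diff(ev) / ev[1]
  if (any(gaps < degeneracy_tol)) {
    k <- which(gaps < degeneracy_tol)[1]
    stop("degenerate covariance: principal axes ", k, " and ", k + 1,
         " are not separable (relative eigenvalue gap ",
         sprintf("%.3g", gaps[k]), " < ", degeneracy_tol, ")")
  }
  V <- e$vectors  # columns, descending eigenvalue
  # greedy anatomy assignment: each eigenvector claims the scanner axis with
  # its largest |component| among those not yet taken
  assigned <- integer(3)
  taken <- logical(3)
  for (i in 1:3) {
    comp <- abs(V[, i]); comp[taken] <- -Inf
    assigned[i] <- which.max(comp)
    taken[assigned[i]] <- TRUE
  }
  for (i in 1:3) if (V[assigned[i], i] < 0) V[, i] <- -V[, i]
  ord <- order(assigned)             # rows of the frame in (AP, LR, SI) order
  R <- t(V[, ord, drop = FALSE])
  ev_ord <- ev[ord]
  if (det(R) < 0) {
    flip <- which.min(ev_ord)
    R[flip, ] <- -R[flip, ]
  }
  structure(list(rotation = R, origin = ctr,
                 axis_labels = AXIS_LABELS,
                 eigenvalues = ev),
            class = "standard_frame")
}

#' @export
print.standard_frame <- function(x, ...) {
  cat("<standard_frame> origin", sprintf("(%.1f, %.1f, %.1f) mm",
      x$origin[1], x$origin[2], x$origin[3]), "\n")
  rot <- round(x$rotation, 3)
  dimnames(rot) <- list(x$axis_labels, c("x(AP)", "y(LR)", "z(SI)"))
  print(rot)
  invisible(x)
}

# standard-frame coordinates of the mask voxels: n x 3, columns (AP, LR, SI)
.standard_coords <- function(mask, spacing, frame) {
  co <- mask_world_coords(mask, spacing)
  sweep(co, 2, frame$origin) %*% t(frame$rotation)
}

#' CEP orientation angle relative to B0
#'
#' Projects the CEP voxel centres onto the mid-sagittal (AP-SI) plane, fits
#' a line by total least squares (first principal component of the 2D
#' coordinates), and returns its angle from the B0 axis (scanner SI axis),
#' folded into [0, 90] degrees.
#'
#' @param cep_mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param b0_axis index of the scanner B0 axis (default 3 = SI).
#' @return angle in degrees in [0, 90].
#' @export
cep_angle <- function(cep_mask, spacing = c(1, 1, 1), b0_axis = 3) {
  co <- mask_world_coords(cep_mask, spacing)
  if (nrow(co) == 0) stop("CEP mask is empty")
  sag_axis <- setdiff(c(1, 3), b0_axis)
  if (length(sag_axis) != 1) sag_axis <- 1
  xy <- co[, c(sag_axis, b0_axis), drop = FALSE]
  xy <- sweep(xy, 2, colMeans(xy))
  C <- crossprod(xy) / max(1, nrow(xy) - 1)
  if (sum(diag(C)) < 1e-12)
    stop("CEP mask collapses to a point in the sagittal plane")
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  ang <- acos(pmin(1, abs(v[2]) / sqrt(sum(v^2)))) * 180 / pi
  ang
}

#' Central CEP region via a kidney-bean template
#'
#' The CEP sheet is standardised by its own principal axes: the footprint is
#' the projection along the thinnest axis (the sheet normal) onto the plane
#' of its two in-plane axes, with the first (longest, near-sagittal) axis
#' playing the AP role. The footprint is intersected with a parametric
#' kidney-bean contour: an ellipse matched to the footprint's extents and
#' scaled so its area is `area_fraction` of the footprint area, minus a
#' posterior-central concavity lobe. Voxels whose footprint coordinates fall
#' inside the contour form the central CEP, by construction a subset of the
#' CEP mask. Using the sheet's own axes (rather than the anatomy-labelled
#' frame) keeps the footprint rotation-covariant even near the magic angle,
#' where the in-plane axis is equidistant from the scanner AP and SI axes.
#'
#' @param cep_mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param frame optional [principal_axis_frame()]; accepted for interface
#'   symmetry with the other region extractors but the projection axes are
#'   always derived from `cep_mask` itself (see above).
#' @param area_fraction target central-to-footprint area ratio (default 0.5).
#' @param concavity_depth relative AP depth of the posterior concavity lobe
#'   (0 disables it; default 0.25).
#' @param concavity_width relative LR half-width of the lobe (default 0.6).
#' @param min_footprint_voxels below this footprint size the unit is flagged
#'   excluded (empty mask returned with attribute `excluded = TRUE`).
#' @return logical array; attribute `excluded` is TRUE when the footprint
#'   was too small to support the template.
#' @export
central_cep_template <- function(cep_mask, spacing = c(1, 1, 1), frame = NULL,
                                 area_fraction = 0.5, concavity_depth = 0.25,
                                 concavity_width = 0.6,
                                 min_footprint_voxels = 20) {
  stopifnot(area_fraction > 0, area_fraction <= 1,
            concavity_depth >= 0, concavity_depth < 1)
  co <- mask_world_coords(cep_mask, spacing)
  out <- array(FALSE, dim(cep_mask))
  if (nrow(co) < min_footprint_voxels) {
    attr(out, "excluded") <- TRUE
    return(out)
  }
  cc <- sweep(co, 2, colMeans(co))
  V <- eigen(crossprod(cc) / (nrow(cc) - 1), symmetric = TRUE)$vectors
  # stable signs: largest-|component| entry positive for each axis
  for (i in 1:3) if (V[which.max(abs(V[, i])), i] < 0) V[, i] <- -V[, i]
  q <- cc %*% V
  ap <- q[, 1]; lr <- q[, 2]
  h <- min(spacing)
  cells <- unique(cbind(floor(ap / h), floor(lr / h)))
  a_fp <- nrow(cells) * h^2
  c1 <- (max(ap) + min(ap)) / 2
  c2 <- (max(lr) + min(lr)) / 2
  a0 <- (max(ap) - min(ap)) / 2
  b0 <- (max(lr) - min(lr)) / 2
  if (a0 <= 0 || b0 <= 0) {
    attr(out, "excluded") <- TRUE
    return(out)
  }
  s <- sqrt(area_fraction * a_fp / (pi * a0 * b0))
  a <- s * a0; b <- s * b0
  inside <- ((ap - c1) / a)^2 + ((lr - c2) / b)^2 <= 1
  if (concavity_depth > 0) {
    # lobe anchored at the posterior (negative AP) pole of the ellipse
    la <- 2 * concavity_depth * a
    lb <- concavity_width * b
    in_lobe <- ((ap - (c1 - a)) / la)^2 + ((lr - c2) / lb)^2 <= 1
    inside <- inside & !in_lobe
  }
  idx <- which(cep_mask)[inside]
  out[idx] <- TRUE
  attr(out, "excluded") <- FALSE
  out
}

#' Hemi-vertebral mask adjacent to an endplate
#'
#' Splits the vertebral body by the plane through its centroid perpendicular
#' to the standard-frame SI axis. The superior half (`SI > 0`) adjoins the
#' superior endplate; the two halves partition the parent mask.
#'
#' @param vertebra_mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param frame [principal_axis_frame()] of the vertebral body.
#' @param side `"superior"` or `"inferior"`.
#' @return logical array, subset of `vertebra_mask`.
#' @export
hemi_vertebra <- function(vertebra_mask, spacing = c(1, 1, 1), frame,
                          side = c("superior", "inferior")) {
  side <- match.arg(side)
  stopifnot(inherits(frame, "standard_frame"))
  q <- .standard_coords(vertebra_mask, spacing, frame)
  keep <- if (side == "superior") q[, 3] > 0 else q[, 3] <= 0
  out <- array(FALSE, dim(vertebra_mask))
  out[which(vertebra_mask)[keep]] <- TRUE
  out
}

#' Central NP region of a disc
#'
#' Keeps disc voxels whose standard-frame AP coordinate lies within the
#' central `ap_fraction` of the disc's AP extent (the NP region), then
#' optionally keeps the SI half adjacent to the named endplate (split at the
#' disc centroid).
#'
#' @param disc_mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param frame [principal_axis_frame()] of the disc.
#' @param ap_fraction central AP fraction retained (default 0.40).
#' @param adjacent `"superior"`, `"inferior"`, or `NULL` for no SI split.
#' @return logical array, subset of `disc_mask`.
#' @export
np_central_region <- function(disc_mask, spacing = c(1, 1, 1), frame,
                              ap_fraction = 0.40, adjacent = NULL) {
  stopifnot(inherits(frame, "standard_frame"),
            ap_fraction > 0, ap_fraction <= 1)
  q <- .standard_coords(disc_mask, spacing, frame)
  ap <- q[, 1]
  lo <- min(ap); hi <- max(ap)
  margin <- (1 - ap_fraction) / 2 * (hi - lo)
  keep <- ap >= lo + margin & ap <= hi - margin
  if (!is.null(adjacent)) {
    adjacent <- match.arg(adjacent, c("superior", "inferior"))
    keep <- keep & (if (adjacent == "superior") q[, 3] > 0 else q[, 3] <= 0)
  }
  out <- array(FALSE, dim(disc_mask))
  out[which(disc_mask)[keep]] <- TRUE
  out
}
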