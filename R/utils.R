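#' @keywords internal
"_PACKAGE"

# Axis convention used throughout: array axis 1 = anterior-posterior (AP),
# axis 2 = left-right (LR), axis 3 = superior-inferior (SI). The SI axis is
# the scanner B0 axis (supine acquisition). World coordinates are in mm with
# the origin at the grid centre, so rigid rotations act about the centre.
AXIS_LABELS <- c("AP", "LR", "SI")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Rotation matrix about an anatomical axis
#'
#' @param axis one of `"AP"`, `"LR"`, `"SI"` (or 1:3).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  if (is.character(axis)) axis <- match(match.arg(axis, AXIS_LABELS), AXIS_LABELS)
  stopifnot(axis %in% 1:3)
  a <- angle_deg * pi / 180
  R <- diag(3)
  idx <- setdiff(1:3, axis)
  R[idx[1], idx[1]] <- cos(a); R[idx[2], idx[2]] <- cos(a)
  R[idx[1], idx[2]] <- -sin(a); R[idx[2], idx[1]] <- sin(a)
  R
}

#' Random rotation matrix
#'
#' Without `max_angle_deg`, draws a rotation uniformly over SO(3) (QR of a
#' Gaussian matrix with the sign fixed so the determinant is +1). With
#' `max_angle_deg`, draws a uniformly random axis and a uniform angle in
#' `[0, max_angle_deg]` -- a bounded perturbation such as a patient's tilt
#' within the scanner. Uses the current RNG stream.
#'
#' @param max_angle_deg optional bound on the rotation angle, degrees.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(max_angle_deg = NULL) {
  if (!is.null(max_angle_deg)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    a <- stats::runif(1, 0, max_angle_deg) * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K)
  }
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' World coordinates of all voxels in a grid
#'
#' Voxel (i, j, k) maps to ((i,j,k) - 1 - (dim - 1)/2) * spacing, i.e. mm
#' coordinates centred on the grid centre.
#'
#' @param dim integer vector of length 3.
#' @param spacing voxel spacing in mm (length 3, recycled from length 1).
#' @return N x 3 matrix (N = prod(dim)) in array order.
#' @keywords internal
grid_world_coords <- function(dim, spacing = c(1, 1, 1)) {
  spacing <- rep_len(spacing, 3)
  ax <- lapply(1:3, function(k) (seq_len(dim[k]) - 1 - (dim[k] - 1) / 2) * spacing[k])
  cbind(
    rep(ax[[1]], times = dim[2] * dim[3]),
    rep(rep(ax[[2]], each = dim[1]), times = dim[3]),
    rep(ax[[3]], each = dim[1] * dim[2])
  )
}

#' World coordinates of the TRUE voxels of a mask
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @return n x 3 matrix of mm coordinates (grid-centre origin).
#' @export
mask_world_coords <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3)
  spacing <- rep_len(spacing, 3)
  ind <- which(mask, arr.ind = TRUE)
  sweep(sweep(ind - 1, 2, (dim(mask) - 1) / 2), 2, spacing, `*`)
}

#' Resample a volume under a rigid rotation about the grid centre
#'
#' Returns the rotated image: the output value at world coordinate p is the
#' input value at t(rotation) %*% p. Nearest-neighbour sampling is used for
#' label masks (no label mixing), trilinear for intensity maps.
#'
#' @param vol 3D numeric or logical array.
#' @param rotation 3x3 rotation matrix to apply to the image.
#' @param spacing voxel spacing in mm.
#' @param method `"nearest"` or `"linear"`.
#' @param fill value used outside the input grid.
#' @return array of the same shape as `vol`.
#' @export
rotate_volume <- function(vol, rotation, spacing = c(1, 1, 1),
                          method = c("nearest", "linear"), fill = 0) {
  method <- match.arg(method)
  stopifnot(is_rotation(rotation, tol = 1e-6))
  dm <- dim(vol)
  spacing <- rep_len(spacing, 3)
  was_logical <- is.logical(vol)
  v <- if (was_logical) (vol * 1) else vol
  p <- grid_world_coords(dm, spacing)
  q <- p %*% rotation  # row-vectors: q_i = t(rotation) %*% p_i
  # continuous voxel indices (1-based)
  idx <- sweep(sweep(q, 2, spacing, `/`), 2, (dm - 1) / 2 + 1, `+`)
  out <- rep(fill, nrow(idx))
  if (method == "nearest") {
    ri <- round(idx)
    ok <- ri[, 1] >= 1 & ri[, 1] <= dm[1] & ri[, 2] >= 1 & ri[, 2] <= dm[2] &
      ri[, 3] >= 1 & ri[, 3] <= dm[3]
    lin <- ri[ok, 1] + (ri[ok, 2] - 1) * dm[1] + (ri[ok, 3] - 1) * dm[1] * dm[2]
    out[ok] <- v[lin]
  } else {
    f <- floor(idx)
    ok <- f[, 1] >= 1 & f[, 1] <= dm[1] - 1 & f[, 2] >= 1 & f[, 2] <= dm[2] - 1 &
      f[, 3] >= 1 & f[, 3] <= dm[3] - 1
    fi <- f[ok, , drop = FALSE]
    w <- idx[ok, , drop = FALSE] - fi
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      lin <- (fi[, 1] + dx) + (fi[, 2] + dy - 1) * dm[1] +
        (fi[, 3] + dz - 1) * dm[1] * dm[2]
      wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
        (if (dy) w[, 2] else 1 - w[, 2]) *
        (if (dz) w[, 3] else 1 - w[, 3])
      acc <- acc + wt * v[lin]
    }
    out[ok] <- acc
  }
  out <- array(out, dm)
  if (was_logical) out > 0.5 else out
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of equal shape.
#' @return Dice coefficient in [0, 1] (1 for two empty masks).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
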