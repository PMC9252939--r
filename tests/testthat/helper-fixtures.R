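# Fixtures are generated in code: simple analytic masks and decay series
# with known ground truth, plus independent brute-force oracles used to
# cross-check the package's fitters.

# axis-aligned box mask centred in the grid; extents in voxels
make_box_mask <- function(grid = c(64, 64, 64), extents = c(50, 20, 10)) {
  co <- expand.grid(i = seq_len(grid[1]), j = seq_len(grid[2]), k = seq_len(grid[3]))
  ctr <- (grid + 1) / 2
  m <- abs(co$i - ctr[1]) <= (extents[1] - 1) / 2 &
    abs(co$j - ctr[2]) <= (extents[2] - 1) / 2 &
    abs(co$k - ctr[3]) <= (extents[3] - 1) / 2
  array(m, grid)
}

# thin sheet with an elliptical footprint, tilted by angle_deg from the SI
# axis in the sagittal plane (angle between the sheet's in-plane sagittal
# direction and SI)
make_elliptical_sheet <- function(grid = c(64, 64, 64), angle_deg = 54.7,
                                  semi_inplane = 14, semi_lr = 10,
                                  half_thick = 1) {
  th <- angle_deg * pi / 180
  v <- c(sin(th), 0, cos(th))
  nrm <- c(-cos(th), 0, sin(th))
  p <- spineqmr::mask_world_coords(array(TRUE, grid))
  u <- p %*% v; w <- p[, 2]; off <- p %*% nrm
  m <- abs(off) <= half_thick & (u / semi_inplane)^2 + (w / semi_lr)^2 <= 1
  array(m, grid)
}

# build a 1-voxel-thick stack of decay curves as a decay_series
series_from_matrix <- function(y, times) {
  n <- nrow(y)
  vol <- array(NA_real_, c(n, 1, 1, length(times)))
  for (j in seq_along(times)) vol[, , , j] <- y[, j]
  spineqmr::decay_series(vol, times)
}

# independent brute-force oracle: dense grid search over tau with S0
# profiled out (linear in the exponentials), then local refinement
oracle_fit_tau <- function(yv, times, tau_range = c(1, 300)) {
  sse <- function(tt) {
    e <- exp(-times / tt)
    s <- sum(yv * e) / sum(e * e)
    sum((s * e - yv)^2)
  }
  grid <- seq(tau_range[1], tau_range[2], by = 0.5)
  t0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
  stats::optimize(sse, c(max(tau_range[1], t0 - 1), min(tau_range[2], t0 + 1)),
                  tol = 1e-10)$minimum
}

# independent plane-fit oracle for the CEP sheet angle: total least-squares
# plane through the voxel centres (smallest-eigenvector normal), then the
# sheet-vs-B0 angle from the normal's SI component
oracle_sheet_angle <- function(mask, spacing = c(1, 1, 1)) {
  co <- spineqmr::mask_world_coords(mask, spacing)
  cc <- sweep(co, 2, colMeans(co))
  n <- eigen(stats::cov(cc), symmetric = TRUE)$vectors[, 3]
  asin(min(1, abs(n[3]))) * 180 / pi
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
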