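# Voxelwise mono-exponential relaxometry: S(t) = S0 * exp(-t / tau), fitted
# per voxel to a multi-echo (TE -> T2*) or spin-lock (TSL -> T1rho) series.
# The same fitter serves both contrasts; only the time axis differs.
#
# Two methods are provided:
#   log_linear  closed-form weighted least squares on log(S), weights S^2
#               (the standard variance-stabilising weights for log-domain
#               exponential fitting with additive noise);
#   nonlinear   untransformed least squares, Levenberg-Marquardt, vectorised
#               across voxels, initialised from the log-linear solution.
# Voxels with any nonpositive signal at a used time point are flagged
# invalid rather than clamped, to avoid log-domain bias.

#' Build a decay series from a list of volumes
#'
#' @param volumes 4D array (last axis = time point) or list of 3D arrays on
#'   a common grid.
#' @param times_ms acquisition times (TE or TSL) in ms, strictly increasing,
#'   length >= 2.
#' @param mask logical array of voxels to fit; default all voxels.
#' @param spacing voxel spacing in mm.
#' @return object of class `decay_series`.
#' @export
decay_series <- function(volumes, times_ms, mask = NULL, spacing = c(1, 1, 1)) {
  if (is.list(volumes)) {
    dm <- dim(volumes[[1]])
    stopifnot(all(vapply(volumes, function(v) identical(dim(v), dm), logical(1))))
    volumes <- array(unlist(volumes), c(dm, length(volumes)))
  }
  stopifnot(length(dim(volumes)) == 4)
  if (length(times_ms) < 2)
    stop("at least 2 time points are required")
  if (length(times_ms) != dim(volumes)[4])
    stop("length(times_ms) must match the number of volumes")
  if (any(times_ms < 0) || any(diff(times_ms) <= 0))
    stop("times_ms must be >= 0 and strictly increasing")
  dm <- dim(volumes)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(identical(dim(mask), dm))
  if (!any(mask)) stop("mask is empty")
  structure(list(volumes = volumes, times_ms = times_ms, mask = mask,
                 spacing = rep_len(spacing, 3)),
            class = "decay_series")
}

# weighted log-linear fit; y: n x T matrix of positive signals
.fit_log_linear <- function(y, t) {
  w <- y^2
  ly <- log(y)
  sw <- rowSums(w)
  swt <- w %*% t
  swt2 <- w %*% t^2
  swy <- rowSums(w * ly)
  swty <- (w * ly) %*% t
  denom <- sw * swt2 - swt^2
  slope <- (sw * swty - swt * swy) / denom
  inter <- (swy - slope * swt) / sw
  list(s0 = exp(as.numeric(inter)), rate = -as.numeric(slope))
}

# vectorised Levenberg-Marquardt refinement of (S0, R = 1/tau)
.fit_lm <- function(y, t, s0, rate, max_iter = 200, tol = 1e-12) {
  n <- nrow(y)
  lambda <- rep(1e-3, n)
  sse <- function(s0v, rv) {
    E <- exp(-outer(rv, t))
    rowSums((s0v * E - y)^2)
  }
  cur <- sse(s0, rate)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(rate, t))
    pred <- s0 * E
    res <- pred - y
    D <- -pred * matrix(t, n, length(t), byrow = TRUE)  # d pred / d rate
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * D)
    a22 <- rowSums(D * D)
    g1 <- rowSums(E * res)
    g2 <- rowSums(D * res)
    m11 <- a11 * (1 + lambda)
    m22 <- a22 * (1 + lambda)
    det_ <- m11 * m22 - a12^2
    det_[abs(det_) < 1e-300] <- 1e-300
    d1 <- (-g1 * m22 + g2 * a12) / det_
    d2 <- (-g2 * m11 + g1 * a12) / det_
    s0_new <- s0 + d1
    rate_new <- rate + d2
    new <- sse(s0_new, rate_new)
    better <- is.finite(new) & new <= cur
    s0[better] <- s0_new[better]
    rate[better] <- rate_new[better]
    improve <- cur[better] - new[better]
    cur[better] <- new[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-12)
    lambda[!better] <- pmin(lambda[!better] * 5, 1e12)
    if (any(better)) {
      step <- max(abs(d1[better]) / (abs(s0[better]) + 1e-12),
                  abs(d2[better]) / (abs(rate[better]) + 1e-12))
      if (step < tol && max(improve / (cur[better] + 1e-300)) < tol) break
    } else if (all(lambda >= 1e11)) break
  }
  list(s0 = s0, rate = rate)
}

#' Fit voxelwise mono-exponential decay
#'
#' Fits `S(t) = S0 * exp(-t / tau)` per masked voxel and returns tau, S0 and
#' per-voxel goodness of fit. Voxels with nonpositive signal at any time
#' point, tau outside `tau_bounds`, or r-squared below `r2_min` are flagged
#' invalid and excluded from downstream regional means.
#'
#' @param series a [decay_series()].
#' @param method `"nonlinear"` (default; log-linear initialisation then
#'   Levenberg-Marquardt on the untransformed signal) or `"log_linear"`.
#' @param tau_bounds admissible tau range in ms, default `c(1, 200)`.
#' @param r2_min minimum r-squared for a voxel to be valid, default 0.7.
#' @return object of class `relaxation_map`: list of 3D arrays `tau_ms`,
#'   `s0`, `r_squared`, `valid` (NA outside the mask).
#' @examples
#' t <- c(0, 10, 20, 30)
#' vol <- array(rep(100 * exp(-t / 25), each = 8), c(2, 2, 2, 4))
#' fit <- fit_decay(decay_series(vol, t))
#' range(fit$tau_ms)
#' @export
fit_decay <- function(series, method = c("nonlinear", "log_linear"),
                      tau_bounds = c(1, 200), r2_min = 0.7) {
  method <- match.arg(method)
  stopifnot(inherits(series, "decay_series"),
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[2] > tau_bounds[1])
  t <- series$times_ms
  dm <- dim(series$mask)
  vox <- which(series$mask)
  nvol <- prod(dm)
  y <- matrix(series$volumes, nrow = nvol)[vox, , drop = FALSE]

  positive <- rowSums(y <= 0) == 0
  tau <- rep(NA_real_, length(vox))
  s0 <- rep(NA_real_, length(vox))
  r2 <- rep(NA_real_, length(vox))

  if (any(positive)) {
    yp <- y[positive, , drop = FALSE]
    init <- .fit_log_linear(yp, t)
    if (method == "nonlinear") {
      ok <- is.finite(init$s0) & is.finite(init$rate) & init$rate > 0
      init$rate[!ok] <- 1 / mean(tau_bounds)
      init$s0[!ok] <- yp[, 1][!ok]
      fit <- .fit_lm(yp, t, init$s0, init$rate)
    } else {
      fit <- init
    }
    tau_p <- 1 / fit$rate
    pred <- fit$s0 * exp(-outer(fit$rate, t))
    ssr <- rowSums((yp - pred)^2)
    sst <- rowSums(sweep(yp, 1, rowMeans(yp))^2)
    r2_p <- ifelse(sst > 0, 1 - ssr / sst, as.numeric(ssr <= 1e-12))
    tau[positive] <- tau_p
    s0[positive] <- fit$s0
    r2[positive] <- r2_p
  }

  valid <- positive & is.finite(tau) & tau >= tau_bounds[1] &
    tau <= tau_bounds[2] & is.finite(r2) & r2 >= r2_min
  if (!any(valid))
    stop("no valid voxels: the fitted map is empty")

  full <- function(v) {
    a <- array(NA_real_, dm); a[vox] <- v; a
  }
  valid_arr <- array(FALSE, dm); valid_arr[vox] <- valid
  structure(list(
    tau_ms = full(tau), s0 = full(s0), r_squared = full(r2),
    valid = valid_arr,
    method = method, tau_bounds = tau_bounds, r2_min = r2_min,
    times_ms = t, spacing = series$spacing
  ), class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  n <- sum(x$valid)
  cat("<relaxation_map>", x$method, "fit,", n, "valid voxels\n")
  if (n) cat("  tau:", sprintf("%.2f", stats::median(x$tau_ms[x$valid])),
             "ms (median), bounds [", x$tau_bounds[1], ",", x$tau_bounds[2], "]\n")
  invisible(x)
}

#' Mean of a parameter map over a region
#'
#' Arithmetic mean of the fitted quantity over the valid voxels of a region.
#' Works for [fit_decay()] maps (`tau_ms`) and [compute_bmff()] maps
#' (`bmff_pct`).
#'
#' @param map a `relaxation_map` or `bmff_map`.
#' @param region_mask logical array on the map grid.
#' @return list with `mean` (NA if no valid voxel) , `n_valid`, and
#'   `missing` flag (TRUE when the region holds no valid voxel, marking the
#'   unit for downstream exclusion).
#' @export
map_region_mean <- function(map, region_mask) {
  values <- if (inherits(map, "relaxation_map")) map$tau_ms
  else if (inherits(map, "bmff_map")) map$bmff_pct
  else stop("map must be a relaxation_map or bmff_map")
  stopifnot(identical(dim(region_mask), dim(values)))
  sel <- region_mask & map$valid
  n <- sum(sel, na.rm = TRUE)
  list(mean = if (n > 0) mean(values[sel]) else NA_real_,
       n_valid = as.integer(n),
       missing = n == 0)
}
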