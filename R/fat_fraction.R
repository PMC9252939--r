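# Vertebral bone-marrow fat fraction from co-registered magnitude fat and
# water images: BMFF(v) = 100 * F(v) / (F(v) + W(v)). Full multi-echo
# water-fat decomposition (field map, R2* correction) happens upstream in
# the reconstruction; this module consumes its fat/water outputs.

#' Compute a bone-marrow fat-fraction map
#'
#' @param fat,water 3D arrays on a common grid (arbitrary units; negative
#'   values are floor-clamped to 0 before division).
#' @param mask optional logical array restricting the computation (e.g. a
#'   vertebral label); default all voxels.
#' @param min_total_signal voxels with `F + W` below this are invalid;
#'   default `1e-6 * max(F + W)`.
#' @param n_central_slices if not `NULL`, restrict the mask to this many
#'   central sagittal (LR-axis) slices, emulating mid-sagittal analysis
#'   (typical value 5).
#' @return object of class `bmff_map`: list of arrays `bmff_pct` (percent,
#'   clamped to [0, 100]) and `valid`.
#' @examples
#' f <- array(30, c(4, 4, 4)); w <- array(70, c(4, 4, 4))
#' m <- compute_bmff(f, w)
#' unique(m$bmff_pct[m$valid])  # 30
#' @export
compute_bmff <- function(fat, water, mask = NULL, min_total_signal = NULL,
                         n_central_slices = NULL) {
  stopifnot(identical(dim(fat), dim(water)), length(dim(fat)) == 3)
  dm <- dim(fat)
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(identical(dim(mask), dm))
  if (!is.null(n_central_slices)) {
    stopifnot(n_central_slices >= 1)
    mid <- (dm[2] + 1) / 2
    keep <- abs(seq_len(dm[2]) - mid) <= (n_central_slices - 1) / 2 + 1e-9
    mask <- mask & rep(rep(keep, each = dm[1]), times = dm[3])
  }
  f <- pmax(fat, 0)
  w <- pmax(water, 0)
  tot <- f + w
  if (is.null(min_total_signal)) min_total_signal <- 1e-6 * max(tot)
  valid <- mask & tot >= min_total_signal & tot > 0
  if (!any(valid)) stop("no voxels above min_total_signal: empty BMFF map")
  bmff <- array(NA_real_, dm)
  bmff[valid] <- pmin(pmax(100 * f[valid] / tot[valid], 0), 100)
  structure(list(bmff_pct = bmff, valid = valid,
                 min_total_signal = min_total_signal),
            class = "bmff_map")
}
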