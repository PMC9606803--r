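#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)` with `r` clipped to plus/minus `1 - eps` so perfect
#' correlations map to a finite value.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param eps Clipping constant (default 1e-7).
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Mean time series over a seed region
#'
#' @param bold A [bold_dataset()].
#' @param seed Logical 3-D seed mask on the same grid.
#' @return Numeric vector of length T (frame-wise mean over seed voxels).
#' @export
extract_seed_series <- function(bold, seed) {
  stopifnot(inherits(bold, "bold_dataset"))
  d <- dim(bold$data)
  seed <- array(as.logical(seed), d[1:3])
  if (!any(seed)) stop("empty seed mask", call. = FALSE)
  flat <- matrix(bold$data, prod(d[1:3]), d[4L])
  colMeans(flat[as.vector(seed), , drop = FALSE])
}

#' Seed-based functional connectivity map (Fisher z)
#'
#' Pearson correlation of every in-mask voxel's series with the mean seed
#' series, Fisher z-transformed. Seed voxels are included in the map (their
#' z is near `atanh(1 - eps)` for a single-voxel seed). Zero-variance voxel
#' series get `r = 0`.
#'
#' @param bold A [bold_dataset()] of preprocessed series.
#' @param seed Logical 3-D seed mask (see also [sphere_seed()]).
#' @param mask Logical 3-D analysis mask.
#' @param eps Fisher-z clipping constant.
#' @return A [voxel_map()] of kind `"fc_z"`.
#' @export
compute_seed_fc_map <- function(bold, seed, mask, eps = 1e-7) {
  s <- extract_seed_series(bold, seed)
  if (stats::sd(s) < 1e-12)
    stop("constant seed series", call. = FALSE)
  d <- dim(bold$data)
  mask <- array(as.logical(mask), d[1:3])
  vox <- which(as.vector(mask))
  y <- t(matrix(bold$data, prod(d[1:3]), d[4L])[vox, , drop = FALSE])
  sds <- apply(y, 2L, stats::sd)
  z <- sweep(y, 2L, colMeans(y))
  z <- sweep(z, 2L, ifelse(sds < 1e-12, 1, sds), "/")
  z[, sds < 1e-12] <- 0
  sz <- (s - mean(s)) / stats::sd(s)
  r <- as.numeric(crossprod(z, sz)) / (length(s) - 1)
  vals <- array(0, d[1:3])
  vals[vox] <- fisher_z(r, eps)
  voxel_map(vals, bold$affine, "fc_z", mask)
}

#' Spherical seed mask around a mm coordinate
#'
#' Alternative to using a full suprathreshold cluster as the seed: all
#' voxels whose centre lies within `radius_mm` of `center_mm`.
#'
#' @param center_mm Length-3 mm coordinate.
#' @param radius_mm Sphere radius in mm.
#' @param affine 4x4 voxel-to-mm matrix (0-based).
#' @param dims Grid dimensions.
#' @param within Optional logical mask to intersect with (e.g. brain).
#' @return Logical 3-D array.
#' @export
sphere_seed <- function(center_mm, radius_mm, affine, dims, within = NULL) {
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  mm <- voxel_to_mm(idx, affine)
  d2 <- rowSums(sweep(mm, 2L, center_mm) ^ 2)
  out <- array(d2 <= radius_mm ^ 2, dims)
  if (!is.null(within)) out <- out & within
  if (!any(out)) stop("sphere seed contains no voxels", call. = FALSE)
  out
}
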