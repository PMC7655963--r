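#' BOLD series container
#'
#' Wraps a subject's 4-D BOLD array together with its voxel-index-to-world
#' affine transform and repetition time. Voxel indices are 0-based when mapped
#' through the affine (NIfTI convention), so the world position of voxel
#' `(i, j, k)` (1-based R indices) is `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param data 4-D numeric array `(i, j, k, t)` of BOLD values (arbitrary units).
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param tr repetition time in seconds (> 0).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine = diag(4), tr = 2.5) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (i, j, k, t)")
  if (dim(data)[4] < 1L) stop("`data` must contain at least one volume")
  check_affine(affine)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  structure(list(data = data, affine = unname(affine), tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Number of volumes in a BOLD series
#' @param series a [bold_series()].
#' @return Integer volume count.
#' @export
n_volumes <- function(series) dim(series$data)[4]

#' Rigid-body motion-parameter trace
#'
#' A per-volume table of the six rigid-body realignment parameters, in the SPM
#' dialect: three translations in mm (`x`, `y`, `z`) followed by three
#' rotations in radians (`alpha`, `beta`, `gamma`).
#'
#' @param params numeric matrix with one row per volume and 6 columns.
#' @return A `motion_trace`: a numeric matrix with fixed column names.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("motion trace must have 6 columns (x, y, z translations mm; ",
         "alpha, beta, gamma rotations rad)")
  if (nrow(params) < 1L) stop("motion trace must have at least one row")
  colnames(params) <- c("x", "y", "z", "alpha", "beta", "gamma")
  class(params) <- c("motion_trace", class(matrix()))
  params
}

#' Gray-matter inclusion mask
#'
#' @param mask logical 3-D array; `TRUE` marks included voxels.
#' @param affine 4x4 voxel-to-world transform shared with the BOLD grid.
#' @param source_threshold the probability cut that produced the mask.
#' @return An object of class `gm_mask`.
#' @seealso [make_gm_mask()]
#' @export
gm_mask <- function(mask, affine = diag(4), source_threshold = NA_real_) {
  if (length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a logical 3-D array")
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels")
  check_affine(affine)
  structure(list(mask = mask, affine = unname(affine),
                 source_threshold = source_threshold),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("<gm_mask> %d voxels of %s (threshold %s)\n", sum(x$mask),
              paste(dim(x$mask), collapse = " x "),
              format(x$source_threshold)))
  invisible(x)
}

#' @export
print.icc_map <- function(x, ...) {
  cat(sprintf("<icc_map> mode = %s%s, %d mask voxels, %s\n", x$mode,
              if (x$mode == "whole") "" else sprintf(" (d_thr = %g mm)", x$d_thr_mm),
              sum(x$mask), if (x$standardized) "z-standardized" else "unstandardized"))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, contrast = %s, dof = %d, %d mask voxels\n",
              x$kind, x$contrast, x$dof, sum(x$mask)))
  invisible(x)
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be invertible")
  invisible(TRUE)
}

#' World coordinates of voxel centers
#'
#' Maps 1-based array indices through a NIfTI-style affine (0-based voxel
#' indices) to world mm coordinates.
#'
#' @param ijk integer matrix of 1-based voxel indices (rows are voxels).
#' @param affine 4x4 voxel-to-world transform.
#' @return Numeric matrix of world coordinates, one row per voxel.
#' @export
voxel_world_coords <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L) - 1
  sweep(ijk %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4], "+")
}

#' Extract the in-mask time-series matrix of a BOLD series
#'
#' @param series a [bold_series()].
#' @param mask logical 3-D array or [gm_mask()].
#' @return T x V numeric matrix, columns ordered by the mask's linear
#'   (column-major) voxel order.
#' @export
mask_series_matrix <- function(series, mask) {
  m <- if (inherits(mask, "gm_mask")) mask$mask else mask
  d <- dim(series$data)
  if (!all(dim(m) == d[1:3]))
    stop("mask dimensions do not match the BOLD grid")
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  t(flat[as.vector(m), , drop = FALSE])
}

#' Place per-voxel values back into a 3-D volume
#'
#' @param values numeric vector, one value per in-mask voxel (mask linear order).
#' @param mask logical 3-D array or [gm_mask()].
#' @param fill value for out-of-mask voxels.
#' @return 3-D numeric array.
#' @export
unmask <- function(values, mask, fill = 0) {
  m <- if (inherits(mask, "gm_mask")) mask$mask else mask
  out <- array(fill, dim(m))
  out[m] <- values
  out
}
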