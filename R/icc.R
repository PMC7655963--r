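#' Threshold a tissue-probability map into a gray-matter mask
#'
#' A voxel is included iff its gray-matter probability strictly exceeds the
#' threshold (default 0.2), so a voxel at exactly the threshold is excluded.
#'
#' @param probability_map 3-D numeric array of probabilities in `[0, 1]`, or a
#'   list with elements `map` and `affine` (as produced by
#'   [generate_cohort()]).
#' @param threshold probability cut; default 0.2.
#' @param affine 4x4 voxel-to-world transform (ignored when
#'   `probability_map` carries its own).
#' @return A [gm_mask()].
#' @export
make_gm_mask <- function(probability_map, threshold = 0.2, affine = diag(4)) {
  if (is.list(probability_map)) {
    affine <- probability_map$affine
    probability_map <- probability_map$map
  }
  if (length(dim(probability_map)) != 3L)
    stop("`probability_map` must be a 3-D array")
  if (min(probability_map) < 0 || max(probability_map) > 1)
    stop("probabilities must lie in [0, 1]")
  if (threshold < 0 || threshold >= 1) stop("`threshold` must lie in [0, 1)")
  m <- probability_map > threshold
  if (!any(m)) stop("empty gray-matter mask at threshold ", threshold)
  gm_mask(m, affine, source_threshold = threshold)
}

#' Compute an intrinsic connectivity contrast map
#'
#' For every in-mask voxel `i`, the unstandardized ICC is the mean squared
#' Pearson correlation between voxel `i`'s time series and every other
#' included voxel `j`:
#' `ICC(i) = (1 / n_i) * sum_{j in stratum(i), j != i} r(i, j)^2`.
#' The stratum is all other mask voxels (`mode = "whole"`), the voxels within
#' Euclidean world distance `d_thr_mm` of voxel `i` (`"short"`, boundary
#' inclusive), or those strictly beyond it (`"long"`). Distances are measured
#' between voxel centers in world mm through the affine. The self pair is
#' always excluded.
#'
#' By default each mode divides by its own included-pair count `n_i`, so all
#' three modes share the `[0, 1]` scale of a mean squared correlation and the
#' count-weighted decomposition `S_whole = S_short + S_long` holds exactly.
#' `denominator = "global_n"` instead divides every sum by the mask size `n`
#' (the literal `1/n` normalization).
#'
#' The engine accumulates correlations in voxel chunks sized to a memory cap
#' and never materializes the full pair matrix; results are bit-identical
#' for any chunk size. Zero-variance voxel series contribute `r = 0` to all
#' pairs (flagged in the output) rather than being dropped, preserving mask
#' geometry.
#'
#' @param series a denoised [bold_series()] with at least 8 timepoints.
#' @param mask a [gm_mask()] (at least 2 voxels) on the same grid.
#' @param mode `"whole"`, `"short"`, or `"long"`.
#' @param d_thr_mm distance threshold in mm for the short/long strata
#'   (default 75).
#' @param mem_mb approximate memory cap (MiB) for the chunked accumulation.
#' @param denominator `"stratum"` (default) or `"global_n"`.
#' @return An object of class `icc_map`: list with 3-D `values`, `counts`
#'   (included-pair counts per voxel), logical `mask` and `zero_variance`
#'   arrays, `affine`, `mode`, `d_thr_mm`, `denominator`, and
#'   `standardized = FALSE`.
#' @export
compute_icc <- function(series, mask, mode = c("whole", "short", "long"),
                        d_thr_mm = 75, mem_mb = 512,
                        denominator = c("stratum", "global_n")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!inherits(mask, "gm_mask")) stop("`mask` must be a gm_mask")
  nt <- n_volumes(series)
  if (nt < 8L) stop("need at least 8 timepoints, got ", nt)
  if (mode != "whole" && d_thr_mm <= 0) stop("`d_thr_mm` must be > 0")

  x <- mask_series_matrix(series, mask)            # T x V
  v <- ncol(x)
  if (v < 2L) stop("mask must contain at least 2 voxels")

  ## column-standardize to unit norm so crossprod gives Pearson r
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  zero_var <- nrm == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel series; their correlations ",
            "are taken as 0")
    nrm[zero_var] <- 1
  }
  z <- sweep(x, 2L, nrm, "/")
  z[, zero_var] <- 0

  coords <- matrix(0, 1L, 3L)
  if (mode != "whole") {
    ijk <- which(mask$mask, arr.ind = TRUE)
    coords <- voxel_world_coords(ijk, mask$affine)
  }
  mode_code <- match(mode, c("whole", "short", "long")) - 1L

  ## the compiled kernel accumulates each voxel's sum in a fixed pair order,
  ## so results are bit-identical regardless of how the mask is chunked; the
  ## chunk size only bounds working-set memory
  rows_per_chunk <- max(1L, min(v, floor(mem_mb * 2^20 / (8 * 2 * v))))
  sums <- numeric(v)
  counts <- integer(v)
  start <- 1L
  while (start <= v) {
    idx <- start:min(v, start + rows_per_chunk - 1L)
    res <- .icc_chunk_kernel(z, as.integer(idx), mode_code, coords,
                             d_thr_mm^2)
    sums[idx] <- res$sums
    counts[idx] <- res$counts
    start <- start + length(idx)
  }

  denom <- if (denominator == "global_n") rep(v, v) else pmax(counts, 1L)
  values <- sums / denom
  values[counts == 0] <- 0

  structure(list(values = unmask(values, mask),
                 counts = unmask(as.integer(counts), mask, fill = 0L),
                 mask = mask$mask, zero_variance = unmask(zero_var, mask, FALSE),
                 affine = mask$affine, mode = mode,
                 d_thr_mm = if (mode == "whole") NA_real_ else d_thr_mm,
                 denominator = denominator, standardized = FALSE),
            class = "icc_map")
}

#' z-standardize an ICC map
#'
#' Subtracts the in-mask mean and divides by the in-mask population
#' (divide-by-N) standard deviation, leaving mean 0 and s.d. 1 over the mask.
#' Standardization is monotone, so the voxel rank order is unchanged.
#' Idempotent on already-standardized input.
#'
#' @param map an `icc_map` from [compute_icc()].
#' @return The map with standardized `values` and `standardized = TRUE`.
#' @export
standardize_map <- function(map) {
  if (!inherits(map, "icc_map")) stop("`map` must be an icc_map")
  vals <- map$values[map$mask]
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))
  if (sdev == 0) stop("cannot standardize a constant map (zero s.d.)")
  map$values <- unmask((vals - mu) / sdev, map$mask)
  map$standardized <- TRUE
  map
}
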