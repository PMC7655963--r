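#' Build a spherical region-of-interest mask
#'
#' A voxel belongs to the sphere iff the world distance from its center to
#' the ROI center is at most the radius (boundary inclusive). If the sphere
#' falls entirely between voxel centers, the nearest voxel is forced in so
#' the ROI is never empty.
#'
#' @param center world-mm coordinates (length 3).
#' @param radius_mm sphere radius (> 0).
#' @param dim grid dimensions (3 voxel counts).
#' @param affine 4x4 voxel-to-world transform.
#' @return Logical 3-D array.
#' @export
make_spherical_roi <- function(center, radius_mm, dim, affine) {
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  if (length(center) != 3L) stop("`center` must be length 3 (world mm)")
  vox <- solve(affine, c(center, 1))[1:3] + 1     # 1-based fractional index
  if (any(vox < 0.5) || any(vox > dim + 0.5))
    stop("ROI center lies outside the volume bounding box")
  ijk <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  world <- voxel_world_coords(ijk, affine)
  d2 <- colSums((t(world) - center)^2)
  mask <- array(d2 <= radius_mm^2, dim)
  if (!any(mask)) mask[ijk[which.min(d2), , drop = FALSE]] <- TRUE
  mask
}

#' Seed-based correlation map
#'
#' Correlates the mean time series of a seed ROI with every target voxel's
#' series (Pearson r), producing a 3-D connectivity map.
#'
#' @param series a denoised [bold_series()].
#' @param roi_mask logical 3-D array (non-empty) selecting the seed voxels.
#' @param target_mask logical 3-D array or [gm_mask()] of voxels to map
#'   (default: all voxels).
#' @return List of class `seed_map` with 3-D `values` (r, 0 outside the
#'   target mask), `mask`, and `affine`.
#' @export
seed_connectivity_map <- function(series, roi_mask, target_mask = NULL) {
  d <- dim(series$data)[1:3]
  if (!is.logical(roi_mask) || !all(dim(roi_mask) == d))
    stop("`roi_mask` must be a logical array on the BOLD grid")
  if (!any(roi_mask)) stop("`roi_mask` is empty")
  if (is.null(target_mask)) target_mask <- array(TRUE, d)
  if (inherits(target_mask, "gm_mask")) target_mask <- target_mask$mask
  ref <- rowMeans(mask_series_matrix(series, roi_mask))
  if (stats::sd(ref) == 0) stop("seed ROI mean series has zero variance")
  y <- mask_series_matrix(series, target_mask)
  yc <- sweep(y, 2L, colMeans(y), "-")
  nrm <- sqrt(colSums(yc^2))
  refc <- ref - mean(ref)
  r <- drop(crossprod(refc, yc)) / (sqrt(sum(refc^2)) * ifelse(nrm == 0, 1, nrm))
  r[nrm == 0] <- 0
  structure(list(values = unmask(r, target_mask), mask = target_mask,
                 affine = series$affine), class = "seed_map")
}

#' Group-level thresholded seed connectivity map
#'
#' Fisher r-to-z transforms each subject's correlation map (variance
#' stabilization; switch off with `fisher = FALSE` to test raw r), runs a
#' voxel-wise one-sample t test, and applies permutation cluster-extent FWE
#' correction (sign flipping) at the given cluster-defining threshold. The
#' output is the binary mask of voxels inside significant clusters.
#'
#' @param seed_maps list of `seed_map`s (>= 3 subjects) sharing grids.
#' @param cdt_p cluster-defining threshold (one-sided).
#' @param n_perm permutation count.
#' @param seed RNG seed (mandatory).
#' @param alpha cluster-level significance level.
#' @param connectivity cluster connectivity.
#' @param fisher apply the r-to-z transform before testing.
#' @return List with `mask` (logical 3-D significance mask), `clusters`
#'   (a `cluster_table`), and `affine`.
#' @export
group_seed_map <- function(seed_maps, cdt_p = 0.001, n_perm = 1000L, seed,
                           alpha = 0.05, connectivity = 26L, fisher = TRUE) {
  if (length(seed_maps) < 3L) stop("need at least 3 subjects")
  if (missing(seed)) stop("`seed` is required for reproducible inference")
  as_icc <- lapply(seed_maps, function(m) {
    v <- m$values
    if (fisher) v <- atanh(pmin(pmax(v, -1 + 1e-7), 1 - 1e-7))
    structure(list(values = v, mask = m$mask, affine = m$affine,
                   standardized = TRUE), class = "icc_map")
  })
  tab <- permutation_cluster_correction(as_icc, cdt_p = cdt_p, n_perm = n_perm,
                                        seed = seed, alpha = alpha,
                                        connectivity = connectivity)
  list(mask = attr(tab, "significance_mask"), clusters = tab,
       affine = seed_maps[[1]]$affine)
}

# Nearest-neighbour resampling of a logical template onto a target grid.
resample_mask_nn <- function(mask, from_affine, to_dim, to_affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(to_dim[1]), j = seq_len(to_dim[2]),
                               k = seq_len(to_dim[3])))
  world <- voxel_world_coords(ijk, to_affine)
  src <- t(solve(from_affine) %*% rbind(t(world), 1))[, 1:3, drop = FALSE] + 1
  src <- round(src)
  ok <- src[, 1] >= 1 & src[, 1] <= dim(mask)[1] &
    src[, 2] >= 1 & src[, 2] <= dim(mask)[2] &
    src[, 3] >= 1 & src[, 3] <= dim(mask)[3]
  out <- rep(FALSE, nrow(ijk))
  out[ok] <- mask[src[ok, , drop = FALSE]]
  array(out, to_dim)
}

#' RSN overlap ratio
#'
#' Fraction of a resting-state-network template covered by a corrected
#' significance mask: `R = N_overlap / N_RSN`, where `N_overlap` is the
#' number of template voxels inside the mask and `N_RSN` the template size.
#' `R = 1` means the template lies fully within the corrected map; `R = 0`
#' means no overlap.
#'
#' @param significance_mask logical 3-D array (corrected group map).
#' @param template a template list (`name`, `mask`, `affine`) as produced by
#'   [generate_cohort()], or a logical 3-D array.
#' @param mask_affine affine of `significance_mask`; only needed when the
#'   template grid differs and must be resampled (nearest neighbour).
#' @return List with `ratio`, `n_overlap`, `n_rsn`.
#' @export
overlap_ratio <- function(significance_mask, template, mask_affine = NULL) {
  tm <- if (is.list(template)) template$mask else template
  if (!any(tm)) stop("template mask is empty")
  if (!all(dim(tm) == dim(significance_mask))) {
    if (is.null(mask_affine) || !is.list(template))
      stop("template grid differs from the mask grid; supply affines to resample")
    tm <- resample_mask_nn(tm, template$affine, dim(significance_mask),
                           mask_affine)
    if (!any(tm)) stop("template mask is empty after resampling")
  }
  n_rsn <- sum(tm)
  n_overlap <- sum(tm & significance_mask)
  list(ratio = n_overlap / n_rsn, n_overlap = n_overlap, n_rsn = n_rsn)
}

#' Overlap profile across the 14 canonical RSN templates
#'
#' Computes the overlap ratio of one seed's corrected connectivity map
#' against each of the 14 canonical templates, in the fixed order of
#' [rsn_labels()].
#'
#' @param significance_mask logical 3-D array.
#' @param templates named list of 14 templates covering every label in
#'   [rsn_labels()].
#' @param seed_id identifier recorded in the output.
#' @param mask_affine optional affine for cross-grid resampling.
#' @return data.frame of class `overlap_profile` with columns `seed`,
#'   `template`, `n_overlap`, `n_rsn`, `ratio` (14 rows, canonical order).
#' @export
overlap_profile <- function(significance_mask, templates, seed_id = "seed",
                            mask_affine = NULL) {
  labs <- rsn_labels()
  missing_labs <- setdiff(labs, names(templates))
  if (length(missing_labs))
    stop("missing template label(s): ", paste(missing_labs, collapse = ", "))
  rows <- lapply(labs, function(lb) {
    ov <- overlap_ratio(significance_mask, templates[[lb]], mask_affine)
    data.frame(seed = seed_id, template = lb, n_overlap = ov$n_overlap,
               n_rsn = ov$n_rsn, ratio = ov$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overlap_profile", "data.frame")
  out
}
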