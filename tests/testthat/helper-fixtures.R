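# Shared in-code fixtures for the test suite.

# A small, quick cohort used by several module tests.
small_spec <- function(...) {
  defaults <- list(n_subjects = 4L, grid_shape = c(16L, 16L, 16L),
                   n_timepoints = 60L, rng_seed = 101L)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# Bare BOLD series from an explicit T x V matrix laid out on a tiny grid;
# voxels fill the grid in linear (column-major) order.
series_from_matrix <- function(x, dim3 = NULL, affine = NULL, tr = 2.5) {
  v <- ncol(x)
  if (is.null(dim3)) {
    n <- ceiling(v^(1 / 3))
    dim3 <- c(n, n, max(1L, ceiling(v / n^2)))
    while (prod(dim3) < v) dim3[3] <- dim3[3] + 1L
  }
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  arr <- array(0, c(dim3, nrow(x)))
  flat <- matrix(0, prod(dim3), nrow(x))
  flat[seq_len(v), ] <- t(x)
  bold_series(array(flat, c(dim3, nrow(x))), affine, tr)
}

# Mask covering the first `v` voxels of a grid in linear order.
mask_first_voxels <- function(v, dim3, affine = diag(c(3, 3, 3, 1))) {
  m <- array(FALSE, dim3)
  m[seq_len(v)] <- TRUE
  gm_mask(m, affine)
}

# Naive all-pairs ICC oracle: explicit double loop over voxel pairs with
# stats::cor, independent of the chunked engine.
naive_icc <- function(series, mask, mode = "whole", d_thr_mm = 75,
                      denominator = "stratum") {
  x <- mask_series_matrix(series, mask)
  v <- ncol(x)
  ijk <- which(mask$mask, arr.ind = TRUE)
  world <- voxel_world_coords(ijk, mask$affine)
  sds <- apply(x, 2, stats::sd)
  vals <- numeric(v)
  cnts <- integer(v)
  for (i in seq_len(v)) {
    s <- 0
    cnt <- 0L
    for (j in seq_len(v)) {
      if (j == i) next
      d <- sqrt(sum((world[i, ] - world[j, ])^2))
      inc <- switch(mode, whole = TRUE, short = d <= d_thr_mm,
                    long = d > d_thr_mm)
      if (!inc) next
      r <- if (sds[i] == 0 || sds[j] == 0) 0 else stats::cor(x[, i], x[, j])
      s <- s + r^2
      cnt <- cnt + 1L
    }
    cnts[i] <- cnt
    vals[i] <- if (denominator == "global_n") s / v else if (cnt > 0) s / cnt else 0
  }
  list(values = vals, counts = cnts)
}

# Standardized icc_map wrapper around an arbitrary per-voxel value vector,
# for building group-level fixtures directly.
map_from_values <- function(values, mask) {
  structure(list(values = unmask(values, mask$mask), mask = mask$mask,
                 affine = mask$affine, mode = "whole", d_thr_mm = NA_real_,
                 denominator = "stratum", standardized = TRUE),
            class = "icc_map")
}
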