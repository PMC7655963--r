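#' Remove initial volumes from a BOLD series and its motion trace
#'
#' Discards the first `k` volumes (default 5, covering initial BOLD signal
#' instability) from both the series and the matching motion trace so they
#' stay aligned.
#'
#' @param series a [bold_series()].
#' @param trace a [motion_trace()] with one row per volume of `series`.
#' @param k number of initial volumes to drop.
#' @return List with elements `series` and `trace`, both shortened by `k`.
#' @export
trim_initial_volumes <- function(series, trace, k = 5L) {
  nt <- n_volumes(series)
  if (nrow(trace) != nt)
    stop("motion trace rows (", nrow(trace), ") must equal BOLD volumes (", nt, ")")
  if (k < 0L) stop("`k` must be >= 0")
  if (nt <= k) stop("series has ", nt, " volumes; cannot drop ", k)
  if (k == 0L) return(list(series = series, trace = trace))
  keep <- (k + 1L):nt
  out <- bold_series(series$data[, , , keep, drop = FALSE], series$affine,
                     series$tr)
  list(series = out, trace = motion_trace(trace[keep, , drop = FALSE]))
}

#' Build the 24-column motion confound matrix
#'
#' Expands a 6-parameter rigid-body trace `R_t` into the 24 motion regressors
#' `[R_t, R_t^2, R_{t-1}, R_{t-1}^2]`: the parameters, their element-wise
#' squares, the one-volume-lagged parameters, and the lagged squares. The lag
#' at the first volume is filled with 0.
#'
#' @param trace a [motion_trace()].
#' @return T x 24 numeric matrix with labelled columns.
#' @export
build_motion_confounds <- function(trace) {
  r <- unclass(trace)
  if (nrow(r) < 1L) stop("motion trace is empty")
  lag1 <- rbind(0, r[-nrow(r), , drop = FALSE])
  out <- cbind(r, r^2, lag1, lag1^2)
  colnames(out) <- c(colnames(trace),
                     paste0(colnames(trace), "_sq"),
                     paste0(colnames(trace), "_lag"),
                     paste0(colnames(trace), "_lag_sq"))
  out
}

#' Frame-wise displacement of a motion trace
#'
#' `FD_t = |dx| + |dy| + |dz| + radius * (|da| + |db| + |dg|)` with backward
#' differences and `FD_1 = 0`; rotations are converted to arc length on a
#' reference sphere (default radius 50 mm).
#'
#' @param trace a [motion_trace()].
#' @param rotation_radius_mm sphere radius for the rotation arc-length terms.
#' @return Numeric vector of per-volume FD (mm), same length as the trace.
#' @export
compute_fd <- function(trace, rotation_radius_mm = 50) {
  r <- unclass(trace)
  if (nrow(r) < 1L) stop("motion trace is empty")
  d <- abs(diff(r))
  if (nrow(r) == 1L) return(0)
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion-based subject screening
#'
#' Partitions subjects by mean frame-wise displacement: a subject is rejected
#' iff mean FD is strictly greater than the threshold (default 0.2 mm), so a
#' subject at exactly the threshold is kept.
#'
#' @param fd_list named list (or list) of per-subject FD vectors from
#'   [compute_fd()].
#' @param threshold_mm exclusion threshold (mm), > 0.
#' @return data.frame with columns `subject`, `mean_fd`, `kept`.
#' @export
screen_subjects <- function(fd_list, threshold_mm = 0.2) {
  if (threshold_mm <= 0) stop("`threshold_mm` must be > 0")
  ids <- names(fd_list)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(fd_list))
  mfd <- vapply(fd_list, mean, numeric(1))
  data.frame(subject = ids, mean_fd = unname(mfd),
             kept = unname(mfd <= threshold_mm), stringsAsFactors = FALSE)
}

#' Tissue and global nuisance signals
#'
#' Extracts per-volume mean signals from 4 mm spherical regions in the CSF
#' and WM, and over a global mask, plus the backward-difference derivative of
#' each (first element 0): six confound columns in total.
#'
#' @param series a [bold_series()].
#' @param csf_center,wm_center world-mm sphere centers.
#' @param sphere_radius_mm sphere radius (default 4 mm).
#' @param global_mask logical 3-D array defining the global signal support.
#' @return T x 6 matrix with columns `csf`, `wm`, `global` and their `_deriv`
#'   companions.
#' @export
extract_tissue_signals <- function(series, csf_center, wm_center,
                                   sphere_radius_mm = 4, global_mask) {
  d <- dim(series$data)[1:3]
  csf <- make_spherical_roi(csf_center, sphere_radius_mm, d, series$affine)
  wm <- make_spherical_roi(wm_center, sphere_radius_mm, d, series$affine)
  if (!is.logical(global_mask) || !all(dim(global_mask) == d))
    stop("`global_mask` must be a logical array matching the BOLD grid")
  sig <- function(mask) rowMeans(mask_series_matrix(series, mask))
  base <- cbind(csf = sig(csf), wm = sig(wm), global = sig(global_mask))
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0(colnames(base), "_deriv")
  cbind(base, deriv)
}

#' Regress nuisance confounds out of a BOLD series
#'
#' Per-voxel ordinary-least-squares residualization against the confound
#' matrix (an intercept is always added internally). Residuals are orthogonal
#' to every confound column. Rank-deficient confound matrices (e.g. an
#' all-zero motion trace) are reduced to a maximal independent column set
#' with a warning rather than erroring.
#'
#' @param series a [bold_series()].
#' @param confounds T x K numeric matrix, rows matching the series volumes.
#' @return Residual [bold_series()].
#' @export
regress_confounds <- function(series, confounds) {
  nt <- n_volumes(series)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nt)
    stop("confound rows (", nrow(confounds), ") must equal BOLD volumes (", nt, ")")
  x <- cbind(intercept = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning("dropping ", length(dropped), " linearly dependent confound column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  d <- dim(series$data)
  flat <- t(matrix(series$data, prod(d[1:3]), d[4]))   # T x V
  res <- qr.resid(qx, flat)
  bold_series(array(t(res), d), series$affine, series$tr)
}

# Butterworth band-pass coefficients for a series at rate 1/tr.
butter_bandpass <- function(low_hz, high_hz, tr, order = 4L) {
  nyq <- 1 / (2 * tr)
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < `low_hz` < `high_hz`")
  if (high_hz >= nyq)
    stop("`high_hz` (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

# One-pass IIR filter applied column-wise to a matrix; same semantics as
# signal::filter on each column (zero initial conditions). Compiled.
iir_filter_mat <- function(b, a, x) {
  .iir_filter_cols(as.numeric(b), as.numeric(a), x)
}

# Zero-phase (forward-backward) filtering of matrix columns, mirroring
# signal::filtfilt's zero-padding scheme so columns bit-match the vector
# implementation.
filtfilt_mat <- function(b, a, x) {
  npad <- 2L * max(length(a), length(b))
  y <- rbind(x, matrix(0, npad, ncol(x)))
  y <- iir_filter_mat(b, a, y)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- iir_filter_mat(b, a, y)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[seq_len(nrow(x)), , drop = FALSE]
}

#' Band-pass filter a BOLD series
#'
#' Zero-phase (forward-backward) order-4 Butterworth band-pass applied to
#' every voxel time series. Default passband 0.01-0.1 Hz. Zero-phase
#' application avoids shifting temporal correlations between voxels.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz passband edges; requires
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param order Butterworth order (per pass).
#' @return Filtered [bold_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1, order = 4L) {
  bf <- butter_bandpass(low_hz, high_hz, series$tr, order)
  minlen <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  if (n_volumes(series) <= minlen)
    stop("series too short (", n_volumes(series), " volumes) for the filter order")
  d <- dim(series$data)
  flat <- t(matrix(series$data, prod(d[1:3]), d[4]))
  out <- filtfilt_mat(bf$b, bf$a, flat)
  bold_series(array(t(out), d), series$affine, series$tr)
}

#' Run the denoising chain on one subject
#'
#' Applies the fixed stage order: initial-volume trim, confound regression
#' (24 motion terms plus optional tissue/global columns), then band-pass
#' filtering. Returns the denoised series together with the subject's mean
#' frame-wise displacement (computed on the trimmed trace).
#'
#' @param series a [bold_series()].
#' @param trace a [motion_trace()] aligned with the untrimmed series.
#' @param k_trim initial volumes to drop (default 5).
#' @param extra_confounds optional additional confound columns (rows matching
#'   the trimmed series), e.g. from [extract_tissue_signals()].
#' @param low_hz,high_hz band-pass edges.
#' @return List with `series` (denoised [bold_series()]), `mean_fd`, and the
#'   trimmed `trace`.
#' @export
preprocess_subject <- function(series, trace, k_trim = 5L,
                               extra_confounds = NULL,
                               low_hz = 0.01, high_hz = 0.1) {
  tr <- trim_initial_volumes(series, trace, k_trim)
  conf <- build_motion_confounds(tr$trace)
  if (!is.null(extra_confounds)) conf <- cbind(conf, extra_confounds)
  res <- regress_confounds(tr$series, conf)
  filt <- bandpass(res, low_hz, high_hz)
  list(series = filt, mean_fd = mean(compute_fd(tr$trace)), trace = tr$trace)
}
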