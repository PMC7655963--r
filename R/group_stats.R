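#' Build the group-level design matrix
#'
#' Assembles the regression design used for voxel-wise inference on ICC maps:
#' intercept, age (years), ACE-R total score, and the nuisance covariates sex
#' (binary) and mean frame-wise displacement (mm). One-sided contrasts are
#' exposed for both signs of the age and ACE-R effects.
#'
#' @param covariates data.frame with columns `age`, `acer_total`, `sex`.
#' @param mean_fd numeric vector of per-subject mean FD (mm).
#' @return List of class `icc_design` with `X` (N x 5 matrix) and `contrasts`
#'   (named list of contrast vectors: `age+`, `age-`, `acer+`, `acer-`).
#' @export
make_design <- function(covariates, mean_fd) {
  need <- c("age", "acer_total", "sex")
  if (!all(need %in% names(covariates)))
    stop("`covariates` must contain columns: ", paste(need, collapse = ", "))
  if (length(mean_fd) != nrow(covariates))
    stop("`mean_fd` length must match the covariate rows")
  x <- cbind(intercept = 1, age = covariates$age,
             acer_total = covariates$acer_total,
             sex = as.numeric(covariates$sex), mean_fd = mean_fd)
  contrasts <- list(
    "age+" = c(0, 1, 0, 0, 0), "age-" = c(0, -1, 0, 0, 0),
    "acer+" = c(0, 0, 1, 0, 0), "acer-" = c(0, 0, -1, 0, 0))
  contrasts <- lapply(contrasts, function(cc) { names(cc) <- colnames(x); cc })
  structure(list(X = x, contrasts = contrasts), class = "icc_design")
}

resolve_contrast <- function(design, contrast) {
  if (is.character(contrast)) {
    if (!contrast %in% names(design$contrasts))
      stop("unknown contrast `", contrast, "`; available: ",
           paste(names(design$contrasts), collapse = ", "))
    return(design$contrasts[[contrast]])
  }
  if (length(contrast) != ncol(design$X))
    stop("numeric contrast must have length ", ncol(design$X))
  as.numeric(contrast)
}

# Stack standardized map values over a shared mask: N x V matrix.
stack_maps <- function(maps) {
  if (length(maps) < 1L) stop("no maps supplied")
  m0 <- maps[[1]]$mask
  a0 <- maps[[1]]$affine
  rows <- lapply(maps, function(m) {
    if (!all(dim(m$mask) == dim(m0)) || !all(m$mask == m0))
      stop("all maps must share the same mask")
    if (max(abs(m$affine - a0)) > 1e-8)
      stop("all maps must share the same affine")
    m$values[m0]
  })
  list(y = do.call(rbind, rows), mask = m0, affine = a0)
}

#' Voxel-wise ordinary-least-squares group regression
#'
#' Fits the design at every mask voxel and returns the t statistic for the
#' requested contrast, with `dof = N - rank(design)`. Contrast vectors must
#' weight a single design column (one-sided signed contrasts such as `age-`
#' are the negation of their `+` counterpart).
#'
#' @param maps list of standardized `icc_map`s sharing mask and affine.
#' @param design an `icc_design` from [make_design()].
#' @param contrast contrast name (see [make_design()]) or numeric vector.
#' @param t_cap cap on `|t|` for numerically infinite statistics.
#' @return A `stat_map` (kind `t_regression`).
#' @export
fit_voxelwise_glm <- function(maps, design, contrast, t_cap = 1e6) {
  st <- stack_maps(maps)
  x <- design$X
  if (nrow(x) != nrow(st$y))
    stop("design rows (", nrow(x), ") must equal the number of maps (",
         nrow(st$y), ")")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cc <- resolve_contrast(design, contrast)
  dof <- nrow(x) - qx$rank
  beta <- qr.coef(qx, st$y)
  res <- qr.resid(qx, st$y)
  sigma2 <- colSums(res^2) / dof
  xtxi <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * drop(t(cc) %*% xtxi %*% cc))
  eff <- drop(crossprod(cc, beta))
  tt <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, sign(eff) * t_cap))
  tt <- pmin(pmax(tt, -t_cap), t_cap)
  structure(list(statistic = unmask(tt, st$mask), mask = st$mask,
                 affine = st$affine, dof = dof, kind = "t_regression",
                 contrast = if (is.character(contrast)) contrast else "custom",
                 beta = unmask(eff, st$mask)),
            class = "stat_map")
}

#' Voxel-wise one-sample t test
#'
#' Tests the across-subject mean of the maps against zero at every mask
#' voxel: `t = mean / (sd / sqrt(N))`, `dof = N - 1`. Voxels with zero
#' across-subject variance get statistic 0 and are flagged.
#'
#' @param maps list of standardized `icc_map`s (>= 3) sharing mask/affine.
#' @param t_cap cap on `|t|`.
#' @return A `stat_map` (kind `t_one_sample`) with a `zero_variance` flag
#'   array.
#' @export
one_sample_test <- function(maps, t_cap = 1e6) {
  if (length(maps) < 3L) stop("need at least 3 maps")
  st <- stack_maps(maps)
  n <- nrow(st$y)
  mu <- colMeans(st$y)
  sdv <- sqrt(colSums(sweep(st$y, 2L, mu, "-")^2) / (n - 1))
  zv <- sdv == 0
  tt <- numeric(length(mu))
  tt[!zv] <- mu[!zv] / (sdv[!zv] / sqrt(n))
  tt[zv & mu != 0] <- sign(mu[zv & mu != 0]) * t_cap
  tt <- pmin(pmax(tt, -t_cap), t_cap)
  structure(list(statistic = unmask(tt, st$mask), mask = st$mask,
                 affine = st$affine, dof = n - 1L, kind = "t_one_sample",
                 contrast = "mean>0", zero_variance = unmask(zv, st$mask, FALSE)),
            class = "stat_map")
}

#' Convert t statistics to z values
#'
#' Maps a Student-t statistic to the standard-normal deviate with the same
#' tail probability, computed on the log scale so extreme statistics do not
#' saturate.
#'
#' @param t numeric vector of t statistics.
#' @param dof degrees of freedom.
#' @return Numeric vector of z values.
#' @export
t_to_z <- function(t, dof) {
  sign(t) * (-stats::qnorm(stats::pt(-abs(t), dof, log.p = TRUE), log.p = TRUE))
}

# Internal engine shared by the permutation routines.
# Returns observed one-sided t vector and a function perm_t(i) drawing the
# i-th permuted t vector (vectorized over voxels).
perm_engine <- function(y, design = NULL, contrast = NULL, t_cap = 1e6) {
  n <- nrow(y)
  if (is.null(design)) {                       # one-sample, sign flipping
    ss <- colSums(y^2)
    tfun <- function(yrow_signs) {
      m <- colMeans(yrow_signs * y)
      v <- pmax(ss / (n - 1) - n * m^2 / (n - 1), 0)
      se <- sqrt(v / n)
      tt <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * t_cap))
      pmin(pmax(tt, -t_cap), t_cap)
    }
    list(observed = tfun(rep(1, n)), dof = n - 1L,
         draw = function() tfun(sample(c(-1, 1), n, replace = TRUE)))
  } else {                                     # regression, Freedman-Lane
    cc <- contrast
    j <- which(cc != 0)
    if (length(j) != 1L)
      stop("permutation inference requires a single-column contrast")
    sgn <- sign(cc[j])
    x <- design$X
    qz <- qr(x[, -j, drop = FALSE])
    xres <- qr.resid(qz, x[, j])               # contrast column residualized
    xn2 <- sum(xres^2)
    if (xn2 <= 0) stop("contrast column is collinear with the nuisance columns")
    e <- qr.resid(qz, y)                       # reduced-model residuals
    dof <- n - qr(x)$rank
    tfun <- function(perm) {
      ep <- qr.resid(qz, e[perm, , drop = FALSE])
      num <- drop(crossprod(xres, ep))
      ssr <- pmax(colSums(ep^2) - num^2 / xn2, 0)
      se <- sqrt(ssr / dof / xn2)
      tt <- ifelse(se > 0, sgn * num / xn2 / se,
                   ifelse(num == 0, 0, sgn * sign(num) * t_cap))
      pmin(pmax(tt, -t_cap), t_cap)
    }
    list(observed = tfun(seq_len(n)), dof = dof,
         draw = function() tfun(sample.int(n)))
  }
}

cluster_table_row <- function(stat, labels, lab, mask, affine, dof, p) {
  sel <- labels == lab & mask
  k <- sum(sel)
  peak_val <- max(stat[sel])
  peak_idx <- which(sel & stat == peak_val, arr.ind = TRUE)[1, , drop = FALSE]
  xyz <- voxel_world_coords(peak_idx, affine)
  data.frame(x = xyz[1], y = xyz[2], z = xyz[3], stat = peak_val,
             z_value = t_to_z(peak_val, dof), k = k, p_fwe = p, label = lab)
}

#' Permutation cluster-extent family-wise-error correction
#'
#' Thresholds the statistic map at the one-sided cluster-defining threshold
#' (the Student-t quantile at `cdt_p`), labels supra-threshold clusters
#' (default 26-connectivity), and compares each observed cluster extent
#' against the permutation null distribution of the maximum cluster extent:
#' sign flipping for one-sample designs, Freedman-Lane residual permutation
#' for regression designs. Corrected
#' `p = (1 + #(null max >= observed)) / (1 + n_perm)`; clusters with
#' `p < alpha` are reported.
#'
#' @param maps list of standardized `icc_map`s sharing mask/affine.
#' @param design optional `icc_design`; `NULL` means a one-sample test.
#' @param contrast contrast name or vector (regression designs only).
#' @param cdt_p cluster-defining threshold, one-sided, in (0, 0.05].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param alpha cluster-level significance level.
#' @return A `cluster_table` data.frame (columns `x`, `y`, `z`, `stat`,
#'   `z_value`, `k`, `p_fwe`, `label`), sorted by descending peak statistic,
#'   possibly empty. Attributes: `stat_map` (3-D t map), `all_clusters`
#'   (including non-significant ones), `cluster_labels` (supra-threshold
#'   cluster label array), `significance_mask` (voxels inside significant
#'   clusters), `null_max_k`, and `cdt_t`.
#' @export
permutation_cluster_correction <- function(maps, design = NULL, contrast = NULL,
                                           cdt_p = 0.001, n_perm = 1000L, seed,
                                           connectivity = 26L, alpha = 0.05) {
  if (missing(seed)) stop("`seed` is required for reproducible inference")
  if (cdt_p <= 0 || cdt_p > 0.05) stop("`cdt_p` must lie in (0, 0.05]")
  if (n_perm < 100L) stop("`n_perm` must be >= 100")
  st <- stack_maps(maps)
  cc <- if (is.null(design)) NULL else resolve_contrast(design, contrast)
  eng <- perm_engine(st$y, design, cc)
  tthr <- stats::qt(1 - cdt_p, eng$dof)

  obs_supra <- unmask(eng$observed > tthr, st$mask, FALSE)
  cl <- label_clusters(obs_supra, connectivity)

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    tb <- eng$draw()
    supra <- unmask(tb > tthr, st$mask, FALSE)
    null_max[b] <- if (any(supra)) max(label_clusters(supra, connectivity)$sizes) else 0
  }

  stat3d <- unmask(eng$observed, st$mask)
  rows <- lapply(seq_along(cl$sizes), function(lab) {
    p <- (1 + sum(null_max >= cl$sizes[lab])) / (1 + n_perm)
    cluster_table_row(stat3d, cl$labels, lab, st$mask, st$affine, eng$dof, p)
  })
  all_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               stat = numeric(0), z_value = numeric(0), k = integer(0),
               p_fwe = numeric(0), label = integer(0))
  all_tab <- all_tab[order(-all_tab$stat), , drop = FALSE]
  tab <- all_tab[all_tab$p_fwe < alpha, , drop = FALSE]
  rownames(tab) <- NULL
  sig_mask <- array(cl$labels %in% tab$label & cl$labels > 0, dim(cl$labels))
  structure(tab, class = c("cluster_table", "data.frame"),
            stat_map = stat3d, all_clusters = all_tab,
            cluster_labels = cl$labels, significance_mask = sig_mask,
            null_max_k = null_max, cdt_t = tthr)
}

#' Permutation voxel-level FWE threshold with a cluster-extent filter
#'
#' One-sample characterization analysis: voxels are declared significant when
#' their statistic reaches the `1 - p_fwe` quantile of the sign-flip null
#' distribution of the maximum statistic; surviving voxels are clustered and
#' clusters with extent strictly below `extent_min` (default 25 voxels) are
#' discarded, so a cluster of exactly `extent_min` voxels is kept.
#'
#' @param maps list of standardized `icc_map`s.
#' @param p_fwe voxel-level FWE rate.
#' @param extent_min minimum cluster extent kept (>= 1).
#' @param n_perm number of permutations.
#' @param seed RNG seed (mandatory).
#' @param connectivity cluster connectivity.
#' @return A `cluster_table` as in [permutation_cluster_correction()], with
#'   `p_fwe` the peak voxel's corrected p value. Attribute `threshold` holds
#'   the critical statistic.
#' @export
voxel_fwe_threshold <- function(maps, p_fwe = 0.05, extent_min = 25L,
                                n_perm = 1000L, seed, connectivity = 26L) {
  if (missing(seed)) stop("`seed` is required for reproducible inference")
  if (extent_min < 1L) stop("`extent_min` must be >= 1")
  st <- stack_maps(maps)
  eng <- perm_engine(st$y)
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) max(eng$draw()), numeric(1))
  crit <- sort(null_max)[ceiling((1 - p_fwe) * (n_perm + 1))]
  sig <- eng$observed >= crit
  sig3d <- unmask(sig, st$mask, FALSE)
  cl <- label_clusters(sig3d, connectivity)
  stat3d <- unmask(eng$observed, st$mask)
  keep <- which(cl$sizes >= extent_min)
  rows <- lapply(keep, function(lab) {
    peak <- max(stat3d[cl$labels == lab & st$mask])
    p <- (1 + sum(null_max >= peak)) / (1 + n_perm)
    cluster_table_row(stat3d, cl$labels, lab, st$mask, st$affine, eng$dof, p)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               stat = numeric(0), z_value = numeric(0), k = integer(0),
               p_fwe = numeric(0))
  tab <- tab[order(-tab$stat), , drop = FALSE]
  rownames(tab) <- NULL
  sig_kept <- sig3d
  if (length(cl$sizes)) {
    drop_labs <- which(cl$sizes < extent_min)
    if (length(drop_labs)) sig_kept[cl$labels %in% drop_labs] <- FALSE
  }
  structure(tab, class = c("cluster_table", "data.frame"),
            stat_map = stat3d, significance_mask = sig_kept,
            threshold = crit, null_max_t = null_max)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d significant cluster(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}
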