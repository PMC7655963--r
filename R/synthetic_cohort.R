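#' Specification of a synthetic resting-state cohort
#'
#' Collects every knob of the synthetic BOLD generator. Defaults describe a
#' desk-scale cohort: 40 subjects on a 16^3 grid of 6 mm voxels, 120 retained
#' volumes at TR 2.5 s (the generator emits `n_timepoints + 5` volumes so the
#' initial-volume trim of the preprocessing chain can be exercised), four
#' latent networks occupying compact blocks, connector-hub voxels on block
#' borders, and a hub-coupling slope over age.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param n_timepoints retained volumes after trimming; the generator emits
#'   `n_timepoints + 5`.
#' @param tr_seconds repetition time (s).
#' @param n_networks number of latent networks (compact blocks).
#' @param network_amplitude standard deviation of each latent network signal.
#' @param noise_sd standard deviation of the additive white voxel noise.
#' @param hub_voxel_fraction fraction of all grid voxels converted to
#'   connector hubs (loading on two networks); in (0, 1).
#' @param age_range numeric `[min, max]` subject age in years.
#' @param age_effect slope of the hub-voxel network loading per year of age
#'   (centered); negative plants an age-related hub-coupling decline.
#' @param acer_effect optional slope of the last network's voxel loadings per
#'   ACE-R point (centered); default 0 (cognition independent of the BOLD
#'   model).
#' @param motion_sd_mm per-volume random-walk step s.d. of the translation
#'   parameters (mm); rotations are scaled so their frame-wise-displacement
#'   contribution matches the translations.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects = 40L,
                        grid_shape = c(16L, 16L, 16L),
                        voxel_size_mm = 6,
                        n_timepoints = 120L,
                        tr_seconds = 2.5,
                        n_networks = 4L,
                        network_amplitude = 1,
                        noise_sd = 0.5,
                        hub_voxel_fraction = 0.0075,
                        age_range = c(21, 86),
                        age_effect = -0.02,
                        acer_effect = 0,
                        motion_sd_mm = 0.02,
                        rng_seed = 1L) {
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    n_networks = as.integer(n_networks),
    network_amplitude = network_amplitude,
    noise_sd = noise_sd,
    hub_voxel_fraction = hub_voxel_fraction,
    age_range = as.numeric(age_range),
    age_effect = age_effect,
    acer_effect = acer_effect,
    motion_sd_mm = motion_sd_mm,
    rng_seed = as.integer(rng_seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the generator invariants; errors name the offending field.
#'
#' @param spec a [cohort_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  fail <- function(field, why) stop(sprintf("invalid `%s`: %s", field, why),
                                    call. = FALSE)
  if (spec$n_subjects < 1L) fail("n_subjects", "must be >= 1")
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 1L))
    fail("grid_shape", "must be 3 positive voxel counts")
  nv <- prod(spec$grid_shape)
  if (nv < 27 || nv > 32768)
    fail("grid_shape", "total voxel count must be in [27, 32768]")
  if (spec$voxel_size_mm <= 0) fail("voxel_size_mm", "must be > 0")
  if (spec$n_timepoints < 32L)
    fail("n_timepoints", "must be >= 32 for a well-posed band-pass filter")
  if (spec$tr_seconds <= 0) fail("tr_seconds", "must be > 0")
  if (spec$n_networks < 1L) fail("n_networks", "must be >= 1")
  if (spec$network_amplitude <= 0) fail("network_amplitude", "must be > 0")
  if (spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (spec$hub_voxel_fraction <= 0 || spec$hub_voxel_fraction >= 1)
    fail("hub_voxel_fraction", "must lie in (0, 1)")
  if (spec$hub_voxel_fraction * nv < 1)
    fail("hub_voxel_fraction", "times the total voxel count must be >= 1")
  if (length(spec$age_range) != 2L || diff(spec$age_range) < 0)
    fail("age_range", "must be [min, max] with min <= max")
  if (spec$motion_sd_mm < 0) fail("motion_sd_mm", "must be >= 0")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d subjects, grid %s @ %g mm, %d+5 vols ",
                     "@ TR %g s, %d networks, noise %g, hubs %.1f%%\n"),
              x$n_subjects, paste(x$grid_shape, collapse = "x"),
              x$voxel_size_mm, x$n_timepoints, x$tr_seconds, x$n_networks,
              x$noise_sd, 100 * x$hub_voxel_fraction))
  invisible(x)
}

#' Canonical resting-state network labels
#'
#' The 14 template labels used by the overlap profile, in fixed order:
#' dorsal/ventral default mode, precuneus, left/right executive control,
#' anterior/posterior salience, language, visuospatial, basal ganglia,
#' high/primary visual, auditory, sensorimotor.
#'
#' @return Character vector of length 14.
#' @export
rsn_labels <- function() {
  c("dDMN", "vDMN", "Prec", "LECN", "RECN", "aSal", "pSal",
    "Lang", "Visu", "BG", "hVis", "pVis", "Aud", "SMN")
}

# Arrange K network blocks on a 3-D grid of blocks: smallest (kx, ky, kz)
# box with kx*ky*kz >= K, preferring near-cubic shapes.
block_layout <- function(k) {
  kx <- ceiling(k^(1 / 3))
  ky <- ceiling(sqrt(k / kx))
  kz <- ceiling(k / (kx * ky))
  c(kx, ky, kz)
}

# Split `n` voxels into `k` contiguous runs (as balanced as possible);
# returns a list of index vectors.
split_axis <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

# Lay out network territories: returns per-voxel network assignment
# (0 = background) as a 3-D integer array. Each network occupies the core of
# its block, with a background margin (>= 1 voxel per side) separating blocks.
layout_networks <- function(grid_shape, n_networks) {
  lay <- block_layout(n_networks)
  if (any(grid_shape %/% lay < 3L))
    stop("invalid `grid_shape`: too small to host ", n_networks,
         " network blocks with background margins", call. = FALSE)
  ax <- Map(split_axis, grid_shape, lay)
  assignment <- array(0L, grid_shape)
  b <- 0L
  for (kz in seq_len(lay[3])) for (ky in seq_len(lay[2])) for (kx in seq_len(lay[1])) {
    b <- b + 1L
    if (b > n_networks) break
    core <- function(ix) {
      m <- max(1L, floor(0.25 * length(ix)))
      ix[(m + 1L):(length(ix) - m)]
    }
    assignment[core(ax[[1]][[kx]]), core(ax[[2]][[ky]]), core(ax[[3]][[kz]])] <- b
  }
  assignment
}

#' Generate a synthetic resting-state cohort
#'
#' Builds a multi-subject BOLD cohort with known ground truth. Each subject's
#' voxel time series is `loading_matrix %*% latent_networks + white noise`,
#' where the latent network time-courses are moving-average smoothed Gaussian
#' series (spectrum concentrated below ~0.1 Hz at TR 2.5 s), sample-centered
#' and orthonormalized so the planted cross-network correlation is exactly
#' zero, and the loading matrix assigns every gray-matter voxel to one network,
#' except connector-hub voxels on block borders which load equally
#' (`1/sqrt(2)`) on two adjacent networks. Hub-voxel loadings are scaled by
#' `1 + age_effect * (age - mean(age))`, planting an age-modulated
#' hub-coupling effect. Background voxels carry pure noise.
#'
#' With `n_networks = 1` no connector hubs exist and the hub mask is empty.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `bold` (list of
#'   [bold_series()]), `motion` (list of [motion_trace()]), `gm_prob`
#'   (list with `map`, `affine`), `templates` (one binary template per
#'   network, named by [rsn_labels()]), `covariates` (data.frame with
#'   `subject_id`, `age`, `sex`, `acer_total`), `truth` (ground truth:
#'   `network_assignment`, `hub_mask`, `loading_matrix`, `subject_ages`,
#'   `subject_sex`, `true_acer`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$rng_seed)
  g <- spec$grid_shape
  nv <- prod(g)
  tfull <- spec$n_timepoints + 5L
  K <- spec$n_networks
  affine <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -(g - 1) / 2 * spec$voxel_size_mm

  assignment <- layout_networks(g, K)

  ## hub placement: for pair p = (b, b + 1 mod K), convert the core voxels of
  ## network b nearest to network (b+1)'s centroid into connector hubs
  hub_mask <- array(FALSE, g)
  hub_secondary <- integer(nv)            # 0 = not a hub
  if (K >= 2L) {
    n_hub <- max(1L, round(spec$hub_voxel_fraction * nv))
    per_pair <- rep(n_hub %/% K, K)
    if (n_hub %% K > 0) per_pair[seq_len(n_hub %% K)] <- per_pair[seq_len(n_hub %% K)] + 1L
    ijk_all <- which(assignment > 0, arr.ind = TRUE)
    world <- voxel_world_coords(ijk_all, affine)
    net_of <- assignment[assignment > 0]
    lin_all <- which(assignment > 0)
    for (b in seq_len(K)) {
      if (per_pair[b] == 0L) next
      to <- if (b == K) 1L else b + 1L
      cand <- which(net_of == b & hub_secondary[lin_all] == 0L)
      if (length(cand) < 2L * per_pair[b])
        stop("invalid `hub_voxel_fraction`: too many hubs for network ",
             b, "'s territory", call. = FALSE)
      target <- colMeans(world[net_of == to, , drop = FALSE])
      d2 <- colSums((t(world[cand, , drop = FALSE]) - target)^2)
      pick <- cand[order(d2)[seq_len(per_pair[b])]]
      hub_secondary[lin_all[pick]] <- to
      hub_mask[lin_all[pick]] <- TRUE
    }
  }

  ## base loading matrix (V x K)
  loading <- matrix(0, nv, K)
  in_gm <- which(assignment > 0)
  loading[cbind(in_gm, assignment[in_gm])] <- 1
  hubs <- which(hub_secondary > 0L)
  if (length(hubs)) {
    loading[cbind(hubs, assignment[hubs])] <- 1 / sqrt(2)
    loading[cbind(hubs, hub_secondary[hubs])] <- 1 / sqrt(2)
  }

  ## covariates
  ages <- round(runif(spec$n_subjects, spec$age_range[1], spec$age_range[2]), 1)
  sex <- rbinom(spec$n_subjects, 1L, 0.5)
  acer <- pmin(100, pmax(89, round(rnorm(spec$n_subjects, 96.5, 2.2))))

  ma_win <- max(1L, as.integer(round(7.5 / spec$tr_seconds)))

  age_c <- ages - mean(ages)
  acer_c <- acer - mean(acer)
  last_net <- which(assignment == K & !hub_mask)

  bold <- vector("list", spec$n_subjects)
  motion <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sm <- matrix(0, tfull, K)
    for (k in seq_len(K)) {
      w <- rnorm(tfull + ma_win)
      wk <- stats::filter(w, rep(1 / ma_win, ma_win), method = "convolution",
                          sides = 1)
      sm[, k] <- as.numeric(wk[(ma_win + 1L):(ma_win + tfull)])
    }
    ## center and orthonormalize so planted cross-network sample correlation
    ## is exactly zero (keeps the hub ground truth identifiable at finite T),
    ## then rescale to population s.d. = network_amplitude
    sm <- sweep(sm, 2L, colMeans(sm), "-")
    q <- qr.Q(qr(sm))
    q <- sweep(q, 2L, sign(colSums(q * sm)), "*")   # fix QR sign ambiguity
    lat <- t(q) * sqrt(tfull) * spec$network_amplitude
    ld <- loading
    if (length(hubs)) {
      scale_s <- max(0.05, 1 + spec$age_effect * age_c[s])
      ld[hubs, ] <- ld[hubs, , drop = FALSE] * scale_s
    }
    if (spec$acer_effect != 0 && length(last_net)) {
      ld[last_net, ] <- ld[last_net, , drop = FALSE] *
        max(0.05, 1 + spec$acer_effect * acer_c[s])
    }
    y <- ld %*% lat
    if (spec$noise_sd > 0)
      y <- y + matrix(rnorm(nv * tfull, sd = spec$noise_sd), nv, tfull)
    bold[[s]] <- bold_series(array(y, c(g, tfull)), affine, spec$tr_seconds)
    motion[[s]] <- generate_motion(spec)
  }

  gm_prob <- array(0.02, g)
  gm_prob[in_gm] <- 0.9

  labels <- if (K <= 14L) rsn_labels()[seq_len(K)] else sprintf("net%02d", seq_len(K))
  templates <- lapply(seq_len(K), function(k) {
    list(name = labels[k], mask = array(loading[, k] != 0, g), affine = affine)
  })
  names(templates) <- labels

  covariates <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(spec$n_subjects)),
    age = ages, sex = sex, acer_total = acer,
    stringsAsFactors = FALSE)

  truth <- list(network_assignment = assignment, hub_mask = hub_mask,
                loading_matrix = loading, subject_ages = ages,
                subject_sex = sex, true_acer = acer)

  structure(list(bold = bold, motion = motion,
                 gm_prob = list(map = gm_prob, affine = affine),
                 templates = templates, covariates = covariates,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d GM voxels (%d hubs), %d templates\n",
              length(x$bold), sum(x$truth$network_assignment > 0),
              sum(x$truth$hub_mask), length(x$templates)))
  invisible(x)
}

#' Generate a rigid-body motion trace
#'
#' Random-walk six-parameter trace with `n_timepoints + 5` rows. Translation
#' steps have s.d. `motion_sd_mm`; rotation steps have s.d.
#' `motion_sd_mm / 50` rad so that their contribution to frame-wise
#' displacement (50 mm reference sphere) matches the translations.
#' `motion_sd_mm = 0` yields an all-zero trace. Draws from the current RNG
#' stream; seed externally for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @return A [motion_trace()] with `spec$n_timepoints + 5` rows.
#' @export
generate_motion <- function(spec) {
  n <- spec$n_timepoints + 5L
  steps <- matrix(rnorm(6 * (n - 1L)), n - 1L, 6L)
  steps[, 1:3] <- steps[, 1:3] * spec$motion_sd_mm
  steps[, 4:6] <- steps[, 4:6] * spec$motion_sd_mm / 50
  motion_trace(rbind(0, apply(steps, 2L, cumsum)))
}
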