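test_that("gray-matter masking uses a strict threshold", {
  pm <- array(0, c(3, 3, 3))
  pm[1, 1, 1] <- 0.20
  pm[2, 1, 1] <- 0.21
  pm[3, 1, 1] <- 0.9
  gm <- make_gm_mask(pm, 0.2)
  expect_false(gm$mask[1, 1, 1])
  expect_true(gm$mask[2, 1, 1])
  expect_equal(sum(gm$mask), 2L)

  ones <- make_gm_mask(array(1, c(3, 3, 3)), 0.2)
  expect_equal(sum(ones$mask), 27L)

  set.seed(8)
  pm2 <- array(runif(1000), c(10, 10, 10))
  gm2 <- make_gm_mask(pm2, 0.2)
  expect_equal(sum(gm2$mask), sum(pm2 > 0.2))

  expect_error(make_gm_mask(array(0.1, c(3, 3, 3)), 0.2), "empty")
  expect_error(make_gm_mask(array(2, c(3, 3, 3)), 0.2), "\\[0, 1\\]")
})

test_that("distance stratification works in world mm with inclusive boundary", {
  # two voxels exactly 75 mm apart (3-4-5 triangle scaled): boundary -> short
  aff <- diag(c(45, 60, 1, 1))
  m <- array(FALSE, c(2, 2, 2))
  m[1, 1, 1] <- TRUE                         # world (0, 0, 0)
  m[2, 2, 1] <- TRUE                         # world (45, 60, 0)
  gm <- gm_mask(m, aff)
  set.seed(9)
  ser <- bold_series(array(rnorm(8 * 2 * 2 * 2), c(2, 2, 2, 8)), aff, 2.5)
  short <- compute_icc(ser, gm, "short", d_thr_mm = 75)
  long <- compute_icc(ser, gm, "long", d_thr_mm = 75)
  expect_equal(short$counts[m], c(1, 1))
  expect_equal(long$counts[m], c(0, 0))
  expect_equal(long$values[m], c(0, 0))

  # neighbours on a 3 mm isotropic grid are short-range at 75 mm
  aff3 <- diag(c(3, 3, 3, 1))
  m3 <- array(FALSE, c(2, 1, 1)); m3[, 1, 1] <- TRUE
  ser3 <- bold_series(array(rnorm(8 * 2), c(2, 1, 1, 8)), aff3, 2.5)
  s3 <- compute_icc(ser3, gm_mask(m3, aff3), "short", d_thr_mm = 75)
  expect_equal(s3$counts[m3], c(1, 1))

  # anisotropic affine: k-axis neighbours are 4 mm apart
  aff_a <- diag(c(2, 2, 4, 1))
  mk <- array(FALSE, c(1, 1, 2)); mk[1, 1, ] <- TRUE
  serk <- bold_series(array(rnorm(8 * 2), c(1, 1, 2, 8)), aff_a, 2.5)
  s_in <- compute_icc(serk, gm_mask(mk, aff_a), "short", d_thr_mm = 4)
  s_out <- compute_icc(serk, gm_mask(mk, aff_a), "short", d_thr_mm = 3.9)
  expect_equal(s_in$counts[mk], c(1, 1))     # boundary inclusive at 4 mm
  expect_equal(s_out$counts[mk], c(0, 0))
})

test_that("whole-brain ICC equals mean squared correlation", {
  # identical nonconstant series at 3 voxels: all r^2 = 1
  base <- sin(seq_len(10))
  x <- cbind(base, base, base)
  ser <- series_from_matrix(x, c(3, 1, 1))
  gm <- mask_first_voxels(3, c(3, 1, 1))
  m <- compute_icc(ser, gm, "whole")
  expect_equal(m$values[gm$mask], rep(1, 3))
  expect_equal(m$counts[gm$mask], rep(2, 3))

  # two-voxel mask: ICC(i) = r^2 for the single pair (8 timepoints)
  a <- rep(c(1, -1), 4)
  set.seed(10)
  b <- rnorm(8)
  r <- cor(a, b)
  ser2 <- series_from_matrix(cbind(a, b), c(2, 1, 1))
  m2 <- compute_icc(ser2, mask_first_voxels(2, c(2, 1, 1)), "whole")
  expect_equal(m2$values[1, 1, 1], r^2, tolerance = 1e-12)
  expect_equal(m2$values[2, 1, 1], r^2, tolerance = 1e-12)
})

test_that("chunked engine matches the naive all-pairs oracle", {
  set.seed(11)
  d3 <- c(6, 5, 4)
  aff <- diag(c(7, 9, 31, 1))                # awkward spacings
  nvox <- prod(d3)
  msk <- array(sample(c(TRUE, FALSE), nvox, TRUE, c(0.7, 0.3)), d3)
  gm <- gm_mask(msk, aff)
  ser <- bold_series(array(rnorm(nvox * 20), c(d3, 20)), aff, 2.5)
  for (mode in c("whole", "short", "long")) {
    got <- compute_icc(ser, gm, mode, d_thr_mm = 40, mem_mb = 0.01)
    ora <- naive_icc(ser, gm, mode, d_thr_mm = 40)
    expect_equal(got$values[msk], ora$values, tolerance = 1e-10)
    expect_equal(got$counts[msk], ora$counts)
  }
})

test_that("results are bit-identical for any chunk size", {
  coh <- generate_cohort(small_spec(n_subjects = 1L))
  gm <- make_gm_mask(coh$gm_prob)
  for (mode in c("whole", "short", "long")) {
    a <- compute_icc(coh$bold[[1]], gm, mode, mem_mb = 0.02)
    b <- compute_icc(coh$bold[[1]], gm, mode, mem_mb = 512)
    expect_identical(a$values, b$values)
    expect_identical(a$counts, b$counts)
  }
})

test_that("zero-variance voxels contribute zero correlations, flagged", {
  set.seed(12)
  x <- cbind(rnorm(12), rep(3, 12), rnorm(12))
  ser <- series_from_matrix(x, c(3, 1, 1))
  gm <- mask_first_voxels(3, c(3, 1, 1))
  expect_warning(m <- compute_icc(ser, gm, "whole"), "zero-variance")
  expect_true(m$zero_variance[2, 1, 1])
  expect_false(m$zero_variance[1, 1, 1])
  r13 <- cor(x[, 1], x[, 3])
  expect_equal(m$values[1, 1, 1], r13^2 / 2, tolerance = 1e-12)
  expect_equal(m$values[2, 1, 1], 0)
  expect_equal(m$counts[gm$mask], rep(2, 3))  # whole counts stay n - 1
})

test_that("the global-n denominator reproduces the literal 1/n reading", {
  set.seed(13)
  x <- matrix(rnorm(10 * 5), 10, 5)
  ser <- series_from_matrix(x, c(5, 1, 1))
  gm <- mask_first_voxels(5, c(5, 1, 1))
  a <- compute_icc(ser, gm, "whole", denominator = "stratum")
  b <- compute_icc(ser, gm, "whole", denominator = "global_n")
  expect_equal(b$values[gm$mask] * 5, a$values[gm$mask] * 4, tolerance = 1e-12)
})

test_that("standardization is an exact population z-score", {
  ser <- series_from_matrix(matrix(rnorm(40), 10, 4), c(4, 1, 1))
  gm <- mask_first_voxels(3, c(4, 1, 1))
  m <- compute_icc(ser, gm, "whole")
  m$values <- unmask(c(1, 2, 3), gm$mask)    # overwrite with the hand case
  z <- standardize_map(m)
  expect_equal(z$values[gm$mask], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z$values[gm$mask]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$values[gm$mask]^2)), 1, tolerance = 1e-12)

  # idempotent; rank order preserved
  z2 <- standardize_map(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  expect_equal(order(z$values[gm$mask]), order(m$values[gm$mask]))

  m$values <- unmask(rep(2, 3), gm$mask)
  expect_error(standardize_map(m), "constant")
})

test_that("count-weighted short and long sums decompose the whole sum", {
  set.seed(14)
  for (rep in 1:5) {
    d3 <- c(5, 5, 5)
    aff <- diag(c(sample(2:40, 3, TRUE), 1))
    msk <- array(runif(125) < 0.6, d3)
    if (sum(msk) < 3) next
    gm <- gm_mask(msk, aff)
    ser <- bold_series(array(rnorm(125 * 15), c(d3, 15)), aff, 2.5)
    dthr <- runif(1, 10, 120)
    w <- compute_icc(ser, gm, "whole")
    s <- compute_icc(ser, gm, "short", d_thr_mm = dthr)
    l <- compute_icc(ser, gm, "long", d_thr_mm = dthr)
    expect_identical(w$counts[msk], s$counts[msk] + l$counts[msk])
    expect_equal(w$values[msk] * w$counts[msk],
                 s$values[msk] * s$counts[msk] + l$values[msk] * l$counts[msk],
                 tolerance = 1e-12)
  }
})

test_that("relabelling voxels permutes ICC values with them", {
  set.seed(15)
  x <- matrix(rnorm(10 * 6), 10, 6)
  d3 <- c(6, 1, 1)
  gm <- mask_first_voxels(6, d3)
  m1 <- compute_icc(series_from_matrix(x, d3), gm, "whole")
  perm <- sample(6)
  m2 <- compute_icc(series_from_matrix(x[, perm], d3), gm, "whole")
  expect_equal(m2$values[gm$mask], m1$values[gm$mask][perm], tolerance = 1e-12)
})

test_that("raising global coupling cannot lower mean whole-brain ICC", {
  set.seed(16)
  x <- matrix(rnorm(30 * 20), 30, 20)
  d3 <- c(20, 1, 1)
  gm <- mask_first_voxels(20, d3)
  base <- compute_icc(series_from_matrix(x, d3), gm, "whole")
  shared <- rnorm(30)
  for (g in c(0.5, 1, 2, 4)) {
    coupled <- compute_icc(series_from_matrix(x + g * shared, d3), gm, "whole")
    expect_gte(mean(coupled$values[gm$mask]), mean(base$values[gm$mask]))
  }
})

test_that("noise-free hubs carry the highest whole-brain ICC exactly", {
  spec <- small_spec(n_subjects = 2L, noise_sd = 0)
  coh <- generate_cohort(spec)
  gm <- make_gm_mask(coh$gm_prob)
  hub <- coh$truth$hub_mask
  for (s in 1:2) {
    m <- compute_icc(coh$bold[[s]], gm, "whole")
    expect_gt(mean(m$values[hub]), mean(m$values[gm$mask & !hub]))
    top <- which(gm$mask)[order(m$values[gm$mask],
                                decreasing = TRUE)[seq_len(sum(hub))]]
    expect_setequal(top, which(hub))
  }
})
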