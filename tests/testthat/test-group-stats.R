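test_that("connected-component labelling respects the connectivity order", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE                         # corner neighbour of (1,1,1)
  m[4, 4, 4] <- TRUE
  l26 <- label_clusters(m, 26L)
  expect_equal(sort(l26$sizes, decreasing = TRUE), c(2L, 1L))
  expect_equal(l26$labels[1, 1, 1], l26$labels[2, 2, 2])
  l18 <- label_clusters(m, 18L)
  expect_equal(l18$sizes, c(1L, 1L, 1L))     # corner adjacency dropped
  me <- array(FALSE, c(3, 3, 3))
  me[1, 1, 1] <- TRUE; me[1, 2, 1] <- TRUE   # face neighbours
  expect_equal(label_clusters(me, 6L)$sizes, 2L)
  expect_equal(length(label_clusters(array(FALSE, c(3, 3, 3)))$sizes), 0L)
})

make_group_fixture <- function(n, v, d3 = c(5, 5, 2), seedval = 1) {
  set.seed(seedval)
  gm <- mask_first_voxels(v, d3)
  y <- matrix(rnorm(n * v), n, v)
  list(gm = gm, y = y,
       maps = lapply(seq_len(n), function(i) map_from_values(y[i, ], gm)))
}

test_that("voxel-wise regression matches a closed-form OLS oracle", {
  fx <- make_group_fixture(14, 20, seedval = 17)
  covs <- data.frame(age = runif(14, 20, 80), acer_total = rnorm(14, 96, 2),
                     sex = rbinom(14, 1, 0.5))
  fd <- runif(14, 0, 0.2)
  des <- make_design(covs, fd)
  sm <- fit_voxelwise_glm(fx$maps, des, "age+")
  expect_equal(sm$dof, 14L - 5L)

  x <- des$X
  xtxi <- solve(t(x) %*% x)
  for (j in c(1, 7, 20)) {
    yv <- fx$y[, j]
    beta <- xtxi %*% t(x) %*% yv
    resid <- yv - x %*% beta
    se <- sqrt(sum(resid^2) / (14 - 5) * xtxi[2, 2])
    expect_equal(sm$statistic[fx$gm$mask][j], drop(beta[2] / se),
                 tolerance = 1e-10)
  }

  # lm() agreement at one voxel
  fit <- lm(fx$y[, 3] ~ x - 1)
  expect_equal(sm$statistic[fx$gm$mask][3],
               unname(summary(fit)$coefficients[2, 3]), tolerance = 1e-8)
})

test_that("noiseless maps recover the planted slope with capped t", {
  gm <- mask_first_voxels(6, c(3, 2, 1))
  age <- c(25, 35, 45, 55, 65, 75, 30, 60)
  covs <- data.frame(age = age, acer_total = rnorm(8, 96, 1),
                     sex = rep(0:1, 4))
  des <- make_design(covs, runif(8, 0, 0.1))
  beta_true <- -0.02
  maps <- lapply(seq_len(8), function(i)
    map_from_values(rep(beta_true * age[i], 6), gm))
  sm <- fit_voxelwise_glm(maps, des, "age+")
  expect_true(all(sm$statistic[gm$mask] == -1e6))
  expect_equal(sm$beta[gm$mask], rep(beta_true, 6), tolerance = 1e-10)
})

test_that("age contrasts are antisymmetric and shift-invariant", {
  fx <- make_group_fixture(12, 15, seedval = 18)
  covs <- data.frame(age = runif(12, 20, 80), acer_total = rnorm(12, 96, 2),
                     sex = rbinom(12, 1, 0.5))
  des <- make_design(covs, runif(12, 0, 0.2))
  tp <- fit_voxelwise_glm(fx$maps, des, "age+")
  tn <- fit_voxelwise_glm(fx$maps, des, "age-")
  expect_equal(tn$statistic, -tp$statistic, tolerance = 1e-12)

  shifted <- lapply(fx$maps, function(m) {
    m$values <- m$values + 7; m })
  ts <- fit_voxelwise_glm(shifted, des, "age+")
  expect_equal(ts$statistic, tp$statistic, tolerance = 1e-8)
  o1 <- one_sample_test(fx$maps)
  o2 <- one_sample_test(shifted)
  expect_gt(max(abs(o2$statistic - o1$statistic)), 1)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  fx <- make_group_fixture(10, 5, seedval = 19)
  x <- cbind(intercept = 1, age = 1:10, acer_total = rnorm(10),
             sex = rep(0, 10), mean_fd = 2 * (1:10))  # fd collinear with age
  des <- structure(list(X = x, contrasts = list("age+" = c(0, 1, 0, 0, 0))),
                   class = "icc_design")
  expect_error(fit_voxelwise_glm(fx$maps, des, "age+"), "mean_fd")
})

test_that("one-sample t matches t.test and flags degenerate voxels", {
  gm <- mask_first_voxels(2, c(2, 1, 1))
  maps <- lapply(1:5, function(i) map_from_values(c(i, 1), gm))
  sm <- one_sample_test(maps)
  tt <- t.test(1:5)
  expect_equal(sm$statistic[1, 1, 1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(sm$statistic[1, 1, 1], 4.242640687, tolerance = 1e-8)
  expect_equal(sm$dof, 4L)
  # constant nonzero voxel: capped statistic, flagged
  expect_true(sm$zero_variance[2, 1, 1])
  expect_equal(sm$statistic[2, 1, 1], 1e6)

  # identical maps everywhere: capped where nonzero, zero-stat where zero
  maps_id <- lapply(1:4, function(i) map_from_values(c(2, 0), gm))
  smi <- one_sample_test(maps_id)
  expect_equal(smi$statistic[1, 1, 1], 1e6)
  expect_equal(smi$statistic[2, 1, 1], 0)
  expect_true(all(smi$zero_variance[gm$mask]))
})

test_that("under the null the one-sample t follows Student t(N-1)", {
  set.seed(20)
  n <- 10L
  v <- 4000L
  gm <- mask_first_voxels(v, c(20, 20, 10))
  y <- matrix(rnorm(n * v), n, v)
  maps <- lapply(seq_len(n), function(i) map_from_values(y[i, ], gm))
  sm <- one_sample_test(maps)
  ks <- ks.test(pt(sm$statistic[gm$mask], n - 1), "punif")
  expect_gt(ks$p.value, 0.01)
  # roughly 5% of voxels beyond the two-sided 0.05 quantile
  frac <- mean(abs(sm$statistic[gm$mask]) > qt(0.975, n - 1))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("permutation cluster correction recovers a planted block", {
  set.seed(21)
  d3 <- c(6, 6, 4)
  gm <- mask_first_voxels(prod(d3), d3)
  block <- array(FALSE, d3)
  block[2:3, 2:3, 2:3] <- TRUE               # 8-voxel effect block
  n <- 20L
  maps <- lapply(seq_len(n), function(i) {
    vals <- rnorm(prod(d3), sd = 1)
    vals[block[gm$mask]] <- vals[block[gm$mask]] + 1.5
    map_from_values(vals, gm)
  })
  tab <- permutation_cluster_correction(maps, cdt_p = 0.001, n_perm = 200,
                                        seed = 99)
  expect_gte(nrow(tab), 1L)
  # at the permutation floor up to rare near-identity sign patterns
  expect_lte(tab$p_fwe[1], 3 / 201)
  expect_gte(tab$k[1], 8L)
  lab <- attr(tab, "cluster_labels")
  expect_true(all(lab[block] > 0))

  # determinism under the same seed
  tab2 <- permutation_cluster_correction(maps, cdt_p = 0.001, n_perm = 200,
                                         seed = 99)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # corrected p nonincreasing in cluster size
  allc <- attr(tab, "all_clusters")
  if (nrow(allc) > 1) {
    byk <- allc[order(allc$k), ]
    expect_true(all(diff(byk$p_fwe) <= 1e-12))
  }
})

test_that("pure-noise maps usually yield an empty cluster table", {
  hits <- vapply(1:5, function(rep) {
    fx <- make_group_fixture(10, 50, d3 = c(5, 5, 2), seedval = 300 + rep)
    tab <- permutation_cluster_correction(fx$maps, cdt_p = 0.001,
                                          n_perm = 100, seed = 400 + rep)
    nrow(tab) > 0
  }, logical(1))
  expect_lte(sum(hits), 1L)
})

test_that("voxel-level FWE keeps clusters at the extent boundary", {
  set.seed(22)
  d3 <- c(6, 6, 4)
  gm <- mask_first_voxels(prod(d3), d3)
  block <- array(FALSE, d3)
  block[1:5, 1:5, 1] <- TRUE                 # 25-voxel block
  n <- 10L
  maps <- lapply(seq_len(n), function(i) {
    vals <- rnorm(prod(d3), sd = 0.5)
    vals[block[gm$mask]] <- vals[block[gm$mask]] + 8
    map_from_values(vals, gm)
  })
  tab25 <- voxel_fwe_threshold(maps, extent_min = 25L, n_perm = 200, seed = 5)
  expect_gte(nrow(tab25), 1L)
  k_obs <- max(tab25$k)
  # the same analysis with extent_min just above the observed size drops it
  tab_hi <- voxel_fwe_threshold(maps, extent_min = k_obs + 1L, n_perm = 200,
                                seed = 5)
  expect_true(nrow(tab_hi) == 0 || max(tab_hi$k) > k_obs)
  tab_eq <- voxel_fwe_threshold(maps, extent_min = k_obs, n_perm = 200,
                                seed = 5)
  expect_true(k_obs %in% tab_eq$k)           # boundary extent is kept
})

test_that("t-to-z conversion preserves tail probability and sign", {
  t <- c(-3, -0.5, 0, 1.2, 4)
  z <- t_to_z(t, 12)
  expect_equal(pnorm(z), pt(t, 12), tolerance = 1e-10)
  expect_equal(sign(z), sign(t))
  expect_true(is.finite(t_to_z(50, 30)))
})
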