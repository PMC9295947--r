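test_that("noise-free voxel decay is inverted exactly", {
  for (t2 in c(10, 25, 50, 100, 200)) {
    vf <- fit_t2star_voxel(100 * exp(-paper_te / t2), paper_te)
    expect_true(vf$valid)
    expect_equal(vf$t2star_ms, t2, tolerance = 1e-6)
    expect_equal(vf$s0, 100, tolerance = 1e-6)
    expect_lt(vf$rel_uncertainty, 1e-8)
  }
})

test_that("degenerate voxels are flagged invalid", {
  expect_false(fit_t2star_voxel(rep(50, 6), paper_te)$valid)   # zero decay
  expect_false(fit_t2star_voxel(c(10, 5, -1, -2, -3, -4), paper_te)$valid)
  expect_false(fit_t2star_voxel(c(10, 5, 0, 0, 0, 0), paper_te)$valid)
  expect_error(fit_t2star_voxel(c(1, 2, 3), paper_te), "equal length")
})

test_that("noisy voxel fit matches a brute-force grid search", {
  sig <- withr::with_seed(19, 100 * exp(-paper_te / 30) + rnorm(6, 0, 5))
  vf <- fit_t2star_voxel(sig, paper_te)
  # SSE minimization over a 0.01 ms lattice in T2* (S0 profiled per T2*,
  # itself optimal by linear least squares given the decay shape)
  t2_grid <- seq(20, 45, by = 0.01)
  sse <- vapply(t2_grid, function(t2) {
    decay <- exp(-paper_te / t2)
    s0 <- sum(sig * decay) / sum(decay^2)
    sum((sig - s0 * decay)^2)
  }, 0)
  t2_best <- t2_grid[which.min(sse)]
  expect_true(vf$valid)
  expect_lt(abs(vf$t2star_ms - t2_best), 0.01)
})

test_that("signal scaling leaves T2* unchanged and scales S0", {
  sig <- withr::with_seed(23, 100 * exp(-paper_te / 40) + rnorm(6, 0, 2))
  a <- fit_t2star_voxel(sig, paper_te)
  b <- fit_t2star_voxel(sig * 7, paper_te)
  expect_equal(b$t2star_ms, a$t2star_ms, tolerance = 1e-8)
  expect_equal(b$s0, 7 * a$s0, tolerance = 1e-8)
})

test_that("mapping excludes long-T2* voxels with a strict >= 250 ms rule", {
  # three voxels with exact decays at 40, 60 and 300 ms: 300 excluded
  mk <- function(t2s) {
    sig <- array(0, c(length(t2s), 1, 1, 6))
    for (i in seq_along(t2s)) sig[i, 1, 1, ] <- 100 * exp(-paper_te / t2s[i])
    list(signal = sig, echo_times_ms = paper_te)
  }
  mask <- array(TRUE, c(3, 1, 1))
  m <- map_t2star(mk(c(40, 60, 300)), mask)
  expect_equal(m$summary$median_t2star_ms, 50)
  expect_equal(m$summary$n_voxels_used, 2L)
  expect_equal(m$summary$n_voxels_excluded_over_threshold, 1L)
  # boundary: exactly 250 excluded, 249.99 retained
  m2 <- map_t2star(mk(c(250, 249.99)), array(TRUE, c(2, 1, 1)))
  expect_equal(m2$summary$n_voxels_used, 1L)
  expect_equal(m2$summary$n_voxels_excluded_over_threshold, 1L)
  expect_equal(m2$summary$median_t2star_ms, 249.99, tolerance = 1e-6)
})

test_that("mapping a seeded modulated phantom recovers the field median", {
  cfg <- phantom_config(grid_shape = c(28, 28, 8), semi_axes = c(9, 9, 3),
                        noise_sd = 1, seed = 6)
  ph <- simulate_multiecho_phantom(cfg)
  m <- map_t2star(ph, ph)
  truth_med <- median(ph$truth[ph$mask])
  expect_lt(abs(m$summary$median_t2star_ms - truth_med) / truth_med, 0.02)
  expect_error(map_t2star(ph, array(FALSE, dim(ph$mask))), "empty ROI")
})

test_that("amniotic phantom voxels are excluded by the 250 ms rule", {
  amn <- rbind(c(14, 14, 4), c(15, 14, 4), c(14, 15, 4))
  cfg <- phantom_config(grid_shape = c(28, 28, 8), semi_axes = c(9, 9, 3),
                        amniotic_voxels = amn, amniotic_t2star_ms = 300,
                        noise_sd = 0, seed = 1)
  ph <- simulate_multiecho_phantom(cfg)
  m <- map_t2star(ph, ph)
  expect_equal(m$summary$n_voxels_excluded_over_threshold, 3L)
  expect_true(all(m$map[amn] >= 250))
})

test_that("volume arithmetic, interpolation and the ellipsoid oracle agree", {
  # 1000 voxels at standard resolution
  m <- array(TRUE, c(10, 10, 10))
  expect_equal(placental_volume(m, paper_voxel_mm), 10.71875)
  # slice counts (10, missing, 20) -> missing counted as 15
  m2 <- array(FALSE, c(30, 30, 3))
  m2[1:10, 1, 1] <- TRUE
  m2[1:20, 1, 3] <- TRUE
  v <- placental_volume(list(mask = m2, missing_slices = 2L), c(1, 1, 1))
  expect_equal(v, (10 + 15 + 20) / 1000)
  # trailing missing slices copy their nearest present neighbor
  m3 <- array(FALSE, c(30, 30, 3))
  m3[1:10, 1, 1] <- TRUE
  v2 <- placental_volume(list(mask = m3, missing_slices = 2:3), c(1, 1, 1))
  expect_equal(v2, (10 + 10 + 10) / 1000)
  # ellipsoid mask within 5% of (4/3) pi abc x voxel volume
  cfg <- phantom_config(grid_shape = c(30, 30, 16), semi_axes = c(12, 12, 6))
  ph <- simulate_multiecho_phantom(cfg)
  expect_lt(abs(placental_volume(ph, ph$voxel_dims_mm) -
                  4 / 3 * pi * 12 * 12 * 6 * prod(ph$voxel_dims_mm) / 1000) /
              (4 / 3 * pi * 12 * 12 * 6 * prod(ph$voxel_dims_mm) / 1000),
            0.05)
  # no missing slices: volume is exactly count x voxel volume
  expect_equal(placental_volume(ph, ph$voxel_dims_mm),
               sum(ph$mask) * prod(ph$voxel_dims_mm) / 1000)
  expect_error(placental_volume(list(mask = array(FALSE, c(2, 2, 2)),
                                     missing_slices = 1:2),
                                c(1, 1, 1)), "all slices missing")
})

test_that("median summary is order-invariant and midpoint-averaged", {
  mk <- function(t2s) {
    sig <- array(0, c(length(t2s), 1, 1, 6))
    for (i in seq_along(t2s)) sig[i, 1, 1, ] <- 80 * exp(-paper_te / t2s[i])
    list(signal = sig, echo_times_ms = paper_te)
  }
  t2s <- c(30, 70, 45, 55)
  m <- map_t2star(mk(t2s), array(TRUE, c(4, 1, 1)))
  m_perm <- map_t2star(mk(rev(t2s)), array(TRUE, c(4, 1, 1)))
  expect_equal(m$summary$median_t2star_ms, 50, tolerance = 1e-6)
  expect_equal(m$summary$median_t2star_ms, m_perm$summary$median_t2star_ms,
               tolerance = 1e-9)
})
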