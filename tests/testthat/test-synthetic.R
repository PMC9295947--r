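test_that("cohort config validates probabilities, windows and SDs", {
  expect_error(cohort_config(group_probs = c(UN = 0.5, PA = 0.5, SA = 0.5)),
               "group_probs")
  expect_error(cohort_config(site_probs = c(A = 0.7, B = 0.2)), "site_probs")
  expect_error(cohort_config(ga_windows = list(c(10, 25), c(20, 30),
                                               c(30, 40))),
               "non-overlapping")
  models <- default_group_models()$t2star
  models$UN$sd <- -1
  expect_error(cohort_config(group_t2star_models = models), "nonnegative")
})

test_that("group proportions converge to the configured probabilities", {
  coh <- simulate_cohort(cohort_config(n_subjects = 100000, seed = 42))
  subj <- coh[!duplicated(coh$subject_id), ]
  p_hat <- prop.table(table(subj$group))
  # binomial check: each within 4 SEs of its target at n = 1e5
  for (g in c("UN", "PA", "SA")) {
    p0 <- c(UN = 0.626, PA = 0.222, SA = 0.152)[[g]]
    se <- sqrt(p0 * (1 - p0) / 1e5)
    expect_lt(abs(p_hat[[g]] - p0), 4 * se)
  }
  # empirical UN fraction within 0.5 percentage points of 62.6%
  expect_lt(abs(100 * p_hat[["UN"]] - 62.6), 0.5)
})

test_that("the noiseless generator places every scan on its group curve", {
  models <- default_group_models()
  for (nm in names(models)) {
    for (g in names(models[[nm]])) models[[nm]][[g]]$sd <- 0
  }
  cfg <- cohort_config(n_subjects = 80, seed = 11,
                       group_t2star_models = models$t2star,
                       ancillary_models = models[c("hb", "spo2",
                                                   "volume", "t1")])
  coh <- simulate_cohort(cfg)
  for (g in unique(coh$group)) {
    d <- coh[coh$group == g, ]
    expect_equal(d$t2star_ms,
                 evaluate_model("sigmoid", models$t2star[[g]]$params,
                                d$ga_weeks), tolerance = 1e-12)
    expect_equal(d$hb, models$hb[[g]]$params[1] +
                   models$hb[[g]]$params[2] * d$ga_weeks, tolerance = 1e-12)
  }
})

test_that("cohort generation is deterministic and prefix-stable in n", {
  a <- simulate_cohort(cohort_config(n_subjects = 40, seed = 5))
  b <- simulate_cohort(cohort_config(n_subjects = 40, seed = 5))
  expect_identical(a, b)
  big <- simulate_cohort(cohort_config(n_subjects = 70, seed = 5))
  expect_identical(a, big[seq_len(nrow(a)), ])
  # and it does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(simulate_cohort(cohort_config(n_subjects = 5)))
  expect_identical(rnorm(1), x1)
})

test_that("scans within a subject are strictly increasing in GA and in range", {
  coh <- simulate_cohort(cohort_config(n_subjects = 400, seed = 9))
  expect_true(all(coh$ga_weeks >= 10 & coh$ga_weeks <= 40))
  expect_true(all(coh$t2star_ms > 0))
  ok <- vapply(split(coh$ga_weeks, coh$subject_id),
               function(g) all(diff(g) > 0), TRUE)
  expect_true(all(ok))
})

test_that("T2* residuals against the true group curve are Gaussian", {
  cfg <- cohort_config(n_subjects = 4000,
                       group_probs = c(UN = 1, PA = 0, SA = 0), seed = 4)
  coh <- simulate_cohort(cfg)
  expect_gt(nrow(coh), 1e4 * 0.9)
  res <- coh$t2star_ms - evaluate_model("sigmoid", un_sigmoid, coh$ga_weeks)
  p <- suppressWarnings(ks.test(res, "pnorm", 0, un_resid_sd))$p.value
  expect_gt(p, 0.01)
})

test_that("phantom signal follows the closed-form decay and is seeded", {
  cfg <- phantom_config(grid_shape = c(16, 16, 6), semi_axes = c(5, 5, 2),
                        t2star_base_ms = 50, modulation_amplitude = 0,
                        noise_sd = 0, seed = 3)
  ph <- simulate_multiecho_phantom(cfg)
  idx <- which(ph$mask, arr.ind = TRUE)
  s1 <- ph$signal[cbind(idx, 1L)]  # TE 4.92
  s2 <- ph$signal[cbind(idx, 2L)]  # TE 9.84
  expect_equal(s2 / s1, rep(exp(-4.92 / 50), nrow(idx)), tolerance = 1e-12)
  ph2 <- simulate_multiecho_phantom(cfg)
  expect_identical(ph$signal, ph2$signal)
  # ellipsoid must fit inside the grid
  expect_error(phantom_config(grid_shape = c(16, 16, 6),
                              semi_axes = c(10, 5, 2)), "exceeds")
})

test_that("masked phantom volume matches the analytic ellipsoid at large axes", {
  cfg <- phantom_config(grid_shape = c(40, 40, 20), semi_axes = c(14, 11, 8))
  ph <- simulate_multiecho_phantom(cfg)
  vox <- sum(ph$mask)
  expect_lt(abs(vox - 4 / 3 * pi * 14 * 11 * 8) / (4 / 3 * pi * 14 * 11 * 8),
            0.05)
})

test_that("cohort CSV round-trips and rejects malformed files", {
  coh <- simulate_cohort(cohort_config(n_subjects = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$subject_id, coh$subject_id)
  for (col in c("ga_weeks", "t2star_ms", "hb", "spo2_pct", "volume_cm3",
                "t1_ms")) {
    expect_equal(back[[col]], coh[[col]], tolerance = 1e-9)
  }
  # empty collection -> header-only file
  empty <- coh[0, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(nrow(read_cohort(p2)), 0L)
  # missing required column
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(coh[, -4], p3, row.names = FALSE)
  expect_error(read_cohort(p3), "missing required column")
  # non-numeric cell reported with its line
  lines <- readLines(path)
  lines[3] <- sub(",([0-9.]+),", ",oops,", lines[3])
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, p4)
  expect_error(read_cohort(p4), "line 3")
})

test_that("phantom NIfTI round-trip preserves data and metadata", {
  cfg <- phantom_config(grid_shape = c(12, 12, 4), semi_axes = c(4, 4, 1),
                        noise_sd = 0.5, seed = 8)
  ph <- simulate_multiecho_phantom(cfg)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_phantom(dir)
  expect_lt(max(abs(back$signal - ph$signal)), 1e-6)
  expect_identical(back$mask, ph$mask)
  expect_equal(back$truth, ph$truth, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$echo_times_ms, ph$echo_times_ms)
  expect_equal(back$voxel_dims_mm, ph$voxel_dims_mm)
})
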