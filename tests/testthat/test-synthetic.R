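test_that("planted maps are quasi-uncorrelated, standardized, deterministic", {
  maps <- plant_spatial_maps(c(15, 15, 12), 5, seed = 3)
  flat <- matrix(maps, prod(c(15, 15, 12)), 5)
  g <- cor(flat); diag(g) <- 0
  expect_lt(max(abs(g)), 0.2)
  expect_equal(colMeans(flat), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(flat, 2, sd), rep(1, 5), tolerance = 1e-12)
  expect_identical(plant_spatial_maps(c(15, 15, 12), 2, seed = 7),
                   plant_spatial_maps(c(15, 15, 12), 2, seed = 7))
  expect_error(plant_spatial_maps(c(10, 15, 12), 3, seed = 1), "axis x")
})

test_that("event schedules honor the block structure and accuracy model", {
  spec <- cohort_spec(n_subjects = 1)
  # degenerate accuracies
  ev1 <- schedule_events(spec, 1.0, seed = 2)
  stim <- ev1[ev1$trial_type == "stim", ]
  expect_equal(nrow(stim), 32)                       # 8 odorants x 4 reps
  expect_true(all(stim$outcome == "hit"))
  expect_true(all(stim$duration == 16))
  ev0 <- schedule_events(spec, 0.0, seed = 2)
  expect_true(all(ev0$outcome[ev0$trial_type == "stim"] == "miss"))
  # baseline block after each set of eight
  expect_equal(sum(ev1$trial_type == "baseline"), 4)
  expect_true(all(diff(ev1$onset) > 0))
  # each odorant appears reps_per_run times
  expect_equal(as.integer(table(stim$odorant)), rep(4L, 8))
  # Bernoulli draws are replayable from the seed
  ev <- schedule_events(spec, 0.5, seed = 11)
  set.seed(11)
  u <- runif(32)
  expect_equal(sum(ev$outcome[ev$trial_type == "stim"] == "hit"),
               sum(u < 0.5))
  # insufficient run length is rejected with the required frame count
  expect_error(cohort_spec(n_frames = 100), "288")
})

test_that("simulated motion is bounded with plantable spikes", {
  m0 <- simulate_motion(100, 0, seed = 5)
  expect_lt(max(framewise_displacement(m0)), 1)
  m1 <- simulate_motion(100, 1, seed = 5)
  expect_gte(sum(framewise_displacement(m1) > 1), 1)
  expect_identical(simulate_motion(50, 0.1, seed = 9),
                   simulate_motion(50, 0.1, seed = 9))
  # spike count is binomial: over many seeds the mean rate approaches p
  counts <- vapply(1:30, function(s)
    length(attr(simulate_motion(200, 0.05, seed = s), "spikes")), 0L)
  expect_gt(mean(counts), 10 - 3 * sqrt(200 * 0.05 * 0.95 / 30))
  expect_lt(mean(counts), 10 + 3 * sqrt(200 * 0.05 * 0.95 / 30))
  # FD/DVARS flag exactly the planted spike frames at low thermal noise
  spec <- tiny_spec(thermal_sd = 0.05, drift_sd = 0, spike_prob = 0.05)
  coh <- generate_cohort(spec, seed = 21, n_components = 2)
  mo <- coh$motion[[1]][[1]]
  fd <- framewise_displacement(mo)
  expect_setequal(which(fd > 1),
                  sort(unique(c(attr(mo, "spikes"),
                                attr(mo, "spikes") + 1L))))
})

test_that("noiseless BOLD equals the planted mean field", {
  # all noise terms and amplitudes zero -> identically zero volume
  spec <- tiny_spec(thermal_sd = 0, drift_sd = 0, intrinsic_sd = 0)
  maps <- plant_spatial_maps(spec$grid, 2, seed = 1)
  gt <- list(planted_maps = maps,
             tmfc = list(seed_component = 1, target_voxels = integer(0)))
  ev <- schedule_events(spec, 0.7, seed = 3)
  b0 <- simulate_subject_bold(spec, gt, list(ev), matrix(0, 2, 2), 0, seed = 4)
  expect_equal(max(abs(b0[[1]]$data)), 0)

  # unit amplitude on one component: per-voxel regression on its time course
  # returns the planted map value (least-squares oracle)
  amp <- rbind(c(1, 0.5), c(0, 0))
  b1 <- simulate_subject_bold(spec, gt, list(ev), amp, 0, seed = 4)
  tc <- attr(b1[[1]], "timecourses")[, 1]
  y <- t(matrix(b1[[1]]$data, prod(spec$grid), spec$n_frames))
  beta <- naive_ols(cbind(1, tc), y)[2, ]
  expect_equal(unname(beta), as.vector(maps[, , , 1]), tolerance = 1e-8)

  # linearity: doubling the amplitude doubles the contribution
  b2 <- simulate_subject_bold(spec, gt, list(ev), 2 * amp, 0, seed = 4)
  expect_equal(b2[[1]]$data, 2 * b1[[1]]$data, tolerance = 1e-10)

  # grid mismatch is rejected
  bad_spec <- tiny_spec(grid = c(13, 12, 12), thermal_sd = 0)
  expect_error(simulate_subject_bold(bad_spec, gt, list(ev),
                                     matrix(0, 2, 2), 0, seed = 1), "grid")
})

test_that("cohorts are reproducible, with recorded seeds and draws", {
  spec <- tiny_spec(n_subjects = 3)
  c1 <- generate_cohort(spec, seed = 6, n_components = 2)
  c2 <- generate_cohort(spec, seed = 6, n_components = 2)
  expect_identical(c1$bold[[2]][[1]]$data, c2$bold[[2]][[1]]$data)
  expect_identical(c1$participants, c2$participants)
  expect_length(c1$ground_truth$seeds, 3)
  # carrier assignment replays from the base seed
  set.seed(6)
  u <- runif(3)
  expect_equal(c1$participants$apoe4, as.integer(u < spec$apoe_frac))
  # hit rate follows the logistic identification model
  expect_equal(c1$accuracy,
               plogis(0.35 * (c1$participants$sdoit - 4)))
})

test_that("on-disk cohorts are byte-reproducible and round-trip", {
  spec <- tiny_spec(n_subjects = 2, thermal_sd = 0.5)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(spec, seed = 4, dir = d1, n_components = 2)
  generate_cohort(spec, seed = 4, dir = d2, n_components = 2)
  f1 <- file.path(d1, "sub-01", "func", "sub-01_run-1_bold.nii.gz")
  f2 <- file.path(d2, "sub-01", "func", "sub-01_run-1_bold.nii.gz")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_length(gt$seeds, 2)          # one recorded seed per subject
  lc <- load_cohort(d1)
  expect_equal(nrow(lc$participants), 2)
  expect_equal(dim(lc$bold[[1]][[1]]$data), c(12, 12, 12, spec$n_frames))
  unlink(c(d1, d2), recursive = TRUE)
})
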