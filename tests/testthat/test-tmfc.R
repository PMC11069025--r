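make_ppi_fixture <- function(n = 100, seed = 19) {
  h <- canonical_hrf(10, 2)
  ev <- make_events(seq(0, 3 * 32, by = 32),
                    outcomes = c("hit", "miss", "hit", "miss"))
  task <- concat_run_designs(list(build_task_design(ev, 2, n, h)))
  set.seed(seed)
  seed_tc <- 0.8 * task$x[, "hit"] + 0.5 * task$x[, "miss"] + rnorm(n)
  list(h = h, ev = ev, task = task, seed_tc = seed_tc, n = n)
}

test_that("PPI designs center parents and form exact interaction products", {
  fx <- make_ppi_fixture()
  cf <- matrix(rnorm(fx$n * 3), fx$n, 3,
               dimnames = list(NULL, paste0("nuis", 1:3)))
  d <- build_ppi_design(fx$seed_tc, fx$task, cf)
  expect_equal(colnames(d$x)[1:6],
               c("intercept_run1", "hit", "miss", "seed", "hit_x_seed",
                 "miss_x_seed"))
  expect_equal(ncol(d$x), 1 + 2 + 1 + 2 + 3)   # bookkeeping
  # interactions equal elementwise products of the centered parents
  expect_equal(d$x[, "hit_x_seed"], d$x[, "hit"] * d$x[, "seed"],
               tolerance = 1e-12)
  expect_equal(mean(d$x[, "seed"]), 0, tolerance = 1e-12)
  # zero seed: seed and interaction columns dropped with a message
  expect_message(d0 <- build_ppi_design(rep(0, fx$n), fx$task, NULL),
                 "all-zero")
  expect_false(any(c("seed", "hit_x_seed") %in% colnames(d0$x)))
  # a seed exactly collinear with the task block is rejected by name
  expect_error(build_ppi_design(fx$task$x[, "hit"], fx$task, NULL),
               "collinear")
  expect_error(build_ppi_design(fx$seed_tc[-1], fx$task, NULL), "length")
})

test_that("voxelwise GLM is exact OLS and matches the per-voxel oracle", {
  fx <- make_ppi_fixture()
  d <- build_ppi_design(fx$seed_tc, fx$task, NULL)
  k <- ncol(d$x)
  set.seed(20)
  truth <- matrix(rnorm(k * 5), k, 5)
  y <- d$x %*% truth                      # exact linear combinations
  fit <- fit_voxelwise_glm(y, d)
  expect_lt(max(abs(fit$beta - truth)), 1e-10)
  expect_equal(fit$df, fx$n - k)
  # independent normal-equations oracle on a noisy 5-voxel image
  yn <- y + matrix(rnorm(fx$n * 5), fx$n, 5)
  fit2 <- fit_voxelwise_glm(yn, d)
  expect_equal(unname(fit2$beta), unname(naive_ols(d$x, yn)),
               tolerance = 1e-8)
  # permuting voxels permutes outputs identically
  perm <- c(3, 1, 5, 2, 4)
  fit3 <- fit_voxelwise_glm(yn[, perm], d)
  expect_equal(fit3$beta, fit2$beta[, perm], tolerance = 1e-12)
  # non-finite voxels are excluded with a warning
  yn[3, 2] <- NA
  expect_warning(fit4 <- fit_voxelwise_glm(yn, d), "non-finite")
  expect_equal(sum(fit4$mask), 4)
})

test_that("planted hit-specific coupling is recovered exactly at zero noise", {
  spec <- cohort_spec(n_subjects = 2, reps_per_run = 2, n_frames = 160,
                      thermal_sd = 0, drift_sd = 0, intrinsic_sd = 1)
  coh <- generate_cohort(spec, seed = 5, intrinsic_components = 1)
  gt <- coh$ground_truth
  seed_tc <- do.call(c, lapply(coh$timecourses[[1]], function(tc)
    tc[, gt$tmfc$seed_component]))
  tm <- tmfc_subject(coh$bold[[1]], coh$events[[1]], seed_tc)
  mask_idx <- which(as.vector(coh$bold[[1]][[1]]$mask))
  tpos <- match(gt$tmfc$target_voxels, mask_idx)
  expect_lt(max(abs(tm$hit[tpos] - gt$tmfc$gains[1])), 1e-6)
  expect_lt(max(abs(tm$hit[-tpos])), 1e-6)
  expect_lt(max(abs(tm$miss)), 1e-6)
})

test_that("interaction betas are invariant to nuisance signal and seed offset", {
  fx <- make_ppi_fixture()
  cf <- cbind(dct_highpass_basis(fx$n, 2, 0.01),
              nuis = rnorm(fx$n))
  d <- build_ppi_design(fx$seed_tc, fx$task, cf)
  set.seed(21)
  y <- matrix(rnorm(fx$n * 4), fx$n, 4)
  b0 <- fit_voxelwise_glm(y, d)$beta["hit_x_seed", ]
  # adding any combination of nuisance columns leaves interaction betas fixed
  y2 <- y + cf %*% matrix(rnorm(ncol(cf) * 4, 0, 3), ncol(cf), 4)
  b1 <- fit_voxelwise_glm(y2, d)$beta["hit_x_seed", ]
  expect_equal(b1, b0, tolerance = 1e-8)
  # adding a constant to the seed leaves the TMFC maps unchanged (centering)
  d2 <- build_ppi_design(fx$seed_tc + 42, fx$task, cf)
  b2 <- fit_voxelwise_glm(y, d2)$beta["hit_x_seed", ]
  expect_equal(b2, b0, tolerance = 1e-10)
})

test_that("missing conditions yield missing TMFC maps, not zeros", {
  h <- canonical_hrf(10, 2)
  n <- 100
  ev_hit <- make_events(seq(0, 3 * 32, by = 32), outcomes = "hit")
  task <- concat_run_designs(list(build_task_design(ev_hit, 2, n, h)))
  set.seed(22)
  seed_tc <- rnorm(n) + task$x[, "hit"]
  suppressMessages(d <- build_ppi_design(seed_tc, task, NULL))
  fit <- fit_voxelwise_glm(matrix(rnorm(n * 3), n, 3), d)
  tm <- extract_tmfc(fit)
  expect_null(tm$miss)
  expect_equal(tm$missing, "miss")
  expect_false(is.null(tm$hit))
  expect_true(all(is.finite(tm$hit)))
})
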