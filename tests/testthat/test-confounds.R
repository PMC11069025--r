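test_that("framewise displacement follows the Power formulation", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m[5:10, 1] <- 1  # single 1-mm x-translation jump at frame 5
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 1)
  expect_equal(fd[-5], rep(0, 9))
  m2 <- matrix(0, 10, 6); m2[5:10, 4] <- 0.02  # rotation jump, 50-mm sphere
  expect_equal(framewise_displacement(m2)[5], 1.0)
  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("DVARS is the masked RMS frame difference, median-standardized", {
  grid <- c(5, 5, 4)
  arr <- array(1, c(grid, 6))
  b <- bold4d(arr, diag(c(3, 3, 3, 1)), tr_s = 2)
  expect_equal(dvars(b)$raw, rep(0, 6))

  set.seed(3)
  arr <- array(rnorm(prod(grid) * 6), c(grid, 6))
  arr[, , , 4] <- arr[, , , 3] + 2.5  # uniform +k offset at one frame
  b2 <- bold4d(arr, diag(c(3, 3, 3, 1)), tr_s = 2)
  dv <- dvars(b2)
  expect_equal(dv$raw[4], 2.5, tolerance = 1e-12)
  expect_equal(median(dv$std[-1]), 1, tolerance = 1e-12)
  b3 <- b2; b3$mask <- array(FALSE, grid)
  expect_error(dvars(b3), "mask")
})

test_that("24-parameter expansion is [m, dm, m^2, dm^2]", {
  expect_true(all(motion_expansion(matrix(0, 8, 6)) == 0))
  set.seed(4)
  m <- matrix(rnorm(48), 8, 6)
  ex <- motion_expansion(m)
  expect_equal(ncol(ex), 24)
  expect_equal(unname(ex[, 13:18]), unname(m^2))
  expect_equal(unname(ex[1, 7:12]), rep(0, 6))        # leading zero on derivs
  expect_equal(unname(ex[2:8, 7:12]), unname(diff(m)))
})

test_that("aCompCor recovers a planted noise factor, orthogonal and ordered", {
  grid <- c(8, 8, 6); nt <- 60
  noise_mask <- array(FALSE, grid); noise_mask[1:2, , ] <- TRUE
  mask <- array(FALSE, grid); mask[4:8, , ] <- TRUE
  set.seed(5)
  tt <- seq_len(nt)
  sinus <- sin(2 * pi * tt / 12)
  arr <- array(rnorm(prod(grid) * nt, 0, 0.05), c(grid, nt))
  w <- runif(sum(noise_mask), 0.5, 2)
  nm_idx <- which(array(rep(noise_mask, nt), c(grid, nt)))
  flat <- matrix(arr, prod(grid), nt)
  flat[as.vector(noise_mask), ] <- flat[as.vector(noise_mask), ] +
    outer(w, sinus)
  b <- bold4d(array(flat, c(grid, nt)), diag(c(3, 3, 3, 1)), tr_s = 2,
              mask = mask)
  cc <- acompcor(b, noise_mask, 5)
  # compare against the detrended factor (detrending is part of the operator)
  sinus_dt <- residuals(lm(sinus ~ tt))
  expect_gt(abs(cor(cc[, 1], sinus_dt)), 0.99)
  expect_equal(unname(crossprod(cc)), diag(5), tolerance = 1e-8)
  # explained variance nonincreasing across components
  y <- t(flat[as.vector(noise_mask), ])
  y <- stats::lm.fit(cbind(1, tt), y)$residuals
  ev <- rowSums((t(cc) %*% y)^2)
  expect_true(all(diff(ev) <= 1e-8))
  # disjointness and size guards
  expect_error(acompcor(b, mask, 5), "disjoint")
  tiny <- array(FALSE, grid); tiny[1, 1, 1] <- TRUE
  expect_error(acompcor(b, tiny, 5), "at least")
})

test_that("spike regressors flag FD/DVARS exceedances once per frame", {
  expect_equal(ncol(spike_regressors(c(0, 0.2, 0), c(0, 1, 1))), 0)
  sp <- spike_regressors(c(0, 2, 0), c(0, 0, 3), 1, 2)
  expect_equal(dim(sp), c(3L, 2L))
  expect_equal(which(sp[, 1] == 1), 2L)
  expect_equal(which(sp[, 2] == 1), 3L)
  expect_true(all(colSums(sp) == 1))
  # a frame exceeding both thresholds yields a single column
  sp2 <- spike_regressors(c(0, 2, 0), c(0, 3, 0), 1, 2)
  expect_equal(ncol(sp2), 1)
  expect_error(spike_regressors(c(2, 2), c(0, 0)), "saturated")
  expect_error(spike_regressors(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("DCT high-pass basis has the right size and removes slow drift", {
  basis <- dct_highpass_basis(300, 2, 0.01)
  expect_equal(ncol(basis), 12)  # floor(2 * 300 * 2 * 0.01)
  expect_equal(unname(crossprod(basis)), diag(12), tolerance = 1e-10)
  tt <- seq_len(300)
  slow <- sin(2 * pi * 0.005 * tt * 2)  # 0.005 Hz at TR 2
  x <- cbind(1, basis)
  resid <- slow - x %*% solve(crossprod(x), crossprod(x, slow))
  expect_lt(sum(resid^2) / sum((slow - mean(slow))^2), 0.01)
  expect_error(dct_highpass_basis(20, 2, 0.3), "too high")
})

test_that("assembled confound matrix has fMRIPrep-style structure", {
  spec <- tiny_spec(thermal_sd = 0.3, spike_prob = 0)
  coh <- generate_cohort(spec, seed = 8, n_components = 2)
  b <- coh$bold[[1]][[1]]
  nm <- attr(b, "noise_mask")
  motion <- coh$motion[[1]][[1]]
  motion[30, 1] <- motion[30, 1] + 2  # force one spike
  cm <- build_confound_matrix(motion[, 1:6], b, nm)
  expect_s3_class(cm, "confound_matrix")
  expect_true(all(c("trans_x", "a_comp_cor_00", "cosine_00") %in%
                    colnames(cm$x)))
  n_out <- sum(grepl("motion_outlier", colnames(cm$x)))
  expect_gte(n_out, 2)  # the forced jump flags the frame and its successor
  expect_equal(length(cm$fd), dim(b$data)[4])
  p <- tempfile(fileext = ".tsv")
  save_confound_matrix(cm, p)
  expect_true("framewise_displacement" %in% names(read.delim(p)))
})
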