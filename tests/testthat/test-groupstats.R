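make_participants <- function(n, seed = 23) {
  set.seed(seed)
  data.frame(subject = sprintf("sub-%02d", seq_len(n)),
             apoe4 = rbinom(n, 1, 16 / 36),
             sdoit = rbinom(n, 8, 0.55),
             familiarity = pmin(pmax(rnorm(n, 4.75, 1.9), 1), 10),
             age = rnorm(n, 76.6, 4.2),
             sex = rbinom(n, 1, 0.5))
}

test_that("the group design centers continuous predictors before products", {
  pp <- make_participants(34)
  des <- group_design(pp)
  expect_equal(colnames(des$x),
               c("intercept", "apoe", "sdoit", "fam", "sex", "age",
                 "apoe_x_sdoit", "apoe_x_fam", "sdoit_x_fam",
                 "apoe_x_sdoit_x_fam"))
  expect_equal(mean(des$x[, "sdoit"]), 0, tolerance = 1e-12)
  expect_equal(mean(des$x[, "fam"]), 0, tolerance = 1e-12)
  expect_setequal(unique(des$x[, "apoe"]), c(0, 1))  # binary not centered
  expect_equal(des$x[, "apoe_x_sdoit_x_fam"],
               des$x[, "apoe"] * des$x[, "sdoit"] * des$x[, "fam"],
               tolerance = 1e-12)
  # missing covariates are dropped with a message
  pp2 <- pp; pp2$sdoit[3] <- NA
  expect_message(des2 <- group_design(pp2), "removed")
  expect_equal(nrow(des2$x), 33)
  # aliasing is reported by column name
  pp3 <- pp; pp3$familiarity <- pp3$sdoit * 2
  expect_error(group_design(pp3), "aliased")
})

test_that("group regression is exact OLS matching the textbook oracle", {
  pp <- make_participants(34)
  des <- group_design(pp)
  beta_true <- c(0.1, -0.25, 0.05, 0.05, 0.02, 0.001, -0.1, 0.1, 0.02, 0.078)
  y <- as.numeric(des$x %*% beta_true)
  fit <- fit_group_regression(y, des)
  expect_lt(max(abs(fit$coef[, 1] - beta_true)), 1e-10)
  # oracle equivalence with noise, including SEs, t and p
  set.seed(24)
  yn <- y + rnorm(34, 0, 0.3)
  fit2 <- fit_group_regression(yn, des)
  lmfit <- lm(yn ~ des$x - 1)
  sm <- summary(lmfit)$coefficients
  expect_equal(unname(fit2$coef[, 1]), unname(sm[, 1]), tolerance = 1e-8)
  expect_equal(unname(fit2$se[, 1]), unname(sm[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit2$p[, 1]), unname(sm[, 4]), tolerance = 1e-8)
  expect_equal(fit2$df, 24)
  # subjects with missing outcome are dropped with a message
  yn[5] <- NA
  expect_message(fit3 <- fit_group_regression(yn, des), "missing outcome")
  expect_equal(fit3$n, 33)
  des11 <- group_design(make_participants(11, seed = 40))
  y11 <- rnorm(11); y11[2] <- NA
  expect_error(suppressMessages(fit_group_regression(y11, des11)),
               "more subjects")
})

test_that("the highest-order coefficient is centering invariant", {
  pp <- make_participants(34, seed = 25)
  set.seed(25)
  y <- rnorm(34)
  f_c <- fit_group_regression(y, group_design(pp, center = TRUE))
  f_u <- fit_group_regression(y, group_design(pp, center = FALSE))
  expect_equal(f_c$coef["apoe_x_sdoit_x_fam", 1],
               f_u$coef["apoe_x_sdoit_x_fam", 1], tolerance = 1e-10)
})

test_that("one-sample t maps match the per-voxel textbook formula", {
  set.seed(26)
  n <- 8; grid <- c(6, 6, 4); V <- prod(grid)
  maps <- matrix(rnorm(n * V), n, V) + rep(c(0, 3), each = V / 2)[1:V]
  sm <- one_sample_tmap(maps, grid, p_voxel = 0.001, k_min = 1)
  t_oracle <- apply(maps, 2, function(v) mean(v) / (sd(v) / sqrt(n)))
  expect_equal(as.vector(sm$stat), t_oracle, tolerance = 1e-10)
  # sign-flipped pairs give t = 0 everywhere
  half <- matrix(rnorm(4 * V), 4, V)
  sym <- rbind(half, -half)
  sm0 <- one_sample_tmap(sym, grid, p_voxel = 0.001, k_min = 1)
  expect_equal(max(abs(sm0$stat)), 0, tolerance = 1e-10)
  expect_equal(nrow(sm0$clusters), 0)
  expect_error(one_sample_tmap(maps[1:2, ], grid), "3 subjects")
})

test_that("cluster-extent thresholding matches a flood-fill oracle", {
  grid <- c(12, 12, 12)
  # a cubic blob of 80 supra-threshold voxels
  stat <- array(0, grid); stat[3:6, 3:7, 3:6] <- 5    # 4*5*4 = 80
  p <- array(1, grid); p[stat > 0] <- 1e-5
  sm <- cluster_threshold(as.vector(stat), as.vector(p), grid,
                          p_voxel = 0.001, k_min = 75)
  expect_equal(nrow(sm$clusters), 1)
  expect_equal(sm$clusters$size, 80)
  sm2 <- cluster_threshold(as.vector(stat), as.vector(p), grid,
                           p_voxel = 0.001, k_min = 100)
  expect_equal(nrow(sm2$clusters), 0)
  expect_error(cluster_threshold(as.vector(stat), as.vector(p), grid,
                                 connectivity = 10), "connectivity")
  # random maps: labels equal the independent flood-fill oracle
  set.seed(27)
  for (conn in c(6, 18, 26)) {
    stat <- array(rnorm(prod(grid)), grid)
    p <- array(runif(prod(grid)), grid)
    sm3 <- cluster_threshold(as.vector(stat), as.vector(p), grid,
                             p_voxel = 0.2, k_min = 1, connectivity = conn)
    for (dir_sign in c(1, -1)) {
      supra <- p < 0.2 & sign(stat) == dir_sign
      oracle <- flood_fill_oracle(supra, conn)
      ours <- array(0L, grid)
      sel <- sm3$labels > 0 & sign(sm3$stat) == dir_sign
      ours[sel] <- sm3$labels[sel]
      expect_true(same_partition(ours, oracle))
    }
  }
})

test_that("marginal means display interaction geometry correctly", {
  pp <- make_participants(34, seed = 28)
  des <- group_design(pp)
  # no interactions: the four lines are parallel in the identification score
  b_flat <- c(0.5, -0.2, 0.1, 0.05, 0, 0, 0, 0, 0, 0)
  fit <- fit_group_regression(as.numeric(des$x %*% b_flat), des)
  mm <- marginal_means(fit, sdoit_values = 0:8)
  slopes <- sapply(split(mm, interaction(mm$apoe, mm$familiarity_group)),
                   function(d) unname(coef(lm(predicted ~ sdoit, d))[2]))
  expect_equal(unname(slopes), rep(0.1, 4), tolerance = 1e-10)
  # a planted ApoE x SDOIT slope offsets carrier lines by the coefficient
  b_int <- b_flat; b_int[7] <- -0.15
  fit2 <- fit_group_regression(as.numeric(des$x %*% b_int), des)
  mm2 <- marginal_means(fit2, sdoit_values = 0:8)
  sl <- sapply(split(mm2, interaction(mm2$apoe, mm2$familiarity_group)),
               function(d) unname(coef(lm(predicted ~ sdoit, d))[2]))
  expect_equal(unname(sl[c("1.low", "1.high")] - sl[c("0.low", "0.high")]),
               c(-0.15, -0.15), tolerance = 1e-10)
  # predictions at observed covariates equal fitted values
  yhat <- as.numeric(des$x %*% fit2$coef[, 1])
  expect_equal(as.numeric(des$x %*% fit2$coef[, 1]),
               unname(fitted(lm(as.numeric(des$x %*% b_int) ~ des$x - 1))),
               tolerance = 1e-8)
  # the extrapolation flag marks scores outside the observed hull
  mm3 <- marginal_means(fit2, sdoit_values = c(-5, 4, 20))
  expect_true(all(mm3$extrapolated[mm3$sdoit %in% c(-5, 20)]))
})
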