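test_that("REML fit agrees with lme4 on unbalanced longitudinal data", {
  skip_if_not_installed("lme4")
  for (seed in c(2, 9, 23)) {
    d <- make_lmm_data(seed)
    d <- d[-sample(nrow(d), 4), ]  # unbalanced: drop a few occasions
    fit <- fit_eq1(d, include_quadratic = TRUE)
    xm <- mean(d$x)
    m <- suppressWarnings(  # lme4 warns about raw-days predictor scaling
      lme4::lmer(y ~ I(x - xm) + I((x - xm)^2) + (1 | subject),
                 data = d, REML = TRUE))
    expect_equal(unname(fit$coefficients),
                 unname(lme4::fixef(m)), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(fit$sigma_b2, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-5)
    expect_equal(unname(fit$se),
                 unname(coef(summary(m))[, "Std. Error"]), tolerance = 1e-5)
  }
})

test_that("REML criterion argmax matches a brute-force grid oracle", {
  d <- make_lmm_data(4, n_subj = 5, days = c(0, 10, 20))
  fit <- fit_eq1(d, include_quadratic = FALSE)
  xm <- mean(d$x)
  X <- cbind(1, d$x - xm)
  grid_b <- seq(0.01, 1, length.out = 60)
  grid_e <- seq(0.005, 0.5, length.out = 60)
  ll <- outer(grid_b, grid_e, Vectorize(function(sb2, se2)
    bf_reml_loglik(X, d$y, d$subject, sb2, se2)))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(fit$sigma_b2, grid_b[best[1]],
               tolerance = 2 * diff(grid_b)[1] / grid_b[best[1]])
  expect_equal(fit$sigma_e2, grid_e[best[2]],
               tolerance = 2 * diff(grid_e)[1] / grid_e[best[2]])
  # the profiled criterion at the REML solution beats every grid point
  expect_gte(fit$reml_loglik + 1e-6, max(ll))
})

test_that("boundary and degenerate designs reduce exactly to OLS", {
  set.seed(5)
  d1 <- data.frame(subject = 1:12, x = 1:12, y = rnorm(12))
  fit <- fit_eq1(d1, include_quadratic = TRUE)
  xm <- mean(d1$x)
  ols <- lm(y ~ I(x - xm) + I((x - xm)^2), data = d1)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$sigma_b2, 0)
  expect_true(fit$boundary)
  expect_equal(unname(fit$se),
               unname(coef(summary(ols))[, "Std. Error"]), tolerance = 1e-8)
  expect_error(fit_eq1(d1[1:3, ]), "fewer observations")
  d1$y[1] <- Inf
  expect_error(fit_eq1(d1), "non-finite")
  expect_error(fit_eq1(data.frame(subject = 1, x = 1:5, y = rnorm(5))),
               "2 subjects")
})

test_that("fit is invariant to subject relabeling and row order", {
  d <- make_lmm_data(8)
  fit <- fit_eq1(d)
  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  d2$subject <- paste0("s", 9 - d2$subject)  # relabel
  fit2 <- fit_eq1(d2)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, fit2$sigma_b2, tolerance = 1e-5)
  expect_equal(fit$reml_loglik, fit2$reml_loglik, tolerance = 1e-8)
})

test_that("balanced-design REML matches the ANOVA moment estimator", {
  d <- make_lmm_data(12, n_subj = 10, days = c(0, 1, 2, 3),
                     sigma_b = 0.7, sigma_e = 0.3)
  fit <- fit_eq1(d, include_quadratic = FALSE)
  # method of moments on residuals of the fixed-effect fit
  a <- stats::aov(y ~ x + Error(factor(subject)), data = d)
  ms <- summary(a)
  ms_between <- ms[["Error: factor(subject)"]][[1]]["Residuals", "Mean Sq"]
  ms_within <- ms[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  k <- 4
  mom_b2 <- (ms_between - ms_within) / k
  skip_if_not(mom_b2 > 0)
  expect_equal(fit$sigma_b2, mom_b2, tolerance = 0.05)
  expect_equal(fit$sigma_e2, ms_within, tolerance = 0.05)
})

test_that("centring the predictor re-parameterises without changing the test", {
  d <- make_lmm_data(15)
  f_c <- fit_eq1(d, include_quadratic = FALSE, center_predictor = TRUE)
  f_u <- fit_eq1(d, include_quadratic = FALSE, center_predictor = FALSE)
  expect_equal(f_c$t[["x"]], f_u$t[["x"]], tolerance = 1e-8)
  expect_equal(f_c$coefficients[["x"]], f_u$coefficients[["x"]], tolerance = 1e-8)
  # with the quadratic: the top coefficient and fit are unchanged,
  # the linear term re-expands as beta1_u = beta1_c - 2 beta2 xbar
  f_cq <- fit_eq1(d, include_quadratic = TRUE, center_predictor = TRUE)
  f_uq <- fit_eq1(d, include_quadratic = TRUE, center_predictor = FALSE)
  expect_equal(f_cq$t[["x2"]], f_uq$t[["x2"]], tolerance = 1e-6)
  xm <- mean(d$x)
  expect_equal(f_uq$coefficients[["x"]],
               f_cq$coefficients[["x"]] - 2 * f_cq$coefficients[["x2"]] * xm,
               tolerance = 1e-6)
})

test_that("voxel-wise fitting maps constants to null results and drops missing", {
  dims <- c(3, 3, 1)
  mask <- array(TRUE, dims)
  obs <- data.frame(subject = rep(1:4, each = 3), x = rep(c(0, 50, 100), 4))
  maps <- lapply(seq_len(nrow(obs)), function(i) array(1, dims))
  vf <- voxelwise_fit(maps, obs, mask, include_quadratic = FALSE)
  expect_true(all(vf$beta1 == 0))
  expect_true(all(vf$p_beta1 == 1))
  # missing maps dropped with a message
  maps2 <- lapply(seq_len(nrow(obs)), function(i) {
    if (i == 2) NULL else array(rnorm(prod(dims)), dims)
  })
  expect_message(vf2 <- voxelwise_fit(maps2, obs, mask,
                                      include_quadratic = FALSE),
                 "dropping 1")
  expect_equal(vf2$n_obs, nrow(obs) - 1L)
})

test_that("voxel-wise fit recovers an injected positive slope", {
  set.seed(77)
  dims <- c(4, 4, 1)
  mask <- array(TRUE, dims)
  days <- c(3, 13, 31, 98, 370)
  obs <- expand.grid(subject = 1:8, j = 1:5)
  obs$x <- days[obs$j]
  slope_vox <- 1:8  # half the voxels carry the effect
  maps <- lapply(seq_len(nrow(obs)), function(i) {
    m <- array(rnorm(prod(dims), sd = 0.2), dims)
    m[slope_vox] <- m[slope_vox] + 0.01 * obs$x[i]
    m
  })
  vf <- voxelwise_fit(maps, obs, mask, include_quadratic = FALSE)
  expect_true(all(vf$beta1[slope_vox] > 0))
  expect_true(all(vf$p_beta1[slope_vox] < 0.01))
  expect_gt(min(vf$p_beta1[setdiff(seq_len(16), slope_vox)]), 0.001)
})

test_that("group comparison behaves at the identical and separated extremes", {
  gd <- group_difference_at_timepoint(rep(2, 5), rep(2, 6))
  expect_equal(gd$t, 0)
  expect_equal(gd$p_value, 1)
  set.seed(99)
  a <- rnorm(8, mean = 3, sd = 1)
  b <- rnorm(10, mean = 0, sd = 1)
  gd2 <- group_difference_at_timepoint(a, b)
  expect_lt(gd2$p_value, 0.001)
  expect_error(group_difference_at_timepoint(1, c(1, 2)), "at least 2")
})
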