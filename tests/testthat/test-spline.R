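test_that("B-spline basis is a partition of unity with the expected size", {
  spec <- basis_spec(degree = 3, n_knots = 10, age_domain = c(20, 87))
  ages <- c(20, runif(50, 20, 87), 87)
  B <- build_basis(spec, ages)
  expect_equal(ncol(B), 10 + 3 - 1)
  expect_true(all(abs(rowSums(B) - 1) < 1e-12))
  expect_error(build_basis(spec, c(30, 90)), class = "adipoage_domain_error")
})

test_that("linear basis gives hat functions splitting weight at midpoints", {
  spec <- basis_spec(degree = 1, n_knots = 11, age_domain = c(0, 10))
  B <- build_basis(spec, 3.5)  # midway between integer knots
  nz <- B[1, B[1, ] > 0]
  expect_equal(unname(nz), c(0.5, 0.5))
})

test_that("huge lambda with a second-order penalty collapses onto the OLS line", {
  d <- linear_data(n = 300, seed = 42, sd = 5)
  f <- fit_pspline(d, "y", lambda = 1e12)
  ols <- lm(y ~ age, data = d)
  pred <- unname(predict(ols, data.frame(age = f$fitted_grid$age)))
  expect_lt(max(abs(f$fitted_grid$fit - pred)), 1e-6)
  expect_lt(abs(f$edf - 2), 0.01)
})

test_that("penalty null space passes through the fit unshrunk", {
  set.seed(7)
  age <- runif(250, 20, 87)
  d <- data.frame(age = age, y = 3 + 0.25 * age)  # noiseless line
  f <- fit_pspline(d, "y", lambda = 1e6)
  expect_lt(max(abs(f$fitted_grid$fit - (3 + 0.25 * f$fitted_grid$age))), 1e-7)
})

test_that("automatic smoothing recovers a noiseless quadratic under GCV and REML", {
  set.seed(9)
  age <- runif(400, 20, 87)
  d <- data.frame(age = age, y = -(age - 40)^2 + 500)
  for (m in c("GCV", "REML")) {
    f <- fit_pspline(d, "y", lambda = "auto", method = m)
    tru <- -(f$fitted_grid$age - 40)^2 + 500
    expect_lt(max(abs(f$fitted_grid$fit - tru)), 1e-3)
  }
})

test_that("a constant outcome is fitted exactly with minimal flexibility", {
  set.seed(4)
  d <- data.frame(age = runif(200, 20, 87), y = 7)
  f <- fit_pspline(d, "y", lambda = 1e8)
  expect_lt(max(abs(f$fitted_grid$fit - 7)), 1e-9)
  # order-2 penalty leaves a 2-dimensional null space, so edf floors at 2
  expect_lt(f$edf, 2.1)
})

test_that("effective degrees of freedom decrease monotonically in lambda", {
  d <- linear_data(n = 250, seed = 3, sd = 10)
  edfs <- vapply(10^seq(-3, 8, by = 1),
                 function(l) fit_pspline(d, "y", lambda = l)$edf, 0)
  expect_true(all(diff(edfs) < 1e-6))
  expect_true(all(edfs >= 2 - 1e-6 & edfs <= 22))
})

test_that("shifting the outcome by a constant shifts the curve exactly", {
  d <- linear_data(n = 200, seed = 6, sd = 8)
  f1 <- fit_pspline(d, "y", lambda = 10)
  d$y <- d$y + 123.4
  f2 <- fit_pspline(d, "y", lambda = 10)
  expect_equal(f2$fitted_grid$fit, f1$fitted_grid$fit + 123.4, tolerance = 1e-9)
})

test_that("a pure-noise covariate barely moves the fitted trajectory", {
  coh <- generate_cohort(cohort_config(n_subjects = 1000, seed = 15))
  coh$noise_cov <- rnorm(1000)
  f0 <- fit_pspline(coh, "wm_volume", c("sex", "icv"))
  f1 <- fit_pspline(coh, "wm_volume", c("sex", "icv", "noise_cov"))
  se <- pmax(f0$fitted_grid$se, 1e-6)
  expect_true(all(abs(f1$fitted_grid$fit - f0$fitted_grid$fit) < 2 * se))
})

test_that("collinear covariates raise a collinearity error naming columns", {
  coh <- generate_cohort(cohort_config(n_subjects = 200, seed = 2))
  coh$icv2 <- coh$icv
  expect_error(fit_pspline(coh, "wm_volume", c("icv", "icv2")),
               "icv2", class = "adipoage_collinearity_error")
  coh$wm_volume[1] <- Inf
  expect_error(fit_pspline(coh[1:50, ], "wm_volume"),
               class = "adipoage_input_error")
})

test_that("the penalized fit agrees with an independent GAM smoother", {
  skip_if_not_installed("mgcv")
  coh <- generate_cohort(cohort_config(n_subjects = 800, seed = 19))
  f <- fit_pspline(coh, "wm_volume")
  g <- mgcv::gam(wm_volume ~ s(age), data = as.data.frame(coh), method = "REML")
  grid <- data.frame(age = f$fitted_grid$age)
  gp <- as.numeric(mgcv::predict.gam(g, grid))
  # both smoothers should describe the same inverted-U within a few cm^3
  expect_gt(cor(f$fitted_grid$fit, gp), 0.99)
  expect_lt(max(abs(f$fitted_grid$fit - gp)), 5 * max(f$fitted_grid$se))
})

test_that("age-by-BMI interaction is detected under a true trajectory shift", {
  coh <- generate_cohort(cohort_config(n_subjects = 473, seed = 2))
  it <- test_interaction(coh)
  expect_lt(it$t, 0)   # heavier subjects sit lower at older matched ages
  expect_lt(it$p, 0.01)
  itg <- test_interaction(coh, bmi_coding = "group")
  expect_lt(itg$t, 0)
})

test_that("interaction test is quiet when BMI carries no information", {
  coh <- generate_cohort(cohort_config(n_subjects = 400, seed = 23))
  set.seed(77)
  ts <- replicate(10, {
    shuf <- coh
    shuf$bmi <- sample(shuf$bmi)   # break any BMI link by permutation
    test_interaction(shuf)$t
  })
  expect_true(all(abs(ts) < 4))
  expect_gt(max(2 * pt(-abs(ts), df = 380)), 0.1)
})
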