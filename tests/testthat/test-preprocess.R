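test_that("BMI classification uses half-open bands with 25 and 30 on the heavier side", {
  expect_equal(as.character(classify_bmi(c(17, 22.7, 25.0, 27.1, 30.0, 33.5))),
               c("underweight", "lean", "overweight", "overweight", "obese", "obese"))
  expect_equal(as.character(classify_bmi(18.5)), "lean")
  expect_error(classify_bmi(c(22, -1)), class = "adipoage_domain_error")
})

test_that("exclusions apply in order age, underweight, quality and reconcile", {
  coh <- generate_cohort(cohort_config(n_subjects = 200, seed = 5,
                                       age_range = c(15, 87),
                                       wm_peak_age_lean = 43,
                                       include_underweight = TRUE,
                                       underweight_rate = 0.1))
  res <- apply_exclusions(coh)
  rep <- res$report
  expect_equal(rep$n_retained + rep$n_excluded_age + rep$n_excluded_underweight +
                 rep$n_excluded_qc, rep$n_input)
  expect_equal(nrow(rep$excluded_ids),
               rep$n_excluded_age + rep$n_excluded_underweight + rep$n_excluded_qc)
  # each subject counted once, under its first triggering rule
  uw_young <- coh$subject_id[coh$age < 20 & coh$bmi < 18.5]
  if (length(uw_young)) {
    reasons <- rep$excluded_ids$reason[rep$excluded_ids$subject_id %in% uw_young]
    expect_true(all(reasons == "age"))
  }
  # idempotence
  res2 <- apply_exclusions(res$cohort)
  expect_equal(as.data.frame(res2$cohort), as.data.frame(res$cohort))
  expect_equal(res2$report$n_retained, res2$report$n_input)
})

test_that("single underweight subject is excluded with the underweight reason", {
  coh <- generate_cohort(cohort_config(n_subjects = 5, seed = 1, qc_poor_rate = 1e-9))
  coh$bmi[2] <- 17
  res <- apply_exclusions(coh)
  expect_true(coh$subject_id[2] %in% res$report$excluded_ids$subject_id)
  expect_equal(res$report$excluded_ids$reason[
    res$report$excluded_ids$subject_id == coh$subject_id[2]], "underweight")
  # clean cohort passes through untouched
  clean <- coh[-2, ]
  clean$qc <- "good"
  res2 <- apply_exclusions(as_cohort(clean))
  expect_equal(res2$report$n_retained, nrow(clean))
  expect_equal(res2$report$n_excluded_qc, 0)
})

test_that("quality exclusions follow the configured failure rate", {
  # flat 10% poor probability: excluded count should sit in the binomial band
  cfg <- cohort_config(n_subjects = 600, seed = 17, qc_poor_rate = 0.10,
                       qc_age_coefficient = 0)
  res <- apply_exclusions(generate_cohort(cfg))
  band <- qbinom(c(0.025, 0.975), 600, 0.10)
  expect_gte(res$report$n_excluded_qc, band[1])
  expect_lte(res$report$n_excluded_qc, band[2])
})

test_that("hemisphere aggregation sums volumes/areas and averages thickness", {
  expect_equal(aggregate_hemispheres(200, 210, "volume_sum"), 410)
  expect_equal(aggregate_hemispheres(2.4, 2.6, "thickness_mean"), 2.5)
  x <- runif(20, 1, 3)
  expect_equal(aggregate_hemispheres(x, x, "thickness_mean"), x)
  expect_error(aggregate_hemispheres(2.4, NA, "thickness_mean", subject = "S1"),
               "S1", class = "adipoage_missing_data_error")
})

test_that("Box-Cox handles fixed lambdas, the MLE, and preserves order", {
  expect_equal(boxcox_transform(c(2, 3, 4), lambda = 1)$values, c(1, 2, 3))
  expect_equal(boxcox_transform(c(1, exp(1)), lambda = 0)$values, c(0, 1))
  set.seed(8)
  x <- rlnorm(2000, 0, 0.5)
  bc <- boxcox_transform(x, lambda = "mle")
  expect_lt(abs(bc$lambda), 0.15)
  for (lam in c(-1, 0, 0.5, 2)) {
    v <- boxcox_transform(sort(runif(50, 0.1, 10)), lambda = lam)$values
    expect_true(all(diff(v) > 0))
  }
  err <- tryCatch(boxcox_transform(c(1, -2, 3, 0)), error = identity)
  expect_s3_class(err, "adipoage_domain_error")
  expect_equal(err$indices, c(2, 4))
})

test_that("Bland-Altman recovers bias and limits, and its test holds size", {
  x <- rnorm(50)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(unname(ba0$limits_of_agreement), c(0, 0))
  ba_c <- bland_altman(x, x + 3)
  expect_equal(ba_c$mean_difference, 3)
  # symmetry: swapping roles negates the bias and mirrors the limits
  set.seed(2)
  pre <- rnorm(80); post <- pre + rnorm(80, 0.5, 1)
  a <- bland_altman(pre, post); b <- bland_altman(post, pre)
  expect_equal(b$mean_difference, -a$mean_difference)
  expect_equal(unname(b$limits_of_agreement),
               rev(-unname(a$limits_of_agreement)))
  expect_equal(a$f_statistic, b$f_statistic)
  # Monte-Carlo size of the paired test under a true zero mean difference
  set.seed(31)
  p_over <- mean(replicate(200, {
    pre <- rnorm(100)
    bland_altman(pre, pre + rnorm(100))$p_value > 0.05
  }))
  expect_gte(p_over, 0.90)
  expect_error(bland_altman(1:5, 1:4), class = "adipoage_input_error")
})
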