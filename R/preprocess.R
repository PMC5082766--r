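#' Classify BMI into study weight groups
#'
#' Half-open intervals: underweight (0, 18.5), lean [18.5, 25),
#' overweight [25, 30), obese [30, Inf). The boundary convention follows the
#' operative grouping table (18.5-24.99 / 25-29.99 / >=30), so 25 is
#' overweight and 30 is obese.
#'
#' @param bmi numeric vector of BMI values, kg m^-2; must be positive.
#' @return factor with levels underweight, lean, overweight, obese.
#' @examples
#' classify_bmi(c(22.7, 25, 30, 33.5))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop_domain("bmi must be positive and finite")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "lean", "overweight", "obese"))
}

#' Apply study inclusion/exclusion rules
#'
#' Excludes subjects below a minimum age, underweight subjects, and subjects
#' whose reconstruction quality falls in `drop_qc`. Rules are applied in that
#' fixed order and each excluded subject is counted once, under the first
#' rule it triggers, so the report counts always reconcile.
#'
#' @param cohort a `cohort`.
#' @param min_age minimum age in years (default 20).
#' @param min_bmi minimum BMI (default 18.5; below it is underweight).
#' @param drop_qc quality labels to exclude (default `"poor"`).
#' @return a list with elements `cohort` (retained subjects) and `report`
#'   (an `exclusion_report` with per-rule counts and excluded ids).
#' @export
apply_exclusions <- function(cohort, min_age = 20, min_bmi = 18.5,
                             drop_qc = "poor") {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  age_bad <- cohort$age < min_age
  bmi_bad <- !age_bad & cohort$bmi < min_bmi
  qc_bad <- !age_bad & !bmi_bad & cohort$qc %in% drop_qc
  keep <- !(age_bad | bmi_bad | qc_bad)
  if (!any(keep))
    stop_pipeline("all subjects excluded; downstream fits impossible")
  excluded <- data.frame(
    subject_id = cohort$subject_id[!keep],
    reason = c("age", "underweight", "qc")[
      max.col(cbind(age_bad, bmi_bad, qc_bad)[!keep, , drop = FALSE],
              ties.method = "first")],
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_input = nrow(cohort),
    n_excluded_age = sum(age_bad),
    n_excluded_underweight = sum(bmi_bad),
    n_excluded_qc = sum(qc_bad),
    n_retained = sum(keep),
    excluded_ids = excluded
  ), class = "exclusion_report")
  retained <- as_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
                        provenance = attr(cohort, "provenance"))
  list(cohort = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusions: %d in -> %d retained (%d age, %d underweight, %d quality)\n",
              x$n_input, x$n_retained, x$n_excluded_age,
              x$n_excluded_underweight, x$n_excluded_qc))
  invisible(x)
}

#' Aggregate left/right hemisphere measures
#'
#' Volumes and areas are summed across hemispheres; thickness is averaged.
#'
#' @param left,right per-hemisphere values; must be present and positive.
#' @param kind `"volume_sum"`, `"area_sum"` or `"thickness_mean"`.
#' @param subject optional identifier(s) used in error messages.
#' @return the aggregated measure (vectorized).
#' @export
aggregate_hemispheres <- function(left, right,
                                  kind = c("volume_sum", "area_sum", "thickness_mean"),
                                  subject = NULL) {
  kind <- match.arg(kind)
  bad <- !is.finite(left) | !is.finite(right) | is.na(left) | is.na(right)
  if (any(bad)) {
    who <- if (!is.null(subject)) paste(subject[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop_missing(paste0("missing hemisphere value for subject(s): ", who))
  }
  if (any(left <= 0) || any(right <= 0))
    stop_domain("hemisphere measures must be positive")
  if (kind == "thickness_mean") (left + right) / 2 else left + right
}

#' Box-Cox power transform
#'
#' Standard Box-Cox: `(x^k - 1)/k` for `k != 0`, `log(x)` at `k = 0`. With
#' `lambda = "mle"` the exponent maximizes the normal-model profile
#' log-likelihood (computed with [MASS::boxcox()] on an intercept-only model).
#'
#' @param x positive numeric vector.
#' @param lambda a number, or `"mle"` to estimate it.
#' @return list with `values` (transformed vector) and `lambda` (the value used).
#' @examples
#' boxcox_transform(c(2, 3, 4), lambda = 1)$values  # x - 1
#' @export
boxcox_transform <- function(x, lambda = "mle") {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop_domain(paste0("Box-Cox requires positive values; offending indices: ",
                       paste(utils::head(bad, 10), collapse = ", ")),
                indices = bad)
  if (identical(lambda, "mle")) {
    prof <- MASS::boxcox(x ~ 1, data = data.frame(x = x),
                         lambda = seq(-2, 2, 0.01), plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }
  values <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(values = values, lambda = lambda)
}

#' Bland-Altman agreement between paired measurements
#'
#' Mean difference (bias), 1.96 SD limits of agreement, and a paired test of
#' zero mean difference (reported as an F statistic, the square of the paired
#' t, with its two-sided p value).
#'
#' @param pre,post equal-length paired measurement vectors (n >= 3).
#' @return an `agreement_result` list: `mean_difference`,
#'   `limits_of_agreement` (low, high), `f_statistic`, `p_value`, `n`.
#' @export
bland_altman <- function(pre, post) {
  if (length(pre) != length(post))
    stop_input("pre and post must have equal length")
  if (length(pre) < 3) stop_input("need at least 3 pairs")
  d <- post - pre
  m <- mean(d)
  s <- stats::sd(d)
  if (s <= 1e-10 * (abs(m) + 1)) {
    s <- 0
    f <- if (m == 0) 0 else Inf
    p <- if (m == 0) 1 else 0
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    f <- unname(tt$statistic)^2
    p <- tt$p.value
  }
  structure(list(
    mean_difference = m,
    limits_of_agreement = c(low = m - 1.96 * s, high = m + 1.96 * s),
    f_statistic = f, p_value = p, n = length(d)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, limits [%.4g, %.4g], F = %.3g, p = %.3g\n",
              x$n, x$mean_difference, x$limits_of_agreement[1],
              x$limits_of_agreement[2], x$f_statistic, x$p_value))
  invisible(x)
}
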