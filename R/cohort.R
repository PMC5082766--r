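#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set of the synthetic cross-sectional
#' cohort generator. The generator emulates the statistical structure of a
#' population ageing study: ages spread over adulthood, BMI positively
#' correlated with age, an inverted-U white-matter-volume trajectory whose
#' peak is shifted toward younger ages in overweight/obese subjects,
#' near-linear cortical decline, nonlinear fluid-intelligence decline, and
#' image-quality failure that becomes more likely with age.
#'
#' @param n_subjects number of subjects to generate.
#' @param seed integer root seed; all per-column substreams derive from it.
#' @param age_range numeric length-2, years (low, high).
#' @param group_probs expected proportions of (lean, overweight, obese);
#'   must sum to 1.
#' @param bmi_model `"copula"` (default) draws BMI from a right-skewed
#'   shifted-lognormal marginal coupled to age through a Gaussian copula, so
#'   both the age-BMI correlation and the group proportions are controlled;
#'   `"linear"` uses `bmi_base + bmi_age_slope * (age - mid) + N(0, bmi_sd)`
#'   truncated at 18.5.
#' @param bmi_age_cor latent copula correlation between age and BMI
#'   (calibrated default 0.275 yields Pearson r near 0.24).
#' @param bmi_lognorm (meanlog, sdlog) of the shifted-lognormal BMI marginal,
#'   `bmi = 18.5 + LN(meanlog, sdlog)`.
#' @param bmi_base,bmi_age_slope,bmi_sd parameters of the `"linear"` BMI model
#'   (kg m^-2, kg m^-2 per year, kg m^-2).
#' @param include_underweight if `TRUE`, a fraction `underweight_rate` of
#'   subjects receive BMI in (16, 18.5) so exclusion paths can be exercised.
#' @param underweight_rate see `include_underweight`.
#' @param wm_peak_age_lean age (years) at which the lean white-matter
#'   trajectory peaks; must lie inside `age_range`.
#' @param wm_peak_volume peak white-matter volume, cm^3.
#' @param wm_curvature concavity of the trajectory, cm^3 per year^2.
#' @param true_age_shift years; the overweight/obese trajectory is the lean
#'   trajectory evaluated at `age + true_age_shift` (horizontal shift), so the
#'   true brain-age difference on the descending limb is exactly this value.
#' @param wm_noise_sd residual SD of white-matter volume, cm^3.
#' @param trajectory_form `"quadratic"` (default) or `"piecewise"`; the
#'   piecewise variant multiplies the curvature by `wm_rise_ratio` on the
#'   ascending limb, giving an asymmetric inverted U for robustness tests.
#' @param wm_rise_ratio ascending-limb curvature multiplier (piecewise form).
#' @param thickness_intercept,thickness_slope mean cortical thickness (mm) at
#'   mid-age and its linear slope (mm per year).
#' @param thickness_group_offset additive thickness offset (mm) for
#'   overweight/obese subjects.
#' @param thickness_noise_sd residual SD of thickness, mm.
#' @param thickness_gw_coef thickness change per percentage point of
#'   gray-white contrast (myelination surrogate), mm.
#' @param area_intercept,area_slope,area_noise_sd total pial surface area
#'   (cm^2) at mid-age, slope (cm^2 per year), residual SD.
#' @param area_icv_coef surface-area change per cm^3 of ICV.
#' @param cattell_params (level, decline-rate, nonlinearity): score at age 20,
#'   linear decline per year, quadratic acceleration per year^2.
#' @param cattell_icv_coef score points per cm^3 of ICV (brain-size effect).
#' @param cattell_noise_sd residual SD of the Cattell score.
#' @param icv_mean named (female, male) mean intracranial volumes, cm^3.
#' @param icv_sd within-sex ICV standard deviation, cm^3.
#' @param p_female probability of female sex.
#' @param gw_contrast_mean,gw_contrast_slope,gw_contrast_noise_sd gray-white
#'   percentage contrast at mid-age, slope per year, residual SD.
#' @param covariate_prevalences named list of binary-flag prevalences; each
#'   element is either a single probability or `c(p, age_logodds)` where the
#'   flag probability is `plogis(qlogis(p) + age_logodds * (age - mid))`.
#' @param activity_mean,activity_sd physical activity (kJ/day/kg), truncated
#'   at zero.
#' @param qc_poor_rate probability of a "poor" reconstruction at mid-age.
#' @param qc_age_coefficient log-odds increase of "poor" quality per year of
#'   age (older subjects fail quality control more often).
#' @param qc_adequate_rate probability of an "adequate" rating.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [trajectory_true()]
#' @export
cohort_config <- function(n_subjects = 473,
                          seed = 1L,
                          age_range = c(20, 87),
                          group_probs = c(lean = 0.51, overweight = 0.31, obese = 0.18),
                          bmi_model = c("copula", "linear"),
                          bmi_age_cor = 0.275,
                          bmi_lognorm = c(meanlog = 1.856, sdlog = 0.640),
                          bmi_base = 26, bmi_age_slope = 0.057, bmi_sd = 4.5,
                          include_underweight = FALSE, underweight_rate = 0.03,
                          wm_peak_age_lean = 43,
                          wm_peak_volume = 465,
                          wm_curvature = 0.07,
                          true_age_shift = 10,
                          wm_noise_sd = 15,
                          trajectory_form = c("quadratic", "piecewise"),
                          wm_rise_ratio = 1,
                          thickness_intercept = 2.45, thickness_slope = -0.004,
                          thickness_group_offset = 0.02, thickness_noise_sd = 0.08,
                          thickness_gw_coef = 0.01,
                          area_intercept = 1900, area_slope = -2.5, area_noise_sd = 110,
                          area_icv_coef = 0.8,
                          cattell_params = c(level = 38, rate = 0.05, nonlinearity = 0.0015),
                          cattell_icv_coef = 0.005,
                          cattell_noise_sd = 4,
                          icv_mean = c(female = 1400, male = 1550),
                          icv_sd = 110,
                          p_female = 0.5,
                          gw_contrast_mean = 20, gw_contrast_slope = -0.05,
                          gw_contrast_noise_sd = 1.5,
                          covariate_prevalences = list(
                            high_bp = c(0.165, 0.05), diabetes = 0.038,
                            cancer = 0.055, mi = 0.011, stroke = 0.011,
                            high_chol = c(0.116, 0.04), degree = c(0.638, -0.03),
                            income_above = 0.573, smoker = c(0.126, -0.02)
                          ),
                          activity_mean = 47, activity_sd = 21,
                          qc_poor_rate = 0.07,
                          qc_age_coefficient = 0.04,
                          qc_adequate_rate = 0.12) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    age_range = as.numeric(age_range), group_probs = group_probs,
    bmi_model = match.arg(bmi_model), bmi_age_cor = bmi_age_cor,
    bmi_lognorm = bmi_lognorm, bmi_base = bmi_base,
    bmi_age_slope = bmi_age_slope, bmi_sd = bmi_sd,
    include_underweight = include_underweight, underweight_rate = underweight_rate,
    wm_peak_age_lean = wm_peak_age_lean, wm_peak_volume = wm_peak_volume,
    wm_curvature = wm_curvature, true_age_shift = true_age_shift,
    wm_noise_sd = wm_noise_sd, trajectory_form = match.arg(trajectory_form),
    wm_rise_ratio = wm_rise_ratio,
    thickness_intercept = thickness_intercept, thickness_slope = thickness_slope,
    thickness_group_offset = thickness_group_offset,
    thickness_noise_sd = thickness_noise_sd, thickness_gw_coef = thickness_gw_coef,
    area_intercept = area_intercept, area_slope = area_slope,
    area_noise_sd = area_noise_sd, area_icv_coef = area_icv_coef,
    cattell_params = cattell_params, cattell_icv_coef = cattell_icv_coef,
    cattell_noise_sd = cattell_noise_sd,
    icv_mean = icv_mean, icv_sd = icv_sd, p_female = p_female,
    gw_contrast_mean = gw_contrast_mean, gw_contrast_slope = gw_contrast_slope,
    gw_contrast_noise_sd = gw_contrast_noise_sd,
    covariate_prevalences = covariate_prevalences,
    activity_mean = activity_mean, activity_sd = activity_sd,
    qc_poor_rate = qc_poor_rate, qc_age_coefficient = qc_age_coefficient,
    qc_adequate_rate = qc_adequate_rate
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.finite(cfg$n_subjects) || cfg$n_subjects < 1)
    stop_config("n_subjects must be a positive integer", field = "n_subjects")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop_config("age_range must satisfy low < high", field = "age_range")
  if (abs(sum(cfg$group_probs) - 1) > 1e-12)
    stop_config("group_probs must sum to 1 (within 1e-12)", field = "group_probs")
  if (any(cfg$group_probs < 0))
    stop_config("group_probs must be non-negative", field = "group_probs")
  if (cfg$wm_peak_age_lean <= cfg$age_range[1] || cfg$wm_peak_age_lean >= cfg$age_range[2])
    stop_config("wm_peak_age_lean must lie inside age_range", field = "wm_peak_age_lean")
  sds <- c(wm_noise_sd = cfg$wm_noise_sd, thickness_noise_sd = cfg$thickness_noise_sd,
           area_noise_sd = cfg$area_noise_sd, cattell_noise_sd = cfg$cattell_noise_sd,
           icv_sd = cfg$icv_sd, gw_contrast_noise_sd = cfg$gw_contrast_noise_sd,
           activity_sd = cfg$activity_sd, bmi_sd = cfg$bmi_sd)
  bad <- names(sds)[sds < 0]
  if (length(bad))
    stop_config(paste0("noise SDs must be >= 0: ", paste(bad, collapse = ", ")),
                field = bad[1])
  if (cfg$wm_curvature < 0)
    stop_config("wm_curvature must be >= 0 (concave trajectory)", field = "wm_curvature")
  invisible(cfg)
}

# Deterministic per-column substreams: a fixed table of stream seeds derived
# from the root seed, so adding a new column never perturbs existing ones.
substream_seeds <- function(seed, n = 32L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_stream <- function(stream_seed, expr) {
  set.seed(stream_seed)
  expr
}

# Noiseless generating trajectory (no range check; used internally so group
# shifts can be evaluated beyond the sampled age range).
.traj_lean <- function(cfg, age) {
  d <- age - cfg$wm_peak_age_lean
  curv <- rep(cfg$wm_curvature, length(d))
  if (cfg$trajectory_form == "piecewise")
    curv[d < 0] <- cfg$wm_curvature * cfg$wm_rise_ratio
  cfg$wm_peak_volume - curv * d^2
}

#' Noiseless generating white-matter trajectory
#'
#' Oracle for parameter-recovery tests: the expected white-matter volume at a
#' given age under the generating model. Overweight/obese subjects follow the
#' lean trajectory evaluated at `age + true_age_shift`.
#'
#' @param config a [cohort_config()].
#' @param group one of `"lean"`, `"overweight"`, `"obese"`.
#' @param age years; must lie within `config$age_range`.
#' @return expected white-matter volume, cm^3 (vectorized over `age`).
#' @export
trajectory_true <- function(config, group = c("lean", "overweight", "obese"), age) {
  group <- match.arg(group)
  if (any(age < config$age_range[1] - 1e-9 | age > config$age_range[2] + 1e-9))
    stop_domain("age outside the configured age_range")
  shift <- if (group == "lean") 0 else config$true_age_shift
  .traj_lean(config, age + shift)
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws `config$n_subjects` subjects with demographics, health/lifestyle
#' flags, morphometrics and a quality rating, using one deterministic
#' substream per column derived from `config$seed`. Identical (config, seed)
#' pairs give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return a `cohort`: a `data.frame` with one row per subject and columns
#'   `subject_id, age, sex, bmi, icv, wm_volume, surface_area, thickness,
#'   gw_contrast, cattell, qc, high_bp, diabetes, cancer, mi, stroke,
#'   high_chol, degree, income_above, smoker, activity`, carrying the
#'   generating config and seed as a `provenance` attribute.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 200, seed = 1))
#' cor(coh$age, coh$bmi)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_subjects
  ss <- substream_seeds(cfg$seed)
  mid <- mean(cfg$age_range)

  # ages recorded at 0.01-y precision; all downstream columns derive from the
  # recorded value so the stored table is an exact function of itself
  age_raw <- with_stream(ss[1], runif(n, cfg$age_range[1], cfg$age_range[2]))
  age <- pmin(pmax(round(age_raw, 2), cfg$age_range[1]), cfg$age_range[2])
  sex <- with_stream(ss[2], ifelse(runif(n) < cfg$p_female, "female", "male"))

  if (cfg$bmi_model == "copula") {
    z_age <- qnorm(punif(age_raw, cfg$age_range[1], cfg$age_range[2]))
    rho <- cfg$bmi_age_cor
    z <- rho * z_age + sqrt(1 - rho^2) * with_stream(ss[3], rnorm(n))
    u <- pnorm(z)
    # Remap band masses so expected group proportions equal group_probs
    # exactly, while the within-band shape follows the lognormal marginal.
    ml <- cfg$bmi_lognorm[["meanlog"]]; sl <- cfg$bmi_lognorm[["sdlog"]]
    p25 <- plnorm(25 - 18.5, ml, sl); p30 <- plnorm(30 - 18.5, ml, sl)
    g <- cumsum(cfg$group_probs)
    u2 <- ifelse(u < g[1], u / g[1] * p25,
          ifelse(u < g[2], p25 + (u - g[1]) / (g[2] - g[1]) * (p30 - p25),
                 p30 + (u - g[2]) / (1 - g[2]) * (1 - p30)))
    bmi <- 18.5 + qlnorm(pmin(pmax(u2, 1e-12), 1 - 1e-12), ml, sl)
  } else {
    bmi <- cfg$bmi_base + cfg$bmi_age_slope * (age - mid) +
      with_stream(ss[3], rnorm(n, 0, cfg$bmi_sd))
    bmi <- pmax(bmi, 18.5)
  }
  if (cfg$include_underweight) {
    uw <- with_stream(ss[4], runif(n))
    draw <- with_stream(ss[5], runif(n, 16, 18.4))
    bmi[uw < cfg$underweight_rate] <- draw[uw < cfg$underweight_rate]
  }
  bmi <- round(bmi, 2)

  icv <- with_stream(ss[6], rnorm(n, ifelse(sex == "female",
                                            cfg$icv_mean[["female"]],
                                            cfg$icv_mean[["male"]]), cfg$icv_sd))
  icv <- round(icv, 1)
  icv_ref <- cfg$p_female * cfg$icv_mean[["female"]] +
    (1 - cfg$p_female) * cfg$icv_mean[["male"]]

  heavy <- bmi >= 25
  wm_mean <- .traj_lean(cfg, age + ifelse(heavy, cfg$true_age_shift, 0))
  wm <- wm_mean * (icv / icv_ref) + with_stream(ss[7], rnorm(n, 0, cfg$wm_noise_sd))

  area <- cfg$area_intercept + cfg$area_slope * (age - mid) +
    cfg$area_icv_coef * (icv - icv_ref) +
    with_stream(ss[8], rnorm(n, 0, cfg$area_noise_sd))

  gw <- round(cfg$gw_contrast_mean + cfg$gw_contrast_slope * (age - mid) +
    with_stream(ss[9], rnorm(n, 0, cfg$gw_contrast_noise_sd)), 2)

  thick <- cfg$thickness_intercept + cfg$thickness_slope * (age - mid) +
    cfg$thickness_group_offset * heavy +
    cfg$thickness_gw_coef * (gw - cfg$gw_contrast_mean) +
    with_stream(ss[10], rnorm(n, 0, cfg$thickness_noise_sd))

  cp <- cfg$cattell_params
  cattell <- cp[["level"]] - cp[["rate"]] * (age - 20) -
    cp[["nonlinearity"]] * (age - 20)^2 +
    cfg$cattell_icv_coef * (icv - icv_ref) +
    with_stream(ss[11], rnorm(n, 0, cfg$cattell_noise_sd))

  p_poor <- plogis(qlogis(cfg$qc_poor_rate) + cfg$qc_age_coefficient * (age - mid))
  uq <- with_stream(ss[12], runif(n))
  qc <- ifelse(uq < p_poor, "poor",
               ifelse(uq < p_poor + cfg$qc_adequate_rate, "adequate", "good"))

  flags <- lapply(seq_along(cfg$covariate_prevalences), function(i) {
    pr <- cfg$covariate_prevalences[[i]]
    p <- if (length(pr) == 2) plogis(qlogis(pr[1]) + pr[2] * (age - mid)) else rep(pr, n)
    as.integer(with_stream(ss[12 + i], runif(n)) < p)
  })
  names(flags) <- names(cfg$covariate_prevalences)

  activity <- pmax(with_stream(ss[30], rnorm(n, cfg$activity_mean, cfg$activity_sd)), 0)

  coh <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, bmi = bmi, icv = icv,
    wm_volume = round(wm, 2), surface_area = round(area, 1),
    thickness = round(thick, 3), gw_contrast = gw,
    cattell = round(cattell, 1), qc = qc,
    high_bp = flags$high_bp, diabetes = flags$diabetes, cancer = flags$cancer,
    mi = flags$mi, stroke = flags$stroke, high_chol = flags$high_chol,
    degree = flags$degree, income_above = flags$income_above,
    smoker = flags$smoker, activity = round(activity, 1),
    stringsAsFactors = FALSE
  )
  as_cohort(coh, provenance = list(source = "synthetic", seed = cfg$seed,
                                   config = unclass(cfg)))
}

cohort_columns <- c("subject_id", "age", "sex", "bmi", "icv", "wm_volume",
                    "surface_area", "thickness", "gw_contrast", "cattell", "qc",
                    "high_bp", "diabetes", "cancer", "mi", "stroke", "high_chol",
                    "degree", "income_above", "smoker", "activity")

#' Validate a data frame as a cohort
#'
#' Checks the cohort schema and the per-subject invariants (non-negative age,
#' positive BMI/ICV/white-matter volume, a valid quality category).
#'
#' @param x a data.frame with the cohort columns.
#' @param provenance optional list recording where the rows came from.
#' @return `x` with class `cohort` and a `provenance` attribute.
#' @export
as_cohort <- function(x, provenance = list(source = "external")) {
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols))
    stop_input(paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  if (any(x$age < 0, na.rm = TRUE)) stop_input("cohort has negative ages")
  if (any(x$bmi <= 0, na.rm = TRUE)) stop_input("cohort has non-positive BMI")
  if (any(x$icv <= 0, na.rm = TRUE)) stop_input("cohort has non-positive ICV")
  if (any(x$wm_volume <= 0, na.rm = TRUE)) stop_input("cohort has non-positive white-matter volume")
  if (!all(x$qc %in% c("good", "adequate", "poor")))
    stop_input("qc must be one of good/adequate/poor")
  structure(x, class = c("cohort", "data.frame"), provenance = provenance)
}

#' Write / read the cohort CSV dialect
#'
#' `write_cohort()` writes a header row, comma-separated UTF-8, one row per
#' subject, missing values as empty fields, plus a JSON sidecar
#' (`<path>.json`) with the generator configuration and seed when available.
#' `read_cohort()` reads the same dialect back and validates it.
#'
#' @param cohort a `cohort`.
#' @param path output CSV path.
#' @param sidecar write the provenance JSON sidecar next to the CSV?
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a `cohort`.
#' @export
write_cohort <- function(cohort, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns], path,
                   row.names = FALSE, na = "", quote = FALSE, fileEncoding = "UTF-8")
  prov <- attr(cohort, "provenance")
  if (sidecar && !is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  as_cohort(x, provenance = list(source = path))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d, ages %.0f-%.0f\n", x$n_subjects, x$seed,
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  lean WM peak: %.1f cm^3 at %.0f y (curvature %.3f); group age shift %.1f y\n",
              x$wm_peak_volume, x$wm_peak_age_lean, x$wm_curvature, x$true_age_shift))
  invisible(x)
}
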