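#' B-spline basis specification for age-trajectory smooths
#'
#' Defines the penalized-spline basis: cubic B-splines on equally-spaced (or
#' quantile) knots over the age domain with a discrete difference penalty on
#' adjacent coefficients (the standard P-spline construction).
#'
#' @param degree polynomial degree of the B-splines (default cubic).
#' @param n_knots number of knots spanning the age domain, endpoints
#'   included; the basis has `n_knots + degree - 1` functions.
#' @param knot_placement `"equal"` (default) or `"quantile"`.
#' @param penalty_order order of the difference penalty (default 2; its null
#'   space is then straight lines in age).
#' @param age_domain numeric (low, high) years; if `NULL`, taken from the
#'   data at fit time.
#' @return a `basis_spec` list.
#' @export
basis_spec <- function(degree = 3, n_knots = 20,
                       knot_placement = c("equal", "quantile"),
                       penalty_order = 2, age_domain = NULL) {
  knot_placement <- match.arg(knot_placement)
  if (degree < 1) stop_config("degree must be >= 1", field = "degree")
  if (n_knots < penalty_order + 1)
    stop_config("n_knots must be >= penalty_order + 1", field = "n_knots")
  if (!is.null(age_domain) && (length(age_domain) != 2 || age_domain[1] >= age_domain[2]))
    stop_config("age_domain must satisfy low < high", field = "age_domain")
  structure(list(degree = degree, n_knots = n_knots,
                 knot_placement = knot_placement,
                 penalty_order = penalty_order, age_domain = age_domain),
            class = "basis_spec")
}

# Full (extended) knot sequence for the spec over a concrete domain.
spec_knots <- function(spec, ages) {
  dom <- spec$age_domain %||% range(ages)
  lo <- dom[1]; hi <- dom[2]
  if (spec$knot_placement == "equal") {
    inner <- seq(lo, hi, length.out = spec$n_knots)
  } else {
    inner <- unique(as.numeric(stats::quantile(
      ages, probs = seq(0, 1, length.out = spec$n_knots), type = 7)))
    inner[1] <- lo; inner[length(inner)] <- hi
  }
  d <- spec$degree
  h1 <- inner[2] - inner[1]
  h2 <- inner[length(inner)] - inner[length(inner) - 1]
  c(lo - rev(seq_len(d)) * h1, inner, hi + seq_len(d) * h2)
}

#' Build the B-spline design matrix
#'
#' Rows are subjects, columns basis functions; every row sums to one
#' (B-spline partition of unity). Ages outside the basis domain are an error
#' (no clamping).
#'
#' @param spec a [basis_spec()] with a non-`NULL` `age_domain` (or supply
#'   ages spanning the intended domain).
#' @param ages numeric vector of ages, years.
#' @return numeric matrix, `length(ages)` by `n_knots + degree - 1`.
#' @export
build_basis <- function(spec, ages) {
  dom <- spec$age_domain %||% range(ages)
  if (any(ages < dom[1] - 1e-9 | ages > dom[2] + 1e-9))
    stop_domain("ages outside the basis age_domain")
  knots <- spec_knots(spec, ages)
  splines::splineDesign(knots, pmin(pmax(ages, dom[1]), dom[2]),
                        ord = spec$degree + 1)
}

# ---- penalized least-squares core ------------------------------------------

chol_safe <- function(A) {
  tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-9 * mean(diag(A)), ncol(A))))
}

# Normal-equation solve of min ||y - C theta||^2 + lambda ||Dfull theta||^2
# with cached cross-products; cheap enough to call inside lambda selection
# and bootstrap loops.
pen_core <- function(C, y, CtC, Cty, PtP, lambda, need_edf = TRUE) {
  A <- CtC + lambda * PtP
  Rc <- chol_safe(A)
  theta <- backsolve(Rc, backsolve(Rc, Cty, transpose = TRUE))
  r <- y - drop(C %*% theta)
  out <- list(theta = theta, rss = sum(r^2),
              logdetA = 2 * sum(log(diag(Rc))))
  if (need_edf) out$edf <- sum(chol2inv(Rc) * CtC)
  out
}

# Smoothing-parameter selection by GCV or (profiled) REML on log lambda.
select_lambda <- function(C, y, CtC, Cty, PtP, Dfull, n_unpenalized,
                          method = c("GCV", "REML"),
                          interval = log(c(1e-7, 1e9))) {
  method <- match.arg(method)
  n <- length(y)
  p_pen <- nrow(Dfull)           # rank of the penalty
  M <- n_unpenalized             # dimension of the unpenalized space
  obj <- function(loglam) {
    lam <- exp(loglam)
    f <- pen_core(C, y, CtC, Cty, PtP, lam)
    if (method == "GCV") {
      denom <- n - f$edf
      if (denom < 1) return(Inf)
      n * f$rss / denom^2
    } else {
      rss_pen <- f$rss + lam * sum((Dfull %*% f$theta)^2)
      (n - M) * log(max(rss_pen, 1e-300)) + f$logdetA - p_pen * loglam
    }
  }
  opt <- stats::optimize(obj, interval = interval, tol = 0.05)
  exp(opt$minimum)
}

#' Fit a penalized-spline age-trajectory model
#'
#' Minimizes `||y - B theta - X beta||^2 + lambda ||D theta||^2` where `B` is
#' the B-spline design in age, `X` holds mean-centered, unpenalized linear
#' covariates, and `D` is the difference operator of the penalty order. The
#' smoothing parameter is selected by GCV (default) or REML; the final solve
#' uses an augmented QR factorization of `[C; sqrt(lambda) D]`, which remains
#' numerically exact for arbitrarily large `lambda` (where the fit collapses
#' onto the penalty null space, e.g. a straight line for a second-order
#' penalty).
#'
#' Covariates are centered at their cohort means (sex at 1/2, i.e. a
#' sex-balanced reference), so the fitted grid is the trajectory of a
#' reference subject with average covariates.
#'
#' @param cohort a `cohort` (or any data.frame with an `age` column).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names (unpenalized
#'   linear terms). `"sex"` is coded male = 1 and centered at 0.5.
#' @param spec a [basis_spec()]; default cubic, 20 knots, order-2 penalty
#'   over the observed age range.
#' @param lambda non-negative number, or `"auto"` to select by `method`.
#' @param method `"GCV"` or `"REML"` smoothing selection.
#' @param extra optional named list of additional numeric regressors (e.g.
#'   interaction terms); centered and left unpenalized, reported in
#'   `term_tests`.
#' @param center optional named list of centering values overriding the
#'   cohort means (used to put several group fits on a common reference).
#' @param grid_step spacing (years) of the fitted evaluation grid.
#' @return a `pspline_fit` with spline coefficients, covariate coefficients,
#'   `lambda`, smooth and total effective degrees of freedom, residual SD,
#'   the fitted grid (age, fit, se), a whole-smooth F test against the
#'   covariates-only model, and per-term t tests.
#' @export
fit_pspline <- function(cohort, outcome, covariates = character(),
                        spec = NULL, lambda = "auto",
                        method = c("GCV", "REML"), extra = NULL,
                        center = NULL, grid_step = 0.1) {
  method <- match.arg(method)
  dat <- as.data.frame(cohort)
  need <- c("age", outcome, covariates)
  miss_col <- setdiff(need, names(dat))
  if (length(miss_col))
    stop_input(paste0("missing columns: ", paste(miss_col, collapse = ", ")))
  cc <- stats::complete.cases(dat[, need, drop = FALSE])
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  y <- dat[[outcome]]
  if (any(!is.finite(y))) stop_input("non-finite outcome values")
  ages <- dat$age
  spec <- spec %||% basis_spec()
  if (is.null(spec$age_domain)) spec$age_domain <- range(ages)

  B <- build_basis(spec, ages)
  pB <- ncol(B)

  centered_col <- function(nm, v) {
    if (nm == "sex") {
      v <- as.numeric(v == "male") - (center[[nm]] %||% 0.5)
    } else {
      v <- as.numeric(v) - (center[[nm]] %||% mean(as.numeric(v)))
    }
    v
  }
  Xlist <- lapply(covariates, function(nm) centered_col(nm, dat[[nm]]))
  names(Xlist) <- covariates
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      v <- extra[[nm]][cc]
      Xlist[[nm]] <- v - mean(v)
    }
  }
  X <- if (length(Xlist)) do.call(cbind, Xlist) else matrix(0, length(y), 0)
  if (ncol(X)) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop_collinear(paste0("collinear covariate columns: ",
                            paste(dropped, collapse = ", ")))
    }
  }
  if (length(y) <= pB + ncol(X))
    stop_input("more coefficients than observations")

  C <- cbind(B, X)
  D <- diff(diag(pB), differences = spec$penalty_order)
  Dfull <- cbind(D, matrix(0, nrow(D), ncol(X)))
  CtC <- crossprod(C); Cty <- crossprod(C, y); PtP <- crossprod(Dfull)

  if (identical(lambda, "auto")) {
    lambda <- select_lambda(C, y, CtC, Cty, PtP, Dfull,
                            n_unpenalized = spec$penalty_order + ncol(X),
                            method = method)
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop_config("lambda must be a non-negative number or \"auto\"", field = "lambda")

  # Final solve: augmented QR, stable at any lambda.
  if (lambda > 0) {
    Caug <- rbind(C, sqrt(lambda) * Dfull)
    yaug <- c(y, numeric(nrow(Dfull)))
  } else {
    Caug <- C; yaug <- y
  }
  qf <- qr(Caug)
  theta <- qr.coef(qf, yaug)
  theta[is.na(theta)] <- 0
  fitted <- drop(C %*% theta)
  rss <- sum((y - fitted)^2)

  # Diagnostics via the normal-equation factorization.
  Rc <- chol_safe(CtC + lambda * PtP)
  Ainv <- chol2inv(Rc)
  edf_j <- diag(Ainv %*% CtC)
  edf_total <- sum(edf_j)
  edf_smooth <- sum(edf_j[seq_len(pB)])
  n <- length(y)
  sigma2 <- rss / max(n - edf_total, 1)
  Vcoef <- sigma2 * (Ainv %*% CtC %*% Ainv)

  term_tests <- NULL
  beta <- numeric(0)
  if (ncol(X)) {
    idx <- pB + seq_len(ncol(X))
    beta <- stats::setNames(theta[idx], colnames(X))
    se <- sqrt(pmax(diag(Vcoef)[idx], 0))
    tstat <- beta / se
    pval <- 2 * stats::pt(-abs(tstat), df = max(n - edf_total, 1))
    term_tests <- data.frame(term = colnames(X), estimate = beta, se = se,
                             t = tstat, p = pval, row.names = NULL)
  }

  # Whole-smooth F test: penalized model vs covariates-only model.
  X0 <- cbind(intercept = 1, X)
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  df_num <- max(edf_total - ncol(X0), 0.5)
  fstat <- ((rss0 - rss) / df_num) / sigma2
  f_p <- stats::pf(fstat, df_num, max(n - edf_total, 1), lower.tail = FALSE)

  grid <- seq(spec$age_domain[1], spec$age_domain[2], by = grid_step)
  Bg <- build_basis(spec, grid)
  Vb <- Vcoef[seq_len(pB), seq_len(pB)]
  curve <- drop(Bg %*% theta[seq_len(pB)])
  curve_se <- sqrt(pmax(rowSums((Bg %*% Vb) * Bg), 0))

  structure(list(
    basis = spec, knots = spec_knots(spec, ages),
    spline_coefficients = theta[seq_len(pB)],
    covariate_coefficients = beta,
    lambda = lambda, method = method,
    edf = edf_smooth, edf_total = edf_total,
    residual_sd = sqrt(sigma2),
    fitted_grid = data.frame(age = grid, fit = curve, se = curve_se),
    smooth_f = c(F = fstat, p = f_p),
    term_tests = term_tests,
    n = n, n_dropped = n_dropped, rss = rss,
    outcome = outcome, covariates = covariates,
    center = center
  ), class = "pspline_fit")
}

#' Evaluate a fitted P-spline trajectory at new ages
#'
#' @param object a `pspline_fit`.
#' @param ages ages (years) within the basis domain.
#' @param ... unused.
#' @return fitted reference-subject values at `ages`.
#' @export
predict.pspline_fit <- function(object, ages, ...) {
  Bg <- build_basis(object$basis, ages)
  drop(Bg %*% object$spline_coefficients)
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat(sprintf("P-spline fit of %s: n = %d, lambda = %.4g (%s), edf(smooth) = %.2f, sigma = %.3g\n",
              x$outcome, x$n, x$lambda, x$method, x$edf, x$residual_sd))
  cat(sprintf("  smooth F = %.3g (p = %.3g)\n", x$smooth_f["F"], x$smooth_f["p"]))
  if (!is.null(x$term_tests)) {
    cat("  linear terms:\n")
    print(format(x$term_tests, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Test the age-by-BMI interaction on a smooth age trajectory
#'
#' Augments the penalized age smooth with mean-centered linear BMI and
#' age-by-BMI product terms (both unpenalized) and returns the interaction
#' coefficient's t statistic with a two-sided p value on `n - edf_total`
#' residual degrees of freedom. A negative t means heavier subjects lose the
#' outcome faster with age (trajectory modulation by adiposity).
#'
#' @param cohort a `cohort` with `age` and `bmi` columns.
#' @param outcome outcome column name.
#' @param covariates additional linear covariates (see [fit_pspline()]).
#' @param spec a [basis_spec()] or `NULL` for the default.
#' @param bmi_coding `"continuous"` (default) uses centered BMI;
#'   `"group"` uses a lean vs overweight/obese indicator.
#' @param method smoothing selection criterion.
#' @return list with `t`, `p`, and the underlying `fit`.
#' @export
test_interaction <- function(cohort, outcome = "wm_volume",
                             covariates = c("sex", "icv"), spec = NULL,
                             bmi_coding = c("continuous", "group"),
                             method = "GCV") {
  bmi_coding <- match.arg(bmi_coding)
  dat <- as.data.frame(cohort)
  if (!"bmi" %in% names(dat)) stop_input("cohort has no bmi column")
  bmi_term <- if (bmi_coding == "continuous") dat$bmi else
    as.numeric(classify_bmi(dat$bmi) %in% c("overweight", "obese"))
  age_c <- dat$age - mean(dat$age)
  bmi_c <- bmi_term - mean(bmi_term)
  fit <- fit_pspline(dat, outcome, covariates, spec = spec, method = method,
                     extra = list(bmi = bmi_c, age_x_bmi = age_c * bmi_c))
  tt <- fit$term_tests
  row <- tt[tt$term == "age_x_bmi", ]
  list(t = row$t, p = row$p, fit = fit)
}

#' Fit lean and overweight/obese trajectories on a common age grid
#'
#' Splits the cohort into lean (BMI in [18.5, 25)) and overweight/obese
#' (BMI >= 25) groups, fits an independent penalized spline to each, and
#' evaluates both on a shared age grid restricted to the ages covered by both
#' groups. Covariates are centered at pooled-cohort reference values (means;
#' sex at 1/2) so the two curves are directly comparable.
#'
#' @param cohort a `cohort`.
#' @param outcome outcome column (default white-matter volume).
#' @param covariates linear covariates for both fits.
#' @param spec a [basis_spec()] (shared by both groups; default spans the
#'   pooled age range).
#' @param grid_step grid spacing, years (default 0.1).
#' @param min_group,min_span support requirements: each group needs at least
#'   `min_group` subjects spanning at least `min_span` years.
#' @param method smoothing selection criterion.
#' @return a `trajectory_pair`: shared `age_grid`, `lean_curve`, `ow_curve`,
#'   pointwise standard errors, peak ages, and the two `pspline_fit`s.
#' @export
fit_group_trajectories <- function(cohort, outcome = "wm_volume",
                                   covariates = c("sex", "icv"),
                                   spec = NULL, grid_step = 0.1,
                                   min_group = 30, min_span = 40,
                                   method = "GCV") {
  dat <- as.data.frame(cohort)
  grp <- classify_bmi(dat$bmi)
  lean <- dat[grp == "lean", , drop = FALSE]
  heavy <- dat[grp %in% c("overweight", "obese"), , drop = FALSE]
  span <- function(d) diff(range(d$age))
  if (nrow(lean) < min_group || nrow(heavy) < min_group ||
      span(lean) < min_span || span(heavy) < min_span) {
    stop_support(sprintf(
      "insufficient group support: lean n = %d over %.1f y, overweight/obese n = %d over %.1f y",
      nrow(lean), span(lean), nrow(heavy), span(heavy)))
  }
  spec <- spec %||% basis_spec()
  if (is.null(spec$age_domain)) spec$age_domain <- range(dat$age)

  center <- list(sex = 0.5)
  for (nm in setdiff(covariates, "sex"))
    center[[nm]] <- mean(as.numeric(dat[[nm]]), na.rm = TRUE)

  fit_lean <- fit_pspline(lean, outcome, covariates, spec = spec,
                          center = center, method = method, grid_step = grid_step)
  fit_ow <- fit_pspline(heavy, outcome, covariates, spec = spec,
                        center = center, method = method, grid_step = grid_step)

  lo <- max(min(lean$age), min(heavy$age))
  hi <- min(max(lean$age), max(heavy$age))
  grid <- seq(lo, hi, by = grid_step)
  Bg <- build_basis(spec, grid)
  eval_fit <- function(f) drop(Bg %*% f$spline_coefficients)
  interp_se <- function(f) stats::approx(f$fitted_grid$age, f$fitted_grid$se,
                                         xout = grid, rule = 2)$y
  lean_curve <- eval_fit(fit_lean)
  ow_curve <- eval_fit(fit_ow)
  structure(list(
    age_grid = grid,
    lean_curve = lean_curve, ow_curve = ow_curve,
    lean_se = interp_se(fit_lean), ow_se = interp_se(fit_ow),
    lean_peak_age = find_peak(lean_curve, grid),
    ow_peak_age = find_peak(ow_curve, grid),
    fits = list(lean = fit_lean, ow = fit_ow),
    outcome = outcome
  ), class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf("Group trajectories of %s on ages %.1f-%.1f (step %.2g)\n",
              x$outcome, min(x$age_grid), max(x$age_grid),
              x$age_grid[2] - x$age_grid[1]))
  cat(sprintf("  lean peak at %.1f y; overweight/obese peak at %.1f y\n",
              x$lean_peak_age, x$ow_peak_age))
  invisible(x)
}
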