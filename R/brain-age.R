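#' Age of the trajectory maximum
#'
#' Global maximum of an inverted-U curve on an ascending age grid, with ties
#' broken toward the youngest age.
#'
#' @param curve numeric vector of outcome values on `age_grid`.
#' @param age_grid ascending numeric vector of ages (length >= 3).
#' @return the peak age, years.
#' @export
find_peak <- function(curve, age_grid) {
  if (length(age_grid) < 3 || is.unsorted(age_grid))
    stop_input("age_grid must be ascending with length >= 3")
  if (length(curve) != length(age_grid))
    stop_input("curve and age_grid lengths differ")
  if (diff(range(curve)) == 0)
    stop_degenerate("flat trajectory: no identifiable peak")
  age_grid[which.max(curve)]
}

# Vectorized inversion of the descending limb. Returns a list with matched
# ages and status codes: 0 found, 1 volume above the value at peak,
# 2 volume below the limb minimum (no one old enough).
invert_desc_core <- function(curve, age_grid, peak_age, volumes, warn = TRUE) {
  i0 <- which(age_grid >= peak_age - 1e-9)[1]
  ages_d <- age_grid[i0:length(age_grid)]
  curve_d <- curve[i0:length(curve)]
  tol <- 1e-6 * max(diff(range(curve)), 1)
  if (any(diff(curve_d) > tol) && warn)
    warning("descending limb re-increases; using first crossing from the peak",
            call. = FALSE)
  mono <- cummin(curve_d)              # first-crossing semantics
  status <- integer(length(volumes))
  status[volumes > curve_d[1] + 1e-12] <- 1L
  status[volumes < mono[length(mono)] - 1e-12] <- 2L
  ages <- rep(NA_real_, length(volumes))
  ok <- status == 0L
  if (any(ok)) {
    v <- volumes[ok]
    m <- length(mono)
    # mono is non-increasing, so {i : mono[i] <= v} is a suffix; its size is
    # the number of elements of rev(mono) (ascending) that are <= v.
    cnt <- findInterval(v, rev(mono))
    idx <- pmin(pmax(m - cnt + 1L, 1L), m)   # first crossing index
    a <- ages_d[idx]
    prev <- idx > 1
    if (any(prev)) {
      i <- idx[prev]
      c1 <- mono[i - 1]; c2 <- mono[i]
      w <- ifelse(c1 - c2 > 0, pmin(pmax((c1 - v[prev]) / (c1 - c2), 0), 1), 1)
      a[prev] <- ages_d[i - 1] + w * (ages_d[i] - ages_d[i - 1])
    }
    ages[ok] <- a
  }
  list(age = ages, status = status)
}

#' Invert the descending limb of a trajectory at a target volume
#'
#' Restricted to ages at or beyond the peak (the descending limb), finds the
#' age at which the curve crosses the target volume by bracketing adjacent
#' grid points and interpolating linearly. Returns `NA` ("not found") when
#' the volume lies above the value at the peak or below the limb minimum.
#' A locally re-increasing limb triggers a warning and first-crossing
#' semantics.
#'
#' @param curve,age_grid trajectory values on an ascending age grid.
#' @param peak_age age of the trajectory maximum (see [find_peak()]).
#' @param volume target volume (scalar, same units as `curve`).
#' @return matched age in years, or `NA_real_` if not found.
#' @export
invert_descending <- function(curve, age_grid, peak_age, volume) {
  if (!is.finite(volume)) stop_input("volume must be finite")
  if (peak_age < age_grid[1] - 1e-9 || peak_age > age_grid[length(age_grid)] + 1e-9)
    stop_input("peak_age outside the age grid")
  invert_desc_core(curve, age_grid, peak_age, volume)$age
}

# Shared point-estimate computation; returns delta and per-age rule flags for
# the overweight/obese reference ages in eval_ages.
brain_age_delta <- function(lean_curve, ow_curve, age_grid, lean_peak, ow_peak,
                            eval_ages, clamp_negative = TRUE, warn = FALSE) {
  idx <- match(round(eval_ages, 6), round(age_grid, 6))
  v <- ow_curve[idx]
  descending <- eval_ages >= ow_peak - 1e-9
  delta <- rep(NA_real_, length(eval_ages))
  clamped <- truncated <- rep(FALSE, length(eval_ages))
  if (any(descending)) {
    inv <- invert_desc_core(lean_curve, age_grid, lean_peak, v[descending],
                            warn = warn)
    a_lean <- inv$age
    # Volume above the lean value at its peak: the heavier group holds more
    # volume than any age-matched lean reference; treat as rule 2.
    a_lean[inv$status == 1L] <- lean_peak
    # Rule 3: no lean subject old enough; truncate at the oldest grid age.
    a_lean[inv$status == 2L] <- age_grid[length(age_grid)]
    d <- a_lean - eval_ages[descending]
    cl <- rep(FALSE, length(d))
    if (clamp_negative) {
      cl <- d < 0
      d[cl] <- 0
    }
    delta[descending] <- d
    clamped[descending] <- cl
    truncated[descending] <- inv$status == 2L
  }
  list(delta = delta, descending_only = !descending,
       clamped_zero = clamped, truncated_support = truncated)
}

#' Brain-age difference curve at matched white-matter volume
#'
#' For each overweight/obese reference age on the descending limb of the
#' overweight/obese trajectory, matches its fitted volume on the descending
#' limb of the lean trajectory and reports `delta = lean age at matched
#' volume - overweight/obese age` (positive: the heavier group's brain looks
#' older). Three constraint rules are applied: (1) matching is restricted to
#' the descending limbs, so maturational increase is never compared with
#' decline; (2) if the heavier group's volume exceeds the age-matched lean
#' volume (negative delta), delta is set to zero; (3) if no lean reference is
#' old enough to reach the volume, the lean age is truncated at the oldest
#' grid age. Applied rules are flagged per age.
#'
#' @param pair a `trajectory_pair` from [fit_group_trajectories()] (or built
#'   directly from two curves on a shared grid).
#' @param eval_range (low, high) overweight/obese reference ages, years;
#'   default 37-87, the restriction used with the inverted-U trajectory.
#' @param clamp_negative apply rule 2? (`FALSE` exposes negative deltas.)
#' @return a `brain_age_curve`: data.frame with `age`, `delta` and logical
#'   flag columns `descending_only`, `clamped_zero`, `truncated_support`.
#' @export
age_difference_curve <- function(pair, eval_range = c(37, 87),
                                 clamp_negative = TRUE) {
  grid <- pair$age_grid
  keep <- grid >= eval_range[1] - 1e-9 & grid <= eval_range[2] + 1e-9
  if (!any(keep))
    stop_support("eval_range lies outside the trajectory grid support")
  eval_ages <- grid[keep]
  res <- brain_age_delta(pair$lean_curve, pair$ow_curve, grid,
                         pair$lean_peak_age, pair$ow_peak_age,
                         eval_ages, clamp_negative, warn = TRUE)
  out <- data.frame(age = eval_ages, delta = res$delta,
                    descending_only = res$descending_only,
                    clamped_zero = res$clamped_zero,
                    truncated_support = res$truncated_support)
  structure(out, class = c("brain_age_curve", "data.frame"),
            eval_range = eval_range, clamp_negative = clamp_negative,
            pair = pair)
}

#' Bootstrap confidence bands for the brain-age difference curve
#'
#' Resamples subjects with replacement (within each weight group by default,
#' preserving group sizes), refits both group trajectories, and recomputes
#' the constrained brain-age difference curve in every iteration; rules 1-3
#' are applied inside each iteration. Confidence bands are elementwise
#' percentile intervals of the bootstrap deltas; the point estimate is the
#' full-sample curve. Iterations whose resample lacks descending-limb support
#' at an age contribute "not found" there; ages with fewer than 50% valid
#' iterations have their CI marked unavailable.
#'
#' @param cohort a preprocessed `cohort` (both groups non-empty).
#' @param outcome outcome column, default `wm_volume`.
#' @param covariates linear covariates for the group fits.
#' @param spec a [basis_spec()] or `NULL`.
#' @param eval_range overweight/obese reference age window (default 37-87).
#' @param n_iter bootstrap iterations (default 10000).
#' @param levels confidence levels (default 0.90 and 0.95).
#' @param seed integer seed; identical seeds give identical bands.
#' @param resample `"within"` (per-group, default) or `"pooled"`.
#' @param grid_step trajectory grid spacing, years.
#' @param clamp_negative apply rule 2 inside each iteration (and to the
#'   point estimate).
#' @param method smoothing selection criterion for every refit.
#' @return a `brain_age_curve` with CI columns `ci90_lo/ci90_hi`,
#'   `ci95_lo/ci95_hi` (per requested level), `n_valid`, and attributes
#'   `n_iter`, `seed`, `levels`.
#' @export
bootstrap_brain_age <- function(cohort, outcome = "wm_volume",
                                covariates = c("sex", "icv"), spec = NULL,
                                eval_range = c(37, 87), n_iter = 10000,
                                levels = c(0.90, 0.95), seed = 1,
                                resample = c("within", "pooled"),
                                grid_step = 0.1, clamp_negative = TRUE,
                                method = "GCV") {
  resample <- match.arg(resample)
  pair <- fit_group_trajectories(cohort, outcome, covariates, spec = spec,
                                 grid_step = grid_step, method = method)
  point <- age_difference_curve(pair, eval_range, clamp_negative)
  eval_ages <- point$age
  grid <- pair$age_grid

  # Precompute full-sample design objects once; bootstrap rows are indexed.
  spec_used <- pair$fits$lean$basis
  dat <- as.data.frame(cohort)
  grp <- classify_bmi(dat$bmi)
  dat <- dat[grp != "underweight", , drop = FALSE]
  grp <- grp[grp != "underweight"]
  heavy <- grp %in% c("overweight", "obese")
  center <- pair$fits$lean$center
  Ball <- build_basis(spec_used, dat$age)
  Xall <- NULL
  if (length(covariates)) {
    Xall <- sapply(covariates, function(nm) {
      if (nm == "sex") as.numeric(dat[[nm]] == "male") - center[["sex"]]
      else as.numeric(dat[[nm]]) - center[[nm]]
    })
  }
  Call <- if (is.null(Xall)) Ball else cbind(Ball, Xall)
  yall <- dat[[outcome]]
  pB <- ncol(Ball)
  D <- diff(diag(pB), differences = spec_used$penalty_order)
  Dfull <- cbind(D, matrix(0, nrow(D), ncol(Call) - pB))
  PtP <- crossprod(Dfull)
  Bg <- build_basis(spec_used, grid)
  n_unpen <- spec_used$penalty_order + ncol(Call) - pB
  idx_lean <- which(!heavy); idx_heavy <- which(heavy)

  refit_curve <- function(rows) {
    C <- Call[rows, , drop = FALSE]
    y <- yall[rows]
    CtC <- crossprod(C); Cty <- crossprod(C, y)
    lam <- select_lambda(C, y, CtC, Cty, PtP, Dfull, n_unpen, method = method)
    th <- pen_core(C, y, CtC, Cty, PtP, lam, need_edf = FALSE)$theta
    drop(Bg %*% th[seq_len(pB)])
  }

  set.seed(seed)
  deltas <- matrix(NA_real_, n_iter, length(eval_ages))
  for (b in seq_len(n_iter)) {
    if (resample == "within") {
      rl <- sample(idx_lean, replace = TRUE)
      rh <- sample(idx_heavy, replace = TRUE)
    } else {
      all_rows <- sample(nrow(dat), replace = TRUE)
      rl <- all_rows[!heavy[all_rows]]
      rh <- all_rows[heavy[all_rows]]
      if (!length(rl) || !length(rh)) next
    }
    cl <- tryCatch(refit_curve(rl), error = function(e) NULL)
    ch <- tryCatch(refit_curve(rh), error = function(e) NULL)
    if (is.null(cl) || is.null(ch)) next
    pl <- tryCatch(find_peak(cl, grid), error = function(e) NA_real_)
    ph <- tryCatch(find_peak(ch, grid), error = function(e) NA_real_)
    if (is.na(pl) || is.na(ph)) next
    res <- brain_age_delta(cl, ch, grid, pl, ph, eval_ages, clamp_negative)
    deltas[b, ] <- res$delta
  }

  n_valid <- colSums(!is.na(deltas))
  ci_ok <- n_valid >= n_iter / 2
  out <- as.data.frame(point)
  for (lv in levels) {
    a <- (1 - lv) / 2
    qs <- apply(deltas, 2, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) c(NA_real_, NA_real_) else
        stats::quantile(col, c(a, 1 - a), names = FALSE, type = 7)
    })
    lo <- qs[1, ]; hi <- qs[2, ]
    lo[!ci_ok] <- NA_real_; hi[!ci_ok] <- NA_real_
    tag <- sprintf("ci%02d", round(lv * 100))
    out[[paste0(tag, "_lo")]] <- lo
    out[[paste0(tag, "_hi")]] <- hi
  }
  out$n_valid <- n_valid
  structure(out, class = c("brain_age_curve", "data.frame"),
            eval_range = eval_range, clamp_negative = clamp_negative,
            n_iter = n_iter, seed = seed, levels = levels,
            resample = resample, pair = pair)
}

#' Summarize a brain-age difference curve
#'
#' Mean delta over valid (descending, non-truncated) evaluation ages, the
#' maximum delta and the age at which it occurs (ties to the youngest age).
#'
#' @param curve a `brain_age_curve`.
#' @return list with `mean_delta`, `max_delta`, `age_at_max` (years).
#' @export
summarize_brain_age <- function(curve) {
  valid <- !is.na(curve$delta) & !curve$truncated_support
  if (!any(valid)) stop_summary("no valid evaluation ages in the curve")
  d <- curve$delta[valid]; a <- curve$age[valid]
  i <- which.max(d)
  list(mean_delta = mean(d), max_delta = d[i], age_at_max = a[i])
}

#' Serialize a brain-age curve to CSV (+ JSON metadata)
#'
#' Writes `age, delta, ci90_lo, ci90_hi, ci95_lo, ci95_hi, flags` rows and,
#' when present, a `<path>.json` with iteration count, seed, evaluation
#' window and rule toggles.
#'
#' @param curve a `brain_age_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_brain_age_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  flags <- apply(df[, c("descending_only", "clamped_zero", "truncated_support")],
                 1, function(r) paste(c("descending_only", "clamped_zero",
                                        "truncated_support")[as.logical(r)],
                                      collapse = "|"))
  keep <- intersect(c("age", "delta", "ci90_lo", "ci90_hi", "ci95_lo", "ci95_hi"),
                    names(df))
  out <- cbind(df[, keep, drop = FALSE], flags = flags)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  meta <- list(n_iter = attr(curve, "n_iter"), seed = attr(curve, "seed"),
               eval_range = attr(curve, "eval_range"),
               clamp_negative = attr(curve, "clamp_negative"),
               levels = attr(curve, "levels"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.brain_age_curve <- function(x, ...) {
  s <- tryCatch(summarize_brain_age(x), error = function(e) NULL)
  cat(sprintf("Brain-age difference curve over %.0f-%.0f y (%d ages)\n",
              attr(x, "eval_range")[1], attr(x, "eval_range")[2], nrow(x)))
  if (!is.null(s))
    cat(sprintf("  mean delta %.2f y; max %.2f y at %.1f y\n",
                s$mean_delta, s$max_delta, s$age_at_max))
  if (!is.null(attr(x, "n_iter")))
    cat(sprintf("  bootstrap: %d iterations, seed %d\n",
                attr(x, "n_iter"), attr(x, "seed")))
  invisible(x)
}
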