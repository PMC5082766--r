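test_that("find_peak locates maxima with youngest-age tie-breaking", {
  grid <- seq(20, 87, by = 0.5)
  expect_equal(find_peak(-(grid - 40)^2, grid), 40)
  expect_equal(find_peak(rev(seq_along(grid)), grid), 20)  # strictly decreasing
  two <- -pmin(abs(grid - 38), abs(grid - 42))^2           # equal maxima at 38 and 42
  expect_equal(find_peak(two, grid), 38)
  expect_error(find_peak(rep(1, length(grid)), grid),
               class = "adipoage_degenerate_error")
})

test_that("descending-limb inversion brackets and interpolates correctly", {
  grid <- seq(20, 87, by = 0.1)
  line <- 100 - grid
  expect_equal(invert_descending(line, grid, 20, 40), 60)
  quad <- 465 - 0.07 * (grid - 43)^2
  expect_equal(invert_descending(quad, grid, 43, 465), 43)   # value at peak
  expect_true(is.na(invert_descending(quad, grid, 43, min(quad) - 5)))
  # inversion of the quadratic on a 0.1-y grid is accurate to ~1e-4 years
  a445 <- 43 + sqrt((465 - 445) / 0.07)   # exact descending-limb solution
  expect_equal(invert_descending(quad, grid, 43, 445), a445, tolerance = 1e-3)
  # ascending-limb solutions are never returned
  expect_gt(invert_descending(quad, grid, 43, 445), 43)
  wig <- quad; wig[500] <- wig[500] + 1   # local re-increase
  expect_warning(invert_descending(wig, grid, 43, 445), "re-increase")
})

test_that("anchored group curves reproduce the ten-year worked example", {
  pair <- quad_pair(shift = 10, peak = 43, peak_vol = 445 + 0.07 * 17^2,
                    curv = 0.07)
  # overweight/obese curve passes 445 cm^3 at 50 y, lean at 60 y
  expect_equal(pair$ow_curve[match(50, round(pair$age_grid, 6))], 445)
  expect_equal(pair$lean_curve[match(60, round(pair$age_grid, 6))], 445)
  cur <- age_difference_curve(pair, c(37, 87))
  expect_equal(cur$delta[cur$age == 50], 10, tolerance = 1e-8)
})

test_that("identical curves give zero delta everywhere", {
  pair <- quad_pair(shift = 0)
  cur <- age_difference_curve(pair, c(37, 87))
  ok <- !cur$descending_only
  expect_true(all(abs(cur$delta[ok]) < 1e-9))
})

test_that("an exact shift is recovered everywhere both limbs overlap", {
  pair <- quad_pair(shift = 7)
  cur <- age_difference_curve(pair, c(37, 87))
  ok <- !cur$descending_only & !cur$truncated_support
  expect_true(all(abs(cur$delta[ok] - 7) < 0.1))        # one grid step
  expect_true(all(cur$truncated_support[cur$age > 80])) # no lean old enough
  td <- cur$delta[cur$truncated_support]
  expect_true(all(td >= 0 & td < 7 + 0.1))
})

test_that("rule 2 clamps negative deltas to zero and can be toggled off", {
  pair <- quad_pair(shift = -6)   # heavier group *larger* than lean
  cur <- age_difference_curve(pair, c(45, 80))
  ok <- !cur$descending_only
  expect_true(all(cur$delta[ok] >= 0))
  expect_true(any(cur$clamped_zero[ok]))
  raw <- age_difference_curve(pair, c(45, 80), clamp_negative = FALSE)
  expect_true(any(raw$delta[!raw$descending_only] < 0))
})

test_that("halving the grid step changes delta by less than the prior step", {
  for (step in c(0.2, 0.1)) {
    p1 <- quad_pair(shift = 10, grid = seq(20, 87, by = step))
    p2 <- quad_pair(shift = 10, grid = seq(20, 87, by = step / 2))
    c1 <- age_difference_curve(p1, c(45, 75))
    c2 <- age_difference_curve(p2, c(45, 75))
    shared <- intersect(round(c1$age, 6), round(c2$age, 6))
    d1 <- c1$delta[match(shared, round(c1$age, 6))]
    d2 <- c2$delta[match(shared, round(c2$age, 6))]
    expect_lt(max(abs(d1 - d2)), step)
  }
})

test_that("curve summaries report mean, maximum and its age", {
  pair <- quad_pair(shift = 7)
  cur <- age_difference_curve(pair, c(45, 75))
  s <- summarize_brain_age(cur)
  expect_equal(s$mean_delta, 7, tolerance = 0.1)
  one <- cur[5, , drop = FALSE]
  s1 <- summarize_brain_age(one)
  expect_equal(s1$mean_delta, one$delta)
  expect_equal(s1$age_at_max, one$age)
  const <- cur; const$delta <- 7; const$truncated_support <- FALSE
  sc <- summarize_brain_age(const)
  expect_equal(sc$max_delta, 7)
  expect_equal(sc$age_at_max, min(const$age))
  empty <- cur; empty$delta <- NA_real_
  expect_error(summarize_brain_age(empty), class = "adipoage_summary_error")
})
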