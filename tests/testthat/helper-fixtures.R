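# Shared fixtures: small deterministic datasets built in code.

# A trajectory_pair built from exact shifted concave quadratics, peak at
# `peak` with curvature `curv`; the overweight/obese curve is the lean curve
# shifted left by `shift` years.
quad_pair <- function(shift = 10, peak = 43, peak_vol = 465, curv = 0.07,
                      grid = seq(20, 87, by = 0.1)) {
  lean <- peak_vol - curv * (grid - peak)^2
  ow <- peak_vol - curv * (grid + shift - peak)^2
  structure(list(age_grid = grid, lean_curve = lean, ow_curve = ow,
                 lean_peak_age = find_peak(lean, grid),
                 ow_peak_age = find_peak(ow, grid)),
            class = "trajectory_pair")
}

# Small regression dataset with a linear age trend.
linear_data <- function(n = 200, seed = 42, sd = 5) {
  set.seed(seed)
  age <- runif(n, 20, 87)
  data.frame(age = age, y = 400 + 0.5 * age + rnorm(n, 0, sd))
}
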