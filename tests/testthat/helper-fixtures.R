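# Shared fixtures: a minimal two-band scenario with simple closed forms, and
# a relative-error expectation used throughout.

expect_rel <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g of %s",
                              paste(signif(actual, 4), collapse = ","), tol,
                              paste(signif(expected, 4), collapse = ",")))
}

# two bands covering months 4-24 (5 + 16 months), deterministic-friendly
tiny_scenario <- function(n_iterations = 1000, seed = 99) {
  as_scenario(
    concentrations = list(
      water = dist_uniform(0, 0.010),
      formula = dist_point(8e-6),
      rice_cereal = dist_triangular(2e-5, 9e-5, 3e-4),
      other_solid = dist_normal(5e-6, 5e-6, truncate_at_zero = TRUE)),
    bands = list(
      age_band("4-8", 4:8, dist_normal(7, 0.8), dist_triangular(0, 0.2, 0.9),
               serving_spec(dist_normal(20, 10, truncate_at_zero = TRUE), c(3, 4)),
               dist_normal(15, 16, truncate_at_zero = TRUE),
               v_fr = serving_spec(dist_normal(60, 70, truncate_at_zero = TRUE),
                                   c(1, 2))),
      age_band("9-24", 9:24, dist_normal(10, 1.2), dist_triangular(0, 0.2, 0.6),
               serving_spec(dist_normal(24, 20, truncate_at_zero = TRUE), c(3, 4)),
               dist_normal(45, 70, truncate_at_zero = TRUE),
               v_fr = serving_spec(dist_normal(100, 100, truncate_at_zero = TRUE),
                                   c(1, 2)),
               v_m = serving_spec(dist_normal(30, 35, truncate_at_zero = TRUE),
                                  c(1, 2)))),
    tox = list(mrl_acute = 5e-3, mrl_chronic = 3e-4, csf = 1.5,
               mcl_w = 0.010, ed_days = 620, at_days = 25550),
    n_iterations = n_iterations, seed = seed)
}

# triangular CDF, for distributional checks
ptri <- function(q, a, b, c) {
  ifelse(q <= a, 0,
  ifelse(q >= c, 1,
  ifelse(q <= b, (q - a)^2 / ((c - a) * (b - a)),
         1 - (c - q)^2 / ((c - a) * (c - b)))))
}
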