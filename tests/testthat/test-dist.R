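test_that("distribution specs enforce family invariants", {
  expect_error(dist_uniform(1, 0), "low > high")
  expect_error(dist_normal(0, -1), "sd < 0")
  expect_error(dist_triangular(2, 1, 3), "a <= b <= c")
  expect_error(dist_triangular(1, 1, 2, interpretation = "p10_p50_p90"),
               "strictly increasing")
  expect_silent(validate_dist_spec(dist_triangular(1, 1, 2)))
  expect_error(dist_normal(0, Inf), "finite")
})

test_that("point masses return the constant and centrals are family-correct", {
  expect_equal(dist_sample(dist_point(5), 3), c(5, 5, 5))
  expect_equal(dist_central(dist_uniform(0, 0.010)), 0.005)
  expect_equal(dist_central(dist_normal(14.3, 16.1)), 14.3)
  expect_equal(dist_central(dist_triangular(2.30e-5, 9.10e-5, 2.83e-4)), 9.10e-5)
})

test_that("clamp-at-zero reproduces the normal left-tail mass as exact zeros", {
  s <- rng_stream(11)
  x <- dist_sample(dist_normal(14.3, 16.1, truncate_at_zero = TRUE), 1e6, s, "rc")
  expect_true(all(x >= 0))
  # P(N(14.3, 16.1) < 0) = pnorm(-14.3/16.1) = 0.1872
  expect_lt(abs(mean(x == 0) - pnorm(-14.3 / 16.1)), 0.002)
})

test_that("untruncated families match their textbook CDFs (KS at n = 1e5)", {
  s <- rng_stream(12)
  u <- dist_sample(dist_uniform(0, 0.010), 1e5, s, "u")
  expect_gt(suppressWarnings(ks.test(u, punif, 0, 0.010))$p.value, 0.01)
  z <- dist_sample(dist_normal(3, 2), 1e5, s, "z")
  expect_gt(suppressWarnings(ks.test(z, pnorm, 3, 2))$p.value, 0.01)
  tr <- dist_sample(dist_triangular(2.30e-5, 9.10e-5, 2.83e-4), 1e5, s, "t")
  expect_gt(suppressWarnings(
    ks.test(tr, ptri, 2.30e-5, 9.10e-5, 2.83e-4))$p.value, 0.01)
  # uniform mean within 3 MC standard errors
  expect_lt(abs(mean(u) - 0.005), 3 * 0.010 / sqrt(12) / sqrt(1e5))
})

test_that("triangular quantiles follow the closed-form inverse CDF", {
  expect_equal(triangular_quantile(0.5, 0, 1, 2), 1.0)
  expect_equal(triangular_quantile(0.1, 0, 1, 2), sqrt(0.2))
  # right-segment inverse at the rice-cereal parameters:
  # c - sqrt(0.5 (c-a)(c-b)) = 1.2501e-4
  expect_equal(triangular_quantile(0.5, 2.30e-5, 9.10e-5, 2.83e-4),
               2.83e-4 - sqrt(0.5 * (2.83e-4 - 2.30e-5) * (2.83e-4 - 9.10e-5)),
               tolerance = 1e-12)
  expect_equal(round(triangular_quantile(0.5, 2.30e-5, 9.10e-5, 2.83e-4), 7),
               1.25e-4)
  expect_equal(triangular_quantile(c(0, 1), 1, 2, 4), c(1, 4))
  # empirical quantiles of a large sample agree with the closed form
  s <- rng_stream(13)
  x <- dist_sample(dist_triangular(0, 1, 2), 1e5, s, "tq")
  for (p in c(0.1, 0.25, 0.5, 0.9)) {
    q <- triangular_quantile(p, 0, 1, 2)
    dens <- if (q <= 1) q else 2 - q  # triangular density at q (h = 1)
    se <- sqrt(p * (1 - p) / 1e5) / dens
    expect_lt(abs(quantile(x, p) - q), 3 * se)
  }
})

test_that("triangular percentile fitting inverts the forward quantiles", {
  fit <- fit_triangular_from_percentiles(sqrt(0.2), 1, 2 - sqrt(0.2))
  expect_equal(c(fit$a, fit$b, fit$c), c(0, 1, 2), tolerance = 1e-6)
  expect_true(fit$feasible_nonneg)
  expect_lt(fit$residual, 1e-9)
  # a symmetric percentile triple recovers a symmetric triangular
  q <- triangular_quantile(c(0.1, 0.5, 0.9), -2, 0, 2)
  fit <- fit_triangular_from_percentiles(q[1], q[2], q[3])
  expect_equal(fit$a, -fit$c, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  # p10 = 0 is unattainable for a continuous triangular with a >= 0, and a
  # triplet this right-skewed matches no triangular at all: the fit reports
  # infeasibility and anchors p10/p90 with the p50 miss in the residual
  fit <- fit_triangular_from_percentiles(0, 0.148, 0.924)
  expect_false(fit$feasible)
  expect_false(fit$feasible_nonneg)
  expect_lt(fit$a, 0)
  expect_gt(fit$residual, 0.1)
  expect_equal(triangular_quantile(c(0.1, 0.9), fit$a, fit$b, fit$c),
               c(0, 0.924), tolerance = 1e-6)
  expect_error(fit_triangular_from_percentiles(1, 1, 2), "strictly increasing")
})

test_that("percentile-interpreted triangular specs sample with a clamped tail", {
  # feasible triple: the forward 10/50/90 quantiles of Tri(0, 1, 2)
  spec <- dist_triangular(sqrt(0.2), 1, 2 - sqrt(0.2),
                          interpretation = "p10_p50_p90")
  s <- rng_stream(14)
  x <- dist_sample(spec, 1e5, s, "ok")
  expect_lt(abs(quantile(x, 0.5) - 1), 0.02)
  expect_lt(abs(quantile(x, 0.1) - sqrt(0.2)), 0.02)
  # infeasible water-style triplet: the clamped fallback reproduces the
  # labelled p10 = 0 as an atom at zero and anchors p90
  spec0 <- dist_triangular(0, 0.148, 0.924, interpretation = "p10_p50_p90")
  y <- dist_sample(spec0, 1e5, s, "vw")
  expect_true(all(y >= 0))
  expect_lt(abs(mean(y == 0) - 0.10), 0.01)
  expect_lt(abs(quantile(y, 0.9) - 0.924), 0.02)
})

test_that("serving counts are discrete uniform on the configured range", {
  s <- rng_stream(15)
  expect_true(all(sample_serving_count(c(2, 2), 100, s, "a") == 2))
  x <- sample_serving_count(c(1, 2), 1e5, s, "b")
  expect_true(all(x %in% c(1, 2)))
  expect_lt(abs(mean(x) - 1.5), 3 * 0.5 / sqrt(1e5))
  y <- sample_serving_count(c(3, 4), 1e5, s, "c")
  expect_lt(abs(mean(y == 3) - 0.5), 0.005)
  cont <- sample_serving_count(c(1, 2), 1000, s, "d", mode = "continuous")
  expect_true(all(cont >= 1 & cont <= 2) && !all(cont == round(cont)))
  expect_error(sample_serving_count(c(2, 1), 10), "range")
})

test_that("labelled substreams are reproducible and mutually independent", {
  d1 <- dist_sample(dist_normal(0, 1), 100, rng_stream(7), "x")
  d2 <- dist_sample(dist_normal(0, 1), 100, rng_stream(7), "x")
  d3 <- dist_sample(dist_normal(0, 1), 100, rng_stream(7), "y")
  expect_identical(d1, d2)
  expect_false(any(d1 == d3))
  # drawing under one label does not disturb another label's sequence
  s <- rng_stream(7)
  invisible(dist_sample(dist_normal(0, 1), 50, s, "z"))
  expect_identical(dist_sample(dist_normal(0, 1), 100, s, "x"), d1)
})
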