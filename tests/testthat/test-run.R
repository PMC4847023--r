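test_that("identical seed and configuration give bit-identical results", {
  sc <- tiny_scenario()
  f1 <- arsenic_risk(sc, n_iterations = 5000, seed = 31)
  f2 <- arsenic_risk(sc, n_iterations = 5000, seed = 31)
  expect_identical(f1$add_table, f2$add_table)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$mcl$percentiles, f2$mcl$percentiles)
  expect_identical(f1$manifest$config_digest, f2$manifest$config_digest)
  f3 <- arsenic_risk(sc, n_iterations = 5000, seed = 32)
  expect_false(identical(f1$metrics, f3$metrics))
})

test_that("chunked execution reproduces single-pass results exactly", {
  sc <- tiny_scenario()
  whole <- arsenic_risk(sc, n_iterations = 4000, seed = 9)
  chunked <- arsenic_risk(sc, n_iterations = 4000, seed = 9, chunk_size = 997)
  expect_identical(whole$add_table, chunked$add_table)
  expect_identical(whole$metrics, chunked$metrics)
  expect_identical(whole$mcl$percentiles, chunked$mcl$percentiles)
})

test_that("percentile summaries interpolate linearly between order statistics", {
  expect_equal(percentile_summary(1:100, 50), 50.5)
  expect_equal(percentile_summary(rep(3.2, 10), c(25, 50, 75)), rep(3.2, 3))
  set.seed(2)
  u <- runif(1e6)
  expect_lt(abs(percentile_summary(u, 25) - 0.25), 0.002)
  expect_error(percentile_summary(numeric(0), 50), "empty")
})

test_that("doses are nonnegative and totals are exactly additive per iteration", {
  fit <- arsenic_risk(tiny_scenario(), n_iterations = 3000, seed = 17,
                      keep_draws = TRUE)
  expect_true(all(fit$add_table >= 0))
  expect_true(all(fit$metrics >= 0))
  expect_true(all(unlist(lapply(fit$add_draws, function(m) all(m >= 0)))))
  tot <- fit$add_draws$water + fit$add_draws$formula +
    fit$add_draws$rice_cereal + fit$add_draws$other_solid
  expect_identical(tot, fit$add_draws$total)
  # per-iteration dose ordering: min band ADD <= CDI <= max band ADD
  lo <- do.call(pmin, asplit(fit$add_draws$total, 2))
  hi <- do.call(pmax, asplit(fit$add_draws$total, 2))
  expect_true(all(fit$draws$total$cdi >= lo - 1e-18 &
                  fit$draws$total$cdi <= hi + 1e-18))
  # LADD/CDI is the duration ratio, exactly, for every iteration
  expect_equal(fit$draws$total$ladd, fit$draws$total$cdi * 620 / 25550)
})

test_that("scaling one source's concentration scales only that source", {
  sc <- tiny_scenario()
  sc2 <- sc
  sc2$concentrations$water$params$high <- sc$concentrations$water$params$high * 2
  f1 <- arsenic_risk(sc, n_iterations = 3000, seed = 4, keep_draws = TRUE)
  f2 <- arsenic_risk(sc2, n_iterations = 3000, seed = 4, keep_draws = TRUE)
  expect_equal(f2$draws$water$cdi, 2 * f1$draws$water$cdi, tolerance = 1e-12)
  expect_identical(f2$draws$rice_cereal$cdi, f1$draws$rice_cereal$cdi)
  expect_identical(f2$draws$formula$cdi, f1$draws$formula$cdi)
  expect_equal(f2$draws$total$cdi - f1$draws$total$cdi,
               f1$draws$water$cdi, tolerance = 1e-12)
})

test_that("the alternative cancer slope rescales risk exactly", {
  sc <- tiny_scenario()
  f15 <- arsenic_risk(sc, n_iterations = 3000, seed = 12, csf = 1.5)
  f36 <- arsenic_risk(sc, n_iterations = 3000, seed = 12, csf = 3.6)
  expect_equal(f36$metrics["ILCR", , ], 2.4 * f15$metrics["ILCR", , ],
               tolerance = 1e-12)
  expect_identical(f36$metrics["CDI", , ], f15$metrics["CDI", , ])
})

test_that("clamp-driven zero inflation reaches the reported low percentiles", {
  fit <- arsenic_risk(n_iterations = 2e4, seed = 6)
  # P(V_rc <= 0) = pnorm(-44.2/70.9) = 0.27 > 0.25 at 12-14 months
  expect_identical(fit$add_table["12-14", "rice_cereal", "p25"], 0)
  # at 4-5 months the clamp atoms of the shared food concentration and of
  # both serving sizes push the other-solid 25th percentile to near-zero
  expect_lt(fit$add_table["4-5", "other_solid", "p25"], 5e-6)
})

test_that("water-triplet reinterpretation lowers water doses but runs clean", {
  sc <- tiny_scenario()
  f_mmm <- arsenic_risk(sc, n_iterations = 5000, seed = 2)
  f_pct <- arsenic_risk(sc, n_iterations = 5000, seed = 2,
                        water_triplet = "p10_p50_p90")
  # percentile fit pulls the bulk of the distribution toward the p50 value
  expect_false(identical(f_pct$add_table[, "water", ], f_mmm$add_table[, "water", ]))
  expect_true(all(f_pct$add_table[, "water", ] >= 0))
})

test_that("result methods print, plot, coerce and simulate", {
  fit <- arsenic_risk(tiny_scenario(), n_iterations = 2000, seed = 1)
  expect_output(print(fit), "Monte Carlo risk assessment")
  expect_output(summary(fit), "by age band and source")
  d <- as.data.frame(fit, "add")
  expect_equal(nrow(d), 2 * 5 * 3)
  expect_true(all(c("band", "source", "percentile") %in% names(d)))
  expect_equal(nrow(as.data.frame(fit, "mcl")), 2)
  grDevices::pdf(NULL)
  expect_silent(plot(fit))
  grDevices::dev.off()
  sim <- simulate(fit, nsim = 500)
  expect_equal(nrow(sim), 500)
  expect_true(all(c("rice_cereal.cdi", "total.ilcr") %in% names(sim)))
})

test_that("output bundles round-trip through delimited text without loss", {
  fit <- arsenic_risk(tiny_scenario(), n_iterations = 2000, seed = 13)
  dir <- tempfile()
  write_risk_tables(fit, dir)
  expect_setequal(list.files(dir), c("add_table.csv", "metrics.csv",
                                     "shares.csv", "mcl.csv", "manifest.yaml"))
  back <- read_risk_tables(dir)
  expect_identical(back$add$add_mg_kg_day,
                   as.data.frame(fit, "add")$add_mg_kg_day)
  expect_identical(back$metrics$value, as.data.frame(fit, "metrics")$value)
  expect_identical(back$mcl$mcl_mg_per_g, as.data.frame(fit, "mcl")$mcl_mg_per_g)
  expect_equal(back$manifest$config_digest, fit$manifest$config_digest)
  expect_equal(back$manifest$seed, fit$seed)
})

test_that("the command-line interface drives the pipeline end to end", {
  cli <- system.file("cli", "asirisk.R", package = "asirisk")
  expect_true(nzchar(cli))
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    out <- tempfile()
    code <- system2("Rscript", c(cli, ...), stdout = out, stderr = out,
                    env = paste0("R_LIBS=", rlibs))
    list(code = code, log = readLines(out, warn = FALSE))
  }
  # emit a scenario, then run a small simulation from it
  yml <- tempfile(fileext = ".yaml")
  sres <- run_cli("scenario", "--kind", "default", "--out", yml)
  expect_equal(sres$code, 0)
  outdir <- tempfile()
  rres <- run_cli("run", "--config", yml, "--iterations", "2000",
                  "--seed", "42", "--out", outdir)
  expect_equal(rres$code, 0)
  expect_true(file.exists(file.path(outdir, "metrics.csv")))
  # configuration errors exit with the dedicated status
  bad <- run_cli("run", "--config", "no-such-file.yaml")
  expect_equal(bad$code, 2)
})
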