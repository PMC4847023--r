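#' Monte Carlo risk assessment of dietary inorganic arsenic
#'
#' Runs the full probabilistic pipeline: samples concentrations, body
#' weights and intake volumes for every age band; forms per-iteration
#' average daily doses by source (\eqn{ADD = C V / BW}), the month-weighted
#' chronic daily intake, the lifetime average daily dose, acute and chronic
#' hazard quotients and the incremental lifetime cancer risk; back-calculates
#' the allowable rice-cereal concentration; and summarizes everything at the
#' requested percentiles.
#'
#' Within an iteration the four source concentrations are drawn once and
#' shared across age bands (a child keeps the same water source and product
#' brands as it ages), while body weights, intake volumes and serving counts
#' are drawn independently per band; `concentration_mode = "independent"`
#' redraws concentrations per band instead. Negative draws from wide normal
#' intake distributions are clamped to 0.0 (non-consumption), which produces
#' the zero-inflated low percentiles characteristic of infant intake data. A
#' non-positive body-weight draw (probability ~1e-16 at the canonical
#' parameters) is redrawn, never clamped, since body weight is a divisor.
#'
#' @param scenario an [as_scenario()]; defaults to the canonical
#'   parameterization [us_infant_scenario()].
#' @param n_iterations number of Monte Carlo iterations; defaults to the
#'   scenario's setting (one million for the canonical scenario).
#' @param seed root random seed; defaults to the scenario's setting.
#' @param csf cancer slope factor override, (mg/kg/day)^-1 (e.g. 3.6 for the
#'   alternative slope, giving exactly 2.4x the default-1.5 risk).
#' @param percentiles reporting percentiles; defaults to the scenario's
#'   (25, 50, 75).
#' @param concentration_mode `"shared"` (one concentration draw per
#'   iteration, default) or `"independent"` (per band).
#' @param serving_mode `"discrete"` integer serving counts (default) or
#'   `"continuous"`.
#' @param water_triplet interpretation of the water-intake triangular
#'   triplets: `"min_mode_max"` (default) or `"p10_p50_p90"` (percentile fit
#'   with negative tail clamped at zero).
#' @param mcl_rice_intake rice-cereal intake used in the MCL
#'   back-calculation: `"conditional"` redraws intake conditional on
#'   consumption (> 0 g/day, default; the MCL is only meaningful for
#'   consumers), `"band_mean"` uses each band's clamped-mean intake.
#' @param mcl_aggregation how per-band allowable-concentration terms are
#'   aggregated into one MCL per iteration: `"bands"` (default) counts each
#'   age-band profile once against the 21 monthly data sets — the convention
#'   under which the assessment's risk-management levels are defined;
#'   `"months"` is the strict month expansion (month-count-weighted band
#'   mean, the same weighting the CDI uses). See the vignette for the
#'   numerical consequences of the choice.
#' @param mcl_percentile protective reporting percentile for the MCL
#'   (default 25).
#' @param chunk_size process iterations in chunks of this size (memory
#'   guard); results are bit-identical to single-pass execution.
#' @param keep_draws keep the per-iteration metric vectors in the result
#'   (needed by [simulate()][simulate.arsenic_risk] diagnostics; adds ~170
#'   bytes/iteration).
#' @return an object of class `arsenic_risk` with components
#'   \describe{
#'     \item{add_table}{band x source x percentile array of ADDs (mg/kg/day),
#'       including the total-sources column — the dose table.}
#'     \item{metrics}{metric x scope x percentile array for scopes
#'       `rice_cereal` and `total`: `ADD_max`, `CDI`, `LADD` (mg/kg/day),
#'       `HQ_acute`, `HQ_chronic` (dimensionless), `ILCR` (probability).
#'       `CDI`, `LADD`, `HQ_chronic` and `ILCR` are percentiles of
#'       per-iteration values; `ADD_max` (and hence `HQ_acute`) is the
#'       largest entry of the corresponding dose-table percentile column —
#'       the age band with the highest dose at that percentile — matching
#'       the reporting convention of published percentile tables.
#'       Per-iteration maxima are available via `keep_draws`.}
#'     \item{cdi_percentiles}{source x percentile CDIs behind the shares.}
#'     \item{shares}{per-source percentage contribution to the median dose
#'       composition: each source's median CDI over the sum of the four
#'       source median CDIs (sums to 100 by construction). Attributes carry
#'       two diagnostics: `vs_total_percentile` divides by the percentile of
#'       the per-iteration total instead (percentiles are not additive, so
#'       these need not sum to 100), and `mean_share` averages per-iteration
#'       shares.}
#'     \item{mcl}{list with `acute`/`chronic` [summarize_mcl()] results and
#'       the full percentile rows of both MCL distributions (mg/g).}
#'     \item{se}{order-statistic Monte Carlo standard errors for
#'       `add_table` and `metrics` cells.}
#'     \item{manifest}{config digest, seed, iteration count, version,
#'       timestamp.}
#'   }
#' @examples
#' fit <- arsenic_risk(n_iterations = 2e4, seed = 1)
#' fit
#' summary(fit)
#' @export
arsenic_risk <- function(scenario = us_infant_scenario(),
                         n_iterations = NULL, seed = NULL, csf = NULL,
                         percentiles = NULL,
                         concentration_mode = c("shared", "independent"),
                         serving_mode = c("discrete", "continuous"),
                         water_triplet = c("min_mode_max", "p10_p50_p90"),
                         mcl_rice_intake = c("conditional", "band_mean"),
                         mcl_aggregation = c("bands", "months"),
                         mcl_percentile = 25,
                         chunk_size = NULL, keep_draws = FALSE) {
  validate_scenario(scenario)
  concentration_mode <- match.arg(concentration_mode)
  serving_mode <- match.arg(serving_mode)
  water_triplet <- match.arg(water_triplet)
  mcl_rice_intake <- match.arg(mcl_rice_intake)
  mcl_aggregation <- match.arg(mcl_aggregation)
  n <- as.integer(n_iterations %||% scenario$n_iterations)
  seed <- as.integer(seed %||% scenario$seed)
  csf <- csf %||% scenario$tox$csf
  percentiles <- percentiles %||% scenario$percentiles
  stopifnot(n >= 1, csf > 0)

  if (water_triplet == "p10_p50_p90")
    scenario$bands <- lapply(scenario$bands, function(b) {
      p <- b$v_w$params
      b$v_w <- dist_triangular(p$a, p$b, p$c, interpretation = "p10_p50_p90")
      b
    })

  stream <- rng_stream(seed)
  draws <- .draw_all(scenario, n, stream, concentration_mode, serving_mode)
  mcl_vrc <- .draw_mcl_vrc(scenario, n, stream, mcl_rice_intake)

  B <- length(scenario$bands)
  w <- band_month_weights(scenario)
  scopes <- c(SOURCES, "total")

  # per band x source ADD matrices (n x B per scope)
  add <- lapply(scopes, function(s) matrix(0, n, B))
  names(add) <- scopes
  mcl_mat <- list(acute = matrix(0, n, B), chronic = matrix(0, n, B))
  chunks <- .chunk_index(n, chunk_size %||% n)
  tox <- scenario$tox
  for (idx in chunks) {
    for (b in seq_len(B)) {
      d <- lapply(draws$bands[[b]], `[`, idx)
      conc <- lapply(SOURCES, function(s)
        if (concentration_mode == "shared") draws$conc[[s]][idx]
        else draws$conc[[s]][[b]][idx])
      names(conc) <- SOURCES
      intakes <- band_intakes(d)
      tot <- 0
      for (s in SOURCES) {
        a <- compute_add(conc[[s]], intakes[[s]], d$bw)
        add[[s]][idx, b] <- a
        tot <- tot + a
      }
      add$total[idx, b] <- tot
      other_mg <- tox$mcl_w * intakes$water +
        conc$formula * intakes$formula +
        conc$other_solid * intakes$other_solid
      vrc <- mcl_vrc[[b]][idx]
      mcl_mat$acute[idx, b] <- mcl_per_band(tox$mrl_acute, d$bw, other_mg, vrc)
      mcl_mat$chronic[idx, b] <- mcl_per_band(tox$mrl_chronic, d$bw, other_mg, vrc)
    }
  }

  # per-iteration dose and risk metrics by scope
  it <- list()
  for (s in scopes) {
    cdi <- compute_cdi(add[[s]], w)
    it[[s]] <- list(
      cdi = cdi,
      add_max = compute_add_max(add[[s]]),
      ladd = compute_ladd(cdi, tox$ed_days, tox$at_days))
    it[[s]]$hq_acute <- hq_acute(it[[s]]$add_max, tox$mrl_acute)
    it[[s]]$hq_chronic <- hq_chronic(cdi, tox$mrl_chronic)
    it[[s]]$ilcr <- ilcr(it[[s]]$ladd, csf)
  }
  mcl_w_agg <- if (mcl_aggregation == "months") w else rep(1L, B)
  mcl_it <- list(
    acute = drop(mcl_mat$acute %*% mcl_w_agg) / sum(w),
    chronic = drop(mcl_mat$chronic %*% mcl_w_agg) / sum(w))

  # summaries
  pr <- percentiles / 100
  pn <- paste0("p", percentiles)
  band_labels <- vapply(scenario$bands, `[[`, "", "label")
  add_table <- array(0, c(B, length(scopes), length(pr)),
                     dimnames = list(band_labels, scopes, pn))
  add_se <- add_table
  for (s in seq_along(scopes)) for (b in seq_len(B)) {
    qs <- .quantile_with_se(add[[scopes[s]]][, b], pr)
    add_table[b, s, ] <- qs$q
    add_se[b, s, ] <- qs$se
  }
  metric_names <- c("ADD_max", "CDI", "LADD", "HQ_acute", "HQ_chronic", "ILCR")
  metric_scopes <- c("rice_cereal", "total")
  metrics <- array(0, c(length(metric_names), 2, length(pr)),
                   dimnames = list(metric_names, metric_scopes, pn))
  metrics_se <- metrics
  key <- c(ADD_max = "add_max", CDI = "cdi", LADD = "ladd",
           HQ_acute = "hq_acute", HQ_chronic = "hq_chronic", ILCR = "ilcr")
  for (m in metric_names) for (s in metric_scopes) {
    qs <- .quantile_with_se(it[[s]][[key[[m]]]], pr)
    metrics[m, s, ] <- qs$q
    metrics_se[m, s, ] <- qs$se
  }
  # reported ADD_max / HQ_acute: the band with the highest dose at each
  # percentile of the dose table (the printed-table convention), not the
  # percentile of per-iteration maxima
  for (s in metric_scopes) for (k in seq_along(pr)) {
    j <- which.max(add_table[, s, k])
    metrics["ADD_max", s, k] <- add_table[j, s, k]
    metrics["HQ_acute", s, k] <- add_table[j, s, k] / tox$mrl_acute
    metrics_se["ADD_max", s, k] <- add_se[j, s, k]
    metrics_se["HQ_acute", s, k] <- add_se[j, s, k] / tox$mrl_acute
  }
  cdi_pct <- t(vapply(scopes, function(s)
    percentile_summary(it[[s]]$cdi, percentiles), numeric(length(pr))))
  dimnames(cdi_pct) <- list(scopes, pn)
  p50 <- if (50 %in% percentiles) "p50" else pn[which.min(abs(percentiles - 50))]
  shares <- source_shares(cdi_pct[SOURCES, p50], sum(cdi_pct[SOURCES, p50]))
  attr(shares, "vs_total_percentile") <-
    source_shares(cdi_pct[SOURCES, p50], cdi_pct["total", p50])
  attr(shares, "mean_share") <- vapply(SOURCES, function(s)
    100 * mean(it[[s]]$cdi / pmax(it$total$cdi, .Machine$double.xmin)),
    numeric(1))
  mcl <- list(acute = summarize_mcl(mcl_it$acute, mcl_percentile),
              chronic = summarize_mcl(mcl_it$chronic, mcl_percentile),
              percentiles = rbind(
                acute = percentile_summary(mcl_it$acute, percentiles),
                chronic = percentile_summary(mcl_it$chronic, percentiles)))
  colnames(mcl$percentiles) <- pn

  res <- structure(list(
    call = match.call(), scenario = scenario,
    n_iterations = n, seed = seed, csf = csf, percentiles = percentiles,
    settings = list(concentration_mode = concentration_mode,
                    serving_mode = serving_mode,
                    water_triplet = water_triplet,
                    mcl_rice_intake = mcl_rice_intake,
                    mcl_aggregation = mcl_aggregation,
                    mcl_percentile = mcl_percentile),
    add_table = add_table, metrics = metrics,
    cdi_percentiles = cdi_pct, shares = shares, mcl = mcl,
    se = list(add_table = add_se, metrics = metrics_se),
    manifest = run_manifest(scenario, seed, n)),
    class = "arsenic_risk")
  if (keep_draws) {
    res$draws <- it
    res$add_draws <- add
    res$mcl_draws <- mcl_it
  }
  res
}

#' Empirical percentile summary
#'
#' Quantiles by linear interpolation between the closest order statistics
#' (type 7, the standard default).
#'
#' @param values numeric vector, non-empty.
#' @param percentiles percentiles in (0, 100).
#' @return numeric vector of quantiles.
#' @examples
#' percentile_summary(1:100, 50)  # 50.5
#' @export
percentile_summary <- function(values, percentiles = c(25, 50, 75)) {
  if (length(values) == 0) stop("empty input")
  unname(quantile(values, percentiles / 100, type = 7))
}

#' Run manifest
#'
#' Provenance record for a simulation: a digest of the full configuration,
#' the seed and iteration count, package version and timestamp. Two runs
#' with equal digest and seed produce identical tables.
#'
#' @param scenario an [as_scenario()].
#' @param seed,n_iterations the run settings.
#' @return a named list of class `run_manifest`.
#' @export
run_manifest <- function(scenario, seed, n_iterations) {
  structure(list(config_digest = scenario_digest(scenario),
                 seed = seed, n_iterations = n_iterations,
                 package_version = as.character(utils::packageVersion("asirisk")),
                 timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
            class = "run_manifest")
}

#' Digest of a scenario configuration
#'
#' 32-bit FNV-1a hash of the scenario's canonical YAML serialization,
#' rendered as hex. Any parameter change changes the digest.
#'
#' @param scenario an [as_scenario()].
#' @return an 8-character hex string.
#' @export
scenario_digest <- function(scenario) {
  txt <- yaml::as.yaml(.scenario_to_doc(scenario), precision = 15L)
  sprintf("%08x", .hash_label(txt))
}

# internal: scenario -> plain document (shared by write_scenario and digest)
.scenario_to_doc <- function(scenario) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario(scenario, tmp)
  yaml::read_yaml(tmp)
}

# --- internal sampling helpers -------------------------------------------

.chunk_index <- function(n, chunk_size) {
  starts <- seq(1L, n, by = as.integer(chunk_size))
  lapply(starts, function(s) s:min(s + chunk_size - 1L, n))
}

# draw body weight with redraw guard for non-positive values
.draw_bw <- function(spec, n, stream, label) {
  x <- dist_sample(spec, n, stream, label)
  tries <- 0L
  while (any(x <= 0) && tries < 100L) {
    tries <- tries + 1L
    bad <- which(x <= 0)
    x[bad] <- dist_sample(spec, length(bad), stream,
                          paste0(label, "/retry", tries))
  }
  if (any(x <= 0)) stop("body-weight distribution places too much mass at <= 0")
  x
}

.draw_all <- function(scenario, n, stream, concentration_mode, serving_mode) {
  band_labels <- vapply(scenario$bands, `[[`, "", "label")
  conc <- lapply(SOURCES, function(s) {
    spec <- scenario$concentrations[[s]]
    if (concentration_mode == "shared") {
      dist_sample(spec, n, stream, paste0("conc/", s))
    } else {
      out <- lapply(band_labels, function(bl)
        dist_sample(spec, n, stream, paste0("conc/", s, "/band/", bl)))
      names(out) <- band_labels
      out
    }
  })
  names(conc) <- SOURCES
  bands <- lapply(scenario$bands, function(b) {
    lab <- function(q) paste0("band/", b$label, "/", q)
    d <- list(
      bw = .draw_bw(b$body_weight, n, stream, lab("bw")),
      v_w = dist_sample(b$v_w, n, stream, lab("v_w")),
      v_if_g = dist_sample(b$v_if$grams, n, stream, lab("v_if_g")),
      v_if_n = sample_serving_count(b$v_if$servings, n, stream, lab("v_if_n"),
                                    mode = serving_mode),
      v_rc = dist_sample(b$v_rc, n, stream, lab("v_rc")))
    for (f in OTHER_FOODS) {
      if (is.null(b[[f]])) next
      d[[paste0(f, "_g")]] <- dist_sample(b[[f]]$grams, n, stream,
                                          lab(paste0(f, "_g")))
      d[[paste0(f, "_n")]] <- sample_serving_count(b[[f]]$servings, n, stream,
                                                   lab(paste0(f, "_n")),
                                                   mode = serving_mode)
    }
    d
  })
  list(conc = conc, bands = bands)
}

# rice-cereal intake for the MCL back-calculation: strictly positive draws
.draw_mcl_vrc <- function(scenario, n, stream, mode) {
  lapply(scenario$bands, function(b) {
    spec <- b$v_rc
    if (mode == "band_mean")
      return(rep(.clamped_mean(spec), n))
    if (spec$family == "normal") {
      p0 <- pnorm(0, spec$params$mean, spec$params$sd)
      with_substream(stream, paste0("mcl/v_rc/band/", b$label),
                     qnorm(runif(n, p0, 1), spec$params$mean, spec$params$sd))
    } else {
      x <- dist_sample(spec, n, stream, paste0("mcl/v_rc/band/", b$label))
      if (any(x <= 0))
        stop("rice-cereal intake distribution must allow strictly positive draws")
      x
    }
  })
}

# mean of the clamp-at-zero distribution, E[max(X, 0)]
.clamped_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = {
      z <- p$mean / p$sd
      m <- p$mean * pnorm(z) + p$sd * dnorm(z)
      if (m <= 0) stop("clamped-mean rice-cereal intake is not positive")
      m
    },
    uniform = max((p$low + p$high) / 2, 0),
    triangular = (p$a + p$b + p$c) / 3,
    point = p$value)
}

# quantiles plus distribution-free MC standard errors from order statistics
.quantile_with_se <- function(x, pr) {
  n <- length(x)
  sx <- sort(x)
  q <- unname(quantile(sx, pr, type = 7, names = FALSE))
  se <- vapply(pr, function(p) {
    half <- 1.96 * sqrt(p * (1 - p) / n)
    lo <- sx[max(1L, floor(n * (p - half)))]
    hi <- sx[min(n, ceiling(n * (p + half)))]
    (hi - lo) / (2 * 1.96)
  }, numeric(1))
  list(q = q, se = se)
}
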