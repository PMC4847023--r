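#' Study scenarios: the complete model parameterization
#'
#' A scenario bundles everything the simulation needs: the four source
#' concentration distributions, the six age-band profiles (body weight and
#' intake-volume distributions), the toxicology constants, and the simulation
#' settings. [us_infant_scenario()] returns the canonical published
#' parameterization; [load_scenario()] / [write_scenario()] read and write
#' the YAML configuration format; [validate_scenario()] enforces the schema.
#'
#' @name scenario
NULL

OTHER_FOODS <- c("v_fr", "v_v", "v_m")

#' Serving-based intake specification
#'
#' Grams consumed per serving (a distribution) times an integer range of
#' servings per day.
#'
#' @param grams a [dist_spec][dist_uniform] for grams per serving.
#' @param servings integer `c(n_min, n_max)`, `0 <= n_min <= n_max`.
#' @return an object of class `serving_spec`.
#' @export
serving_spec <- function(grams, servings) {
  validate_dist_spec(grams)
  stopifnot(length(servings) == 2L, servings[1] >= 0, servings[1] <= servings[2],
            all(servings == round(servings)))
  structure(list(grams = grams, servings = as.integer(servings)),
            class = "serving_spec")
}

#' Age-band profile
#'
#' One age band's body-weight distribution and all its intake-volume
#' specifications. A band covers a contiguous run of monthly ages; across a
#' scenario the bands must partition months 4 through 24 (21 monthly ages).
#'
#' @param label band label, e.g. `"4-5"`.
#' @param months integer vector of the monthly ages covered.
#' @param body_weight [dist_spec][dist_normal], kg.
#' @param v_w water intake [dist_spec][dist_triangular], L/day.
#' @param v_if formula intake, a [serving_spec()] in g dry weight/serving.
#' @param v_rc rice-cereal intake [dist_spec][dist_normal], g dry/day.
#' @param v_fr,v_v,v_m fruit / vegetable / meat [serving_spec()]s, g/serving,
#'   or `NULL` when the food is not yet consumed at that age.
#' @return an object of class `age_band`.
#' @export
age_band <- function(label, months, body_weight, v_w, v_if, v_rc,
                     v_fr = NULL, v_v = NULL, v_m = NULL) {
  stopifnot(is.character(label), length(months) >= 1)
  months <- as.integer(months)
  structure(list(label = label, months = months, body_weight = body_weight,
                 v_w = v_w, v_if = v_if, v_rc = v_rc,
                 v_fr = v_fr, v_v = v_v, v_m = v_m),
            class = "age_band")
}

#' Construct a scenario
#'
#' @param concentrations named list with [dist_spec][dist_uniform] elements
#'   `water` (mg/L), `formula` (mg per g dry weight), `rice_cereal` (mg/g),
#'   `other_solid` (mg/g).
#' @param bands list of [age_band()] profiles partitioning months 4-24.
#' @param tox named list of toxicology constants: `mrl_acute`, `mrl_chronic`
#'   (mg/kg/day), `csf` ((mg/kg/day)^-1), `mcl_w` (mg/L), `ed_days`,
#'   `at_days`.
#' @param n_iterations Monte Carlo iteration count.
#' @param seed root random seed.
#' @param percentiles reporting percentiles in (0, 100).
#' @return a validated object of class `as_scenario`.
#' @export
as_scenario <- function(concentrations, bands, tox,
                        n_iterations = 1e6, seed = 1L,
                        percentiles = c(25, 50, 75)) {
  tox <- lapply(tox, as.numeric)
  x <- structure(list(concentrations = concentrations, bands = bands, tox = tox,
                      n_iterations = as.numeric(n_iterations),
                      seed = as.integer(seed),
                      percentiles = as.numeric(percentiles)),
                 class = "as_scenario")
  validate_scenario(x)
}

#' The canonical U.S. infant/toddler parameterization
#'
#' Returns the published study scenario: inorganic-arsenic concentration
#' distributions for drinking water (uniform 0 to 0.010 mg/L), infant
#' formula (normal, 7.48e-6 +/- 6.12e-7 mg per g dry weight), rice cereal
#' (triangular, min 2.30e-5 / mode 9.10e-5 / max 2.83e-4 mg/g) and other
#' infant solid food (normal, 4.6e-6 +/- 5.6e-6 mg/g); six age bands (4-5,
#' 6-8, 9-11, 12-14, 15-18, 19-24 months) with their body-weight and
#' intake-volume distributions; and the toxicology constants (acute MRL
#' 5.0e-3 and chronic MRL 3.0e-4 mg/kg/day, cancer slope factor 1.5
#' (mg/kg/day)^-1, drinking-water MCL 0.010 mg/L, exposure duration 620 days,
#' averaging time 25,550 days).
#'
#' Water-intake triplets are interpreted as triangular (min, mode, max); see
#' the package vignette for why the alternative percentile reading is
#' infeasible for a nonnegative triangular. Meat is absent before 6 months.
#'
#' @param n_iterations,seed,percentiles simulation settings.
#' @return an `as_scenario`.
#' @examples
#' sc <- us_infant_scenario()
#' sc$tox$mrl_chronic         # 3e-4 mg/kg/day
#' sc$bands[[1]]$body_weight  # normal(6.95, 0.85) kg
#' @export
us_infant_scenario <- function(n_iterations = 1e6, seed = 20160325,
                               percentiles = c(25, 50, 75)) {
  tn <- function(m, s) dist_normal(m, s, truncate_at_zero = TRUE)
  tri <- function(a, b, c) dist_triangular(a, b, c)
  sv <- function(m, s, n1, n2) serving_spec(tn(m, s), c(n1, n2))
  bands <- list(
    age_band("4-5", 4:5, dist_normal(6.95, 0.85), tri(0, 0.148, 0.924),
             sv(21.5, 9.7, 4, 5), tn(14.3, 16.1),
             v_fr = sv(58.7, 77.4, 1, 2), v_v = sv(61.9, 81.4, 1, 2)),
    age_band("6-8", 6:8, dist_normal(7.95, 1.08), tri(0, 0.218, 0.885),
             sv(22.8, 11.4, 3, 4), tn(20.7, 17.1),
             v_fr = sv(76.6, 47.7, 1, 2), v_v = sv(94.5, 69.4, 1, 2),
             v_m = sv(25.5, 120.7, 1, 2)),
    age_band("9-11", 9:11, dist_normal(9.03, 1.05), tri(0, 0.218, 0.885),
             sv(24.1, 10.1, 3, 4), tn(23.9, 21.7),
             v_fr = sv(94.5, 72.6, 1, 2), v_v = sv(91.3, 85.5, 2, 3),
             v_m = sv(22.7, 37.2, 1, 2)),
    age_band("12-14", 12:14, dist_normal(9.93, 1.08), tri(0, 0.188, 0.624),
             sv(24.5, 22.4, 3, 4), tn(44.2, 70.9),
             v_fr = sv(104.3, 100.5, 1, 2), v_v = sv(104.3, 100.5, 2, 3),
             v_m = sv(34.0, 32.8, 1, 2)),
    age_band("15-18", 15:18, dist_normal(10.90, 1.50), tri(0, 0.188, 0.624),
             sv(25.4, 52.4, 3, 4), tn(44.2, 70.9),
             v_fr = sv(130.4, 138.2, 1, 2), v_v = sv(104.3, 138.2, 2, 3),
             v_m = sv(36.9, 40.1, 1, 2)),
    age_band("19-24", 19:24, dist_normal(11.85, 1.38), tri(0, 0.188, 0.624),
             sv(20.2, 75.4, 3, 4), tn(51.5, 65.8),
             v_fr = sv(156.5, 134.0, 1, 2), v_v = sv(104.3, 93.3, 2, 3),
             v_m = sv(36.9, 35.5, 1, 2))
  )
  as_scenario(
    concentrations = list(
      water       = dist_uniform(0, 0.010),
      formula     = tn(7.48e-6, 6.12e-7),
      rice_cereal = tri(2.30e-5, 9.10e-5, 2.83e-4),
      other_solid = tn(4.6e-6, 5.6e-6)),
    bands = bands,
    tox = list(mrl_acute = 5.0e-3, mrl_chronic = 3.0e-4, csf = 1.5,
               mcl_w = 0.010, ed_days = 620, at_days = 25550),
    n_iterations = n_iterations, seed = seed, percentiles = percentiles)
}

#' Month weights of a scenario's age bands
#'
#' @param scenario an `as_scenario`.
#' @return integer vector of months covered per band (sums to 21 for the
#'   canonical scenario).
#' @export
band_month_weights <- function(scenario)
  vapply(scenario$bands, function(b) length(b$months), integer(1))

#' Validate a scenario against the schema
#'
#' Checks every distribution spec, serving range and toxicology constant, and
#' that the bands' monthly ages are non-empty, contiguous, and together
#' partition months 4 through 24 exactly once.
#'
#' @param scenario an `as_scenario`.
#' @return the scenario, invisibly; stops with a path-named error otherwise.
#' @export
validate_scenario <- function(scenario) {
  fail <- function(path, msg)
    stop(sprintf("scenario$%s: %s", path, msg), call. = FALSE)
  if (!inherits(scenario, "as_scenario")) stop("not an 'as_scenario' object")
  cn <- scenario$concentrations
  if (!setequal(names(cn), SOURCES))
    fail("concentrations", paste("must name exactly:", paste(SOURCES, collapse = ", ")))
  for (s in SOURCES)
    tryCatch(validate_dist_spec(cn[[s]]),
             error = function(e) fail(paste0("concentrations$", s), conditionMessage(e)))
  if (length(scenario$bands) == 0) fail("bands", "no age bands")
  all_months <- integer(0)
  for (i in seq_along(scenario$bands)) {
    b <- scenario$bands[[i]]
    path <- sprintf("bands[[%d]]", i)
    if (!inherits(b, "age_band")) fail(path, "not an 'age_band'")
    if (length(b$months) == 0) fail(paste0(path, "$months"), "empty")
    if (length(b$months) > 1 && any(diff(b$months) != 1L))
      fail(paste0(path, "$months"), "not contiguous")
    if (any(b$months < 4L | b$months > 24L))
      fail(paste0(path, "$months"), "outside 4-24 months")
    all_months <- c(all_months, b$months)
    for (f in c("body_weight", "v_w", "v_rc"))
      tryCatch(validate_dist_spec(b[[f]]),
               error = function(e) fail(paste0(path, "$", f), conditionMessage(e)))
    for (f in c("v_if", OTHER_FOODS)) {
      if (is.null(b[[f]])) {
        if (f == "v_if") fail(paste0(path, "$v_if"), "required")
        next
      }
      if (!inherits(b[[f]], "serving_spec"))
        fail(paste0(path, "$", f), "not a 'serving_spec'")
      tryCatch(validate_dist_spec(b[[f]]$grams),
               error = function(e) fail(paste0(path, "$", f, "$grams"),
                                        conditionMessage(e)))
    }
  }
  if (anyDuplicated(all_months))
    fail("bands", sprintf("months covered more than once: %s",
                          paste(sort(unique(all_months[duplicated(all_months)])),
                                collapse = ", ")))
  missing <- setdiff(4:24, all_months)
  if (length(missing))
    fail("bands", sprintf("months not covered by any band: %s",
                          paste(missing, collapse = ", ")))
  tox <- scenario$tox
  need <- c("mrl_acute", "mrl_chronic", "csf", "mcl_w", "ed_days", "at_days")
  if (!all(need %in% names(tox)))
    fail("tox", paste("missing:", paste(setdiff(need, names(tox)), collapse = ", ")))
  for (k in need)
    if (!is.numeric(tox[[k]]) || length(tox[[k]]) != 1L || tox[[k]] <= 0)
      fail(paste0("tox$", k), "must be a positive scalar")
  if (!is.numeric(scenario$n_iterations) || scenario$n_iterations < 1)
    fail("n_iterations", "must be >= 1")
  p <- scenario$percentiles
  if (!is.numeric(p) || length(p) == 0 || any(p <= 0 | p >= 100))
    fail("percentiles", "must lie strictly between 0 and 100")
  invisible(scenario)
}

#' @export
print.as_scenario <- function(x, ...) {
  cat("<as_scenario>", length(x$bands), "age bands covering months",
      min(unlist(lapply(x$bands, `[[`, "months"))), "to",
      max(unlist(lapply(x$bands, `[[`, "months"))), "\n")
  cat("  sources:", paste(names(x$concentrations), collapse = ", "), "\n")
  cat("  iterations:", format(x$n_iterations, big.mark = ","),
      " seed:", x$seed,
      " percentiles:", paste(x$percentiles, collapse = "/"), "\n")
  invisible(x)
}
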