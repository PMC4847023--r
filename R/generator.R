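#' Scenario generation for testing and sensitivity analysis
#'
#' Three tools make every pipeline stage testable without external data:
#' [degenerate_scenario()] collapses all distributions to point masses so the
#' pipeline output has a closed form; [closed_form_oracle()] evaluates that
#' closed form by direct arithmetic, independently of the Monte Carlo code
#' path; [perturbed_scenario()] applies seeded multiplicative jitter to the
#' parameters while preserving distribution families and schema validity.
#'
#' @name generator
NULL

.point_of <- function(spec) dist_point(dist_central(spec))

.degenerate_serving <- function(sv) {
  mid <- as.integer(floor((sv$servings[1] + sv$servings[2]) / 2))
  serving_spec(.point_of(sv$grams), c(mid, mid))
}

#' Collapse a scenario to point masses
#'
#' Every distribution is replaced by a point mass at its central value
#' (uniform midpoint, normal mean, triangular mode, serving ranges by their
#' midpoint rounded down — the conservative integer choice). The resulting
#' scenario is its own degenerate form (idempotent) and its pipeline output
#' is a closed-form hand computation.
#'
#' @param scenario an [as_scenario()].
#' @return an `as_scenario` with only point-mass distributions.
#' @export
degenerate_scenario <- function(scenario) {
  validate_scenario(scenario)
  scenario$concentrations <- lapply(scenario$concentrations, .point_of)
  scenario$bands <- lapply(scenario$bands, function(b) {
    for (f in c("body_weight", "v_w", "v_rc")) b[[f]] <- .point_of(b[[f]])
    b$v_if <- .degenerate_serving(b$v_if)
    for (f in OTHER_FOODS)
      if (!is.null(b[[f]])) b[[f]] <- .degenerate_serving(b[[f]])
    b
  })
  validate_scenario(scenario)
  scenario
}

#' Seeded multiplicative perturbation of a scenario
#'
#' @param seed perturbation seed.
#' @param concentration_scale,volume_scale,body_weight_scale lognormal jitter
#'   scales (sd on the log) per parameter class; 0 leaves a class untouched.
#' @return an object of class `scenario_perturbation`.
#' @export
scenario_perturbation <- function(seed, concentration_scale = 0.1,
                                  volume_scale = 0.1, body_weight_scale = 0.05) {
  stopifnot(concentration_scale >= 0, volume_scale >= 0, body_weight_scale >= 0)
  structure(list(seed = as.integer(seed),
                 concentration_scale = concentration_scale,
                 volume_scale = volume_scale,
                 body_weight_scale = body_weight_scale),
            class = "scenario_perturbation")
}

# multiply all location/scale parameters of a spec by one positive factor;
# orderings and nonnegativity of scale parameters are preserved
.jitter_spec <- function(spec, scale) {
  if (scale == 0) return(spec)
  f <- exp(rnorm(1, 0, scale))
  spec$params <- lapply(spec$params, function(v) v * f)
  spec
}

#' Apply a perturbation to a scenario
#'
#' Each distribution's parameters are multiplied by a single lognormal
#' factor drawn under the perturbation seed, so orderings (uniform bounds,
#' triangular min/mode/max) and scale nonnegativity are preserved and the
#' result always validates. Serving-count ranges, month structure and
#' toxicology constants are untouched.
#'
#' @param scenario an [as_scenario()].
#' @param perturbation a [scenario_perturbation()].
#' @return a schema-valid perturbed `as_scenario`.
#' @export
perturbed_scenario <- function(scenario, perturbation) {
  validate_scenario(scenario)
  stopifnot(inherits(perturbation, "scenario_perturbation"))
  stream <- rng_stream(perturbation$seed)
  out <- with_substream(stream, "perturb", {
    scenario$concentrations <- lapply(scenario$concentrations, .jitter_spec,
                                      scale = perturbation$concentration_scale)
    scenario$bands <- lapply(scenario$bands, function(b) {
      b$body_weight <- .jitter_spec(b$body_weight, perturbation$body_weight_scale)
      for (f in c("v_w", "v_rc"))
        b[[f]] <- .jitter_spec(b[[f]], perturbation$volume_scale)
      b$v_if$grams <- .jitter_spec(b$v_if$grams, perturbation$volume_scale)
      for (f in OTHER_FOODS)
        if (!is.null(b[[f]]))
          b[[f]]$grams <- .jitter_spec(b[[f]]$grams, perturbation$volume_scale)
      b
    })
    scenario
  })
  validate_scenario(out)
}

#' Closed-form oracle for a degenerate scenario
#'
#' Evaluates every pipeline quantity (band/source doses, CDI, LADD, maximum
#' dose, hazard quotients, cancer risk, source shares, rice-cereal MCL) by
#' direct arithmetic on the point-mass values — deliberately bypassing the
#' sampling and Monte Carlo machinery so it can serve as an independent
#' check of the simulation code path.
#'
#' @param scenario a degenerate [as_scenario()] (all point masses).
#' @param csf optional cancer slope factor override.
#' @param mcl_aggregation `"bands"` (each band term once over the 21 monthly
#'   data sets, the reporting default) or `"months"` (month-count-weighted
#'   band mean); must match the simulation being checked.
#' @return a list shaped like the corresponding [arsenic_risk()] components:
#'   `add_table`, `metrics`, `cdi_percentiles`, `shares`, `mcl`.
#' @export
closed_form_oracle <- function(scenario, csf = NULL,
                               mcl_aggregation = c("bands", "months")) {
  mcl_aggregation <- match.arg(mcl_aggregation)
  validate_scenario(scenario)
  all_point <- all(vapply(scenario$concentrations,
                          function(s) s$family == "point", logical(1))) &&
    all(vapply(scenario$bands, function(b) {
      pt <- function(s) s$family == "point"
      fixed <- function(sv) is.null(sv) ||
        (pt(sv$grams) && sv$servings[1] == sv$servings[2])
      pt(b$body_weight) && pt(b$v_w) && pt(b$v_rc) &&
        fixed(b$v_if) && fixed(b$v_fr) && fixed(b$v_v) && fixed(b$v_m)
    }, logical(1)))
  if (!all_point)
    stop("closed_form_oracle requires a degenerate (all point-mass) scenario")

  tox <- scenario$tox
  csf <- csf %||% tox$csf
  B <- length(scenario$bands)
  w <- band_month_weights(scenario)
  cval <- function(s) s$params$value
  scopes <- c(SOURCES, "total")
  add <- matrix(0, B, length(scopes), dimnames = list(
    vapply(scenario$bands, `[[`, "", "label"), scopes))
  mcl_band <- matrix(0, B, 2, dimnames = list(NULL, c("acute", "chronic")))
  for (b in seq_len(B)) {
    bd <- scenario$bands[[b]]
    bw <- cval(bd$body_weight)
    serving_total <- function(sv)
      if (is.null(sv)) 0 else cval(sv$grams) * sv$servings[1]
    v <- c(water = cval(bd$v_w),
           formula = serving_total(bd$v_if),
           rice_cereal = cval(bd$v_rc),
           other_solid = serving_total(bd$v_fr) + serving_total(bd$v_v) +
             serving_total(bd$v_m))
    for (s in SOURCES)
      add[b, s] <- cval(scenario$concentrations[[s]]) * v[[s]] / bw
    add[b, "total"] <- sum(add[b, SOURCES])
    other_mg <- tox$mcl_w * v[["water"]] +
      cval(scenario$concentrations$formula) * v[["formula"]] +
      cval(scenario$concentrations$other_solid) * v[["other_solid"]]
    for (ep in c("acute", "chronic")) {
      mrl <- tox[[paste0("mrl_", ep)]]
      mcl_band[b, ep] <- (mrl * bw - other_mg) / v[["rice_cereal"]]
    }
  }
  cdi <- drop(w %*% add) / sum(w)
  add_max <- apply(add, 2, max)
  ladd <- cdi * tox$ed_days / tox$at_days
  pn <- paste0("p", scenario$percentiles)
  P <- length(pn)
  rep_p <- function(v) array(rep(v, P), c(dim(v) %||% length(v), P))

  add_table <- array(rep(add, P), c(B, length(scopes), P),
                     dimnames = c(dimnames(add), list(pn)))
  metric_scopes <- c("rice_cereal", "total")
  metrics <- array(0, c(6, 2, P),
                   dimnames = list(c("ADD_max", "CDI", "LADD", "HQ_acute",
                                     "HQ_chronic", "ILCR"), metric_scopes, pn))
  for (s in metric_scopes) {
    vals <- c(add_max[[s]], cdi[[s]], ladd[[s]],
              add_max[[s]] / tox$mrl_acute, cdi[[s]] / tox$mrl_chronic,
              csf * ladd[[s]])
    for (k in seq_len(P)) metrics[, s, k] <- vals
  }
  cdi_pct <- matrix(rep(cdi[scopes], P), length(scopes), P,
                    dimnames = list(scopes, pn))
  w_agg <- if (mcl_aggregation == "months") w else rep(1L, B)
  mcl_val <- drop(w_agg %*% mcl_band) / sum(w)
  list(add_table = add_table, metrics = metrics, cdi_percentiles = cdi_pct,
       shares = 100 * cdi[SOURCES] / cdi[["total"]],
       mcl = list(acute = max(mcl_val[["acute"]], 0),
                  chronic = max(mcl_val[["chronic"]], 0),
                  raw = mcl_val))
}
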