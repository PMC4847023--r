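#' Dose arithmetic
#'
#' The exposure model is a chain of three quantities. The average daily dose
#' from source x at age t is
#' \deqn{ADD_{x,t} = C_x V_{x,t} / BW_t}
#' (concentration times intake over body weight, mg/kg/day). The chronic
#' daily intake is the mean ADD over the 21 monthly ages 4-24 months; since
#' intake tables resolve to age bands, the 21-point mean becomes a
#' month-count-weighted band mean. The lifetime average daily dose prorates
#' the CDI by exposure duration over a 70-year averaging time,
#' \deqn{LADD = CDI \cdot ED / AT.}
#'
#' All functions are vectorised over Monte Carlo iterations.
#'
#' @name exposure
NULL

#' Average daily dose from one source
#'
#' @param conc concentration of the contaminant in the source (mg/L for
#'   water, mg/g otherwise); vectorised.
#' @param intake daily intake (L/day or g/day); vectorised.
#' @param bw body weight, kg, strictly positive; vectorised.
#' @return dose in mg/kg/day.
#' @examples
#' compute_add(9.10e-5, 14.3, 6.95)  # rice cereal at central values
#' @export
compute_add <- function(conc, intake, bw) {
  if (any(bw <= 0)) stop("body weight must be strictly positive")
  conc * intake / bw
}

#' Per-source daily intakes for one age band
#'
#' Combines sampled quantities into the four source intakes: water is the
#' direct draw (L/day); formula is grams dry per serving times servings per
#' day; rice cereal is the direct draw (g dry/day); other solid food sums
#' fruit, vegetable and meat serving totals, with absent foods contributing
#' zero.
#'
#' @param draws a named list of equal-length vectors: `v_w`, `v_if_g`,
#'   `v_if_n`, `v_rc`, and optionally `v_fr_g`/`v_fr_n`, `v_v_g`/`v_v_n`,
#'   `v_m_g`/`v_m_n`.
#' @return list with vectors `water` (L/day), `formula`, `rice_cereal`,
#'   `other_solid` (g/day).
#' @export
band_intakes <- function(draws) {
  other <- 0
  for (f in c("v_fr", "v_v", "v_m")) {
    g <- draws[[paste0(f, "_g")]]
    if (!is.null(g)) other <- other + g * draws[[paste0(f, "_n")]]
  }
  list(water = draws$v_w,
       formula = draws$v_if_g * draws$v_if_n,
       rice_cereal = draws$v_rc,
       other_solid = other)
}

#' Chronic daily intake: month-weighted mean ADD over 4-24 months
#'
#' @param add_by_band matrix (iterations x bands) or vector of band ADDs.
#' @param month_weights months covered by each band; must sum to the total
#'   number of monthly ages (21 for the canonical 4-24 month window).
#' @param total_months expected weight sum; set `NULL` to skip the check.
#' @return CDI per iteration (vector), mg/kg/day.
#' @examples
#' compute_cdi(c(2.3, 2.9, 3.0, 4.9, 4.4, 4.8) * 1e-4, c(2, 3, 3, 3, 4, 6))
#' @export
compute_cdi <- function(add_by_band, month_weights, total_months = 21L) {
  if (!is.null(total_months) && sum(month_weights) != total_months)
    stop(sprintf("month weights sum to %s, expected %s",
                 sum(month_weights), total_months))
  if (is.matrix(add_by_band)) {
    stopifnot(ncol(add_by_band) == length(month_weights))
    drop(add_by_band %*% month_weights) / sum(month_weights)
  } else {
    stopifnot(length(add_by_band) == length(month_weights))
    sum(add_by_band * month_weights) / sum(month_weights)
  }
}

#' Lifetime average daily dose
#'
#' @param cdi chronic daily intake, mg/kg/day (vectorised).
#' @param ed_days exposure duration in days (620 for 4-24 months).
#' @param at_days averaging time in days (25,550 for 70 years).
#' @return LADD, mg/kg/day.
#' @export
compute_ladd <- function(cdi, ed_days, at_days) {
  if (at_days <= 0) stop("averaging time must be positive")
  cdi * ed_days / at_days
}

#' Largest band ADD within the exposure window
#'
#' @param add_by_band matrix (iterations x bands) or vector of band ADDs.
#' @return per-iteration maximum ADD, mg/kg/day.
#' @export
compute_add_max <- function(add_by_band) {
  if (is.matrix(add_by_band)) {
    if (ncol(add_by_band) == 0) stop("no bands")
    do.call(pmax, lapply(seq_len(ncol(add_by_band)),
                         function(j) add_by_band[, j]))
  } else {
    if (length(add_by_band) == 0) stop("no bands")
    max(add_by_band)
  }
}
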