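#' Maximum contaminant level for rice cereal
#'
#' Risk management back-calculates the largest inorganic-arsenic
#' concentration in rice cereal consistent with a safe dose, given exposure
#' from all other sources. Per band,
#' \deqn{(MRL \cdot BW_t - (MCL_w V_{w,t} + C_{if} V_{if,t} +
#'       C_o (V_{fr,t} + V_{v,t} + V_{m,t}))) / V_{rc,t}}
#' and the reported MCL is the month-weighted mean over bands, evaluated per
#' Monte Carlo iteration. The water term is fixed at the regulatory
#' drinking-water MCL (0.010 mg/L), never sampled: the back-calculation
#' budgets for the worst permitted water. Raw values may be negative when
#' other sources alone exceed the safe dose (the chronic endpoint does);
#' negatives are preserved internally and clamped to 0.0 only at reporting.
#'
#' @name mcl
NULL

#' Per-band allowable rice-cereal concentration
#'
#' @param mrl minimal risk level, mg/kg/day.
#' @param bw body weight, kg (vectorised).
#' @param other_dose total daily contaminant mass from all non-rice sources,
#'   mg/day (vectorised).
#' @param v_rc rice-cereal intake, g/day, strictly positive (vectorised).
#' @return allowable concentration, mg/g; may be negative.
#' @examples
#' mcl_per_band(5e-3, 10, 0, 50)  # 1e-3 mg/g with no other sources
#' @export
mcl_per_band <- function(mrl, bw, other_dose, v_rc) {
  if (any(v_rc <= 0)) stop("rice-cereal intake must be strictly positive")
  (mrl * bw - other_dose) / v_rc
}

#' Summarize an MCL distribution at a reporting percentile
#'
#' The protective reporting convention takes a low percentile of the
#' allowable-concentration distribution (default 25th: a level safe even for
#' children whose circumstances allow little headroom). Negative raw values
#' are clamped to 0.0 in the report and flagged.
#'
#' @param values per-iteration MCL values, mg/g (may contain negatives).
#' @param percentile reporting percentile in (0, 100); default 25.
#' @return a list of class `mcl_result`: `mcl` (clamped, mg/g), `raw`
#'   (unclamped percentile), `clamped` flag, `percentile_basis`.
#' @export
summarize_mcl <- function(values, percentile = 25) {
  stopifnot(length(values) > 0, percentile > 0, percentile < 100)
  raw <- unname(quantile(values, percentile / 100, type = 7))
  structure(list(mcl = max(raw, 0), raw = raw, clamped = raw < 0,
                 percentile_basis = percentile),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("MCL %.3g mg/g (%.3g mg/kg) at the %gth percentile%s\n",
              x$mcl, x$mcl * 1000, x$percentile_basis,
              if (x$clamped) sprintf(" [raw %.3g clamped to 0.0]", x$raw) else ""))
  invisible(x)
}
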