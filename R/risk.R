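#' Risk characterization
#'
#' Non-cancer risk is expressed as hazard quotients against the ATSDR
#' minimal risk levels: \eqn{HQ_{acute} = ADD_{max} / MRL_{acute}} uses the
#' largest band dose in the exposure window, \eqn{HQ_{chronic} = CDI /
#' MRL_{chronic}} the mean dose. An HQ at or below 1 means no adverse
#' non-cancer effect is expected. Cancer risk is linear in lifetime dose:
#' \eqn{ILCR = CSF \cdot LADD}, with the EPA slope factor 1.5 (mg/kg/day)^-1
#' by default and 3.6 as a discussed alternative (exactly 2.4 times higher
#' risk for the same dose).
#'
#' All maps are linear and strictly monotone in their dose argument, so
#' percentiles of per-iteration risk equal risk evaluated at dose
#' percentiles.
#'
#' @name risk
NULL

#' Acute hazard quotient
#'
#' @param add_max largest band ADD, mg/kg/day (vectorised).
#' @param mrl_acute acute minimal risk level, mg/kg/day.
#' @return dimensionless HQ.
#' @examples
#' hq_acute(8.2e-4, 5.0e-3)  # 0.164
#' @export
hq_acute <- function(add_max, mrl_acute) {
  if (mrl_acute <= 0) stop("mrl_acute must be positive")
  add_max / mrl_acute
}

#' Chronic hazard quotient
#'
#' @param cdi chronic daily intake, mg/kg/day (vectorised).
#' @param mrl_chronic chronic minimal risk level, mg/kg/day.
#' @return dimensionless HQ.
#' @examples
#' hq_chronic(4.0e-4, 3.0e-4)  # 1.33
#' @export
hq_chronic <- function(cdi, mrl_chronic) {
  if (mrl_chronic <= 0) stop("mrl_chronic must be positive")
  cdi / mrl_chronic
}

#' Incremental lifetime cancer risk
#'
#' @param ladd lifetime average daily dose, mg/kg/day (vectorised).
#' @param csf cancer slope factor, (mg/kg/day)^-1.
#' @return lifetime excess cancer probability.
#' @examples
#' ilcr(9.5e-6, 1.5)  # 1.4e-5
#' @export
ilcr <- function(ladd, csf) {
  if (csf <= 0) stop("csf must be positive")
  csf * ladd
}

#' Source contribution shares at a percentile
#'
#' Each source's percentile CDI divided by the all-sources percentile CDI,
#' as a percentage. Because percentiles are not additive, the shares need
#' not sum to exactly 100 (the canonical scenario's published shares sum to
#' 101).
#'
#' @param cdi_by_source named numeric vector of per-source CDIs at one
#'   percentile.
#' @param cdi_total the total-sources CDI at the same percentile; must be
#'   positive.
#' @return named percentages.
#' @examples
#' source_shares(c(rice_cereal = 4.0e-4), 7.3e-4)  # about 55%
#' @export
source_shares <- function(cdi_by_source, cdi_total) {
  if (cdi_total <= 0) stop("total CDI must be positive")
  100 * cdi_by_source / cdi_total
}
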