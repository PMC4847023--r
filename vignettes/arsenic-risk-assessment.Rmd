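---
title: "Probabilistic assessment of dietary inorganic arsenic exposure in infants and toddlers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic assessment of dietary inorganic arsenic exposure in infants and toddlers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asirisk)
```

## The exposure model

Rice cereal is one of the most common first solid foods in the U.S., and rice
accumulates inorganic arsenic (As~i~) at higher levels than other crops.
`asirisk` implements a probabilistic dietary risk assessment for U.S. infants
and toddlers aged 4–24 months, covering the four exposure routes that matter
at that age: drinking water, infant formula, rice cereal, and other infant
solid food (fruit and vegetable purees, meats).

The model is a chain of standard exposure-assessment quantities. For source
$x$ and monthly age $t$, the average daily dose is

$$ADD_{x,t} = \frac{C_x \, V_{x,t}}{BW_t} \quad \text{(mg/kg/day)},$$

with $C_x$ the As~i~ concentration in the source, $V_{x,t}$ the daily intake,
and $BW_t$ the body weight. The chronic daily intake averages the dose over
the 21 monthly ages,

$$CDI = \frac{1}{21}\sum_{t=4}^{24} ADD_{x,t},$$

and the lifetime average daily dose prorates it over a 70-year averaging
time: $LADD = CDI \cdot ED/AT$ with $ED = 620$ days (20 months) and
$AT = 25{,}550$ days. Risk is characterized by hazard quotients against the
ATSDR minimal risk levels ($HQ_{acute} = ADD_{max}/MRL_{acute}$ with
$MRL_{acute} = 5.0\times10^{-3}$ mg/kg/day; $HQ_{chronic} = CDI/MRL_{chronic}$
with $MRL_{chronic} = 3.0\times10^{-4}$ mg/kg/day) and by the linear cancer
model $ILCR = CSF \cdot LADD$ with slope factor 1.5 (mg/kg/day)^-1^ (3.6 as a
discussed alternative, giving exactly 2.4× the risk).

Risk management inverts the dose budget: the maximum contaminant level for
As~i~ in rice cereal, given all other sources, is per band

$$\bigl(MRL \cdot BW_t - (MCL_w V_{w,t} + C_{if} V_{if,t} + C_o V_{o,t})\bigr) / V_{rc,t},$$

with the water term fixed at the regulatory drinking-water MCL (0.010 mg/L),
never sampled: the back-calculation budgets for the worst permitted water.

All parameters are distributions (uniform for water concentration, wide
normals for intakes, a triangular for the rice-cereal concentration), so
every quantity is simulated by Monte Carlo (one million iterations in the
canonical configuration) and summarized at the 25th/50th/75th percentiles.

## The canonical scenario and its units

`us_infant_scenario()` bundles the full parameterization: four concentration
distributions, six age bands (4–5, 6–8, 9–11, 12–14, 15–18, 19–24 months,
partitioning the 21 monthly ages), and the toxicology constants. It ships as
a versioned YAML file whose keys carry units
(`inst/extdata/us_infant_scenario.yaml`), and `load_scenario()` rejects
unknown keys and schema violations with the offending path named.

Two unit decisions deserve note:

* **Formula concentration.** The formula concentration is applied as mg per
  gram of *dry* formula (7.48×10⁻⁶ ± 6.12×10⁻⁷), matching the formula-intake
  units (g dry/serving, 4.3 g dry per fluid ounce). Only under this reading
  do the formula doses come out at the 10⁻⁴ mg/kg/day scale the dose table
  reports (7.48×10⁻⁶ × ~97 g/day ÷ 6.95 kg ≈ 1.0×10⁻⁴); an mg/L reading
  would be three orders of magnitude off.
* **Household conversions.** The tablespoon/cup constants are stored exactly
  as published even though the fruit/vegetable pair (16.3 g/tbsp, 26.08
  g/cup) is mutually inconsistent; `convert_units()` is a documentation aid,
  the band intake distributions are already in grams.

## Sampling choices

**Clamping, not rejection.** Several intake normals are wide enough to put
substantial mass below zero (e.g. rice cereal at 12–14 months: 44.2 ± 70.9
g/day, 27% negative). A negative draw is kept and set to 0.0 — a
non-consumption day — rather than redrawn. This is what produces the exact
0.0 entries at the 25th percentile of the dose table; a rejection rule would
erase them and shift every mean upward. The one exception is body weight,
which is a divisor: a non-positive draw (probability ~10⁻¹⁶ at the canonical
parameters) is redrawn, never clamped.

**The water-intake triplets.** The water volumes are given as triplets
labelled 10th/50th/90th percentiles of a triangular. That label cannot be
taken literally: a continuous triangular always has its 10th percentile
strictly above its minimum, so p10 = 0 forces a negative minimum — and the
skew of these triplets, (p50−p10)/(p90−p10) ≈ 0.16, is outside the range any
triangular can achieve (about 0.38–0.62; see
`fit_triangular_from_percentiles()`). The default therefore interprets the
triplets as (min, mode, max), the same style the rice-cereal concentration
uses, which also reproduces the published water doses.
`water_triplet = "p10_p50_p90"` switches to the best-effort percentile fit
(p10 and p90 anchored exactly, negative tail clamped at zero, so the
labelled p10 = 0 reappears as a 10% atom at zero).

**Serving counts.** Feeding frequencies ("3–4 servings/day") default to
discrete-uniform integers — a feeding either happens or not — with a
continuous-uniform option, since the source tables do not state the rule.
Meat is absent before 6 months and contributes a structural zero.

**Correlation structure.** Within an iteration the four concentrations are
drawn once and shared across age bands — a child keeps the same water source
and product brands while ageing — whereas body weights, volumes and serving
counts are drawn independently per band (`concentration_mode =
"independent"` removes the sharing). This matters for the spread of
CDI-type averages but little for their medians.

**Reproducibility.** All draws run off a single root seed through labelled
substreams (one per concentration, one per band quantity), so equal seeds
give bit-identical results, chunked execution (`chunk_size`) equals
single-pass execution exactly, and changing one source's parameters leaves
every other source's draws untouched — which the test suite exploits for
exact scale-equivariance checks.

## Reporting conventions

Percentiles use linear interpolation between order statistics
(`quantile(type = 7)`), stated explicitly because spreadsheet Monte Carlo
add-ins do not document theirs. Percentile cells carry distribution-free
Monte Carlo standard errors derived from order-statistic confidence
intervals (`$se`), cheaper than a bootstrap and accurate at these sample
sizes.

Three summary conventions are deliberate and worth understanding, because
with skewed, zero-inflated inputs "the percentile of a combination" and "the
combination of percentiles" differ noticeably:

* **CDI, LADD, HQ~chronic~, ILCR** are percentiles of per-iteration values:
  each simulated child gets a full dose trajectory, and the distribution is
  summarized at the end. These run some 20–25% above what one gets by
  averaging the dose table's percentile columns, because averaging before
  taking the median undoes the skew-induced deflation of per-band medians.
* **ADD~max~ and HQ~acute~** are reported from the dose table itself: the
  band with the highest dose at each percentile. The max operator is not a
  monotone scalar transform, so percentiles of per-iteration maxima are a
  different (and ~2× larger) quantity — the maximum is then attained in
  different bands across iterations. The per-iteration maxima remain
  available under `keep_draws = TRUE`.
* **Source shares** describe the composition of the median exposure profile:
  each source's median CDI over the sum of the four source median CDIs, so
  they total 100% by construction. Dividing by the median of the
  per-iteration total instead (attribute `vs_total_percentile`) gives shares
  that need not sum to 100%, because percentiles are not additive.

**MCL aggregation.** The per-band allowable concentrations must be combined
into one number, and two conventions are provided. `mcl_aggregation =
"months"` weights each band by the months it spans — the same weighting the
CDI uses. The default, `"bands"`, counts each band profile once against the
21 monthly data sets; it is the convention under which this assessment's
risk-management levels are defined, and it yields materially lower (more
protective) levels — the two differ by roughly the ratio of band count to
month count:

```{r mcl-modes, eval = FALSE}
fit_b <- arsenic_risk(n_iterations = 1e5, mcl_aggregation = "bands")
fit_m <- arsenic_risk(n_iterations = 1e5, mcl_aggregation = "months")
c(bands = fit_b$mcl$acute$mcl, months = fit_m$mcl$acute$mcl) * 1000  # mg/kg
```

For the MCL back-calculation the rice-cereal intake divides, so the clamped
zeros are inadmissible; the default redraws it conditional on consumption
(> 0 g/day, exact inverse-CDF truncation) on the grounds that a contaminant
limit is only meaningful for consumers, with `mcl_rice_intake = "band_mean"`
as a sensitivity alternative. Raw negative MCLs (the chronic endpoint: other
sources alone already exceed the chronic safe dose) are preserved internally
and clamped to 0.0 only at reporting, with a flag — 0.0 is then read as a
maximum contaminant level *goal*, not an enforceable level.

## Scenario tools and the closed-form oracle

Because the model is arithmetic over sampled inputs, it admits an exact
oracle. `degenerate_scenario()` collapses every distribution to its central
point mass (uniform → midpoint, normal → mean, triangular → mode, serving
ranges → midpoint rounded down — the conservative integer choice,
documented since either rounding is defensible), and
`closed_form_oracle()` evaluates every pipeline quantity by direct
arithmetic, bypassing the sampling machinery entirely. The test suite
requires Monte Carlo output on a degenerate scenario to match the oracle in
every cell to a relative 10⁻¹². `perturbed_scenario()` applies seeded
multiplicative lognormal jitter per parameter class (one factor per
distribution, so orderings survive) for robustness and monotonicity tests.

What the generated scenarios do *not* emulate: real diets correlate
consumption across foods and over time (a child who eats much cereal this
month likely did last month too), consumption frequency is irregular rather
than daily, and concentrations vary by brand and lot around the fitted
distributions. Passing tests therefore demonstrate correctness of the
simulation given the stated distributions, not validity of those
distributions for any particular child.

## Problem sizes and runtime

The canonical configuration uses 10⁶ iterations (a few seconds and ~1 GB
at these problem sizes). The test suite and the acceptance script run the
full scenario at 10⁵ iterations, where percentile estimates carry Monte
Carlo standard errors of a few tenths of a percent — an order of magnitude
below the coarseness of two-significant-figure reporting — and the
iteration-stability test checks that medians at 10⁵ and 10⁶ agree within
2% in every cell.

## Known limitations

* The exposure window model charges a lifetime cancer risk to a 20-month
  window; dose-rate effects over a lifetime are not modelled.
* Organic/inorganic speciation is folded into the concentration parameters;
  no speciation chemistry is modelled.
* The 6–8-month other-solid-food dose has a heavier low tail in published
  summaries than the stated distributions can produce (its zero mass
  computes to ~21%, short of the 25% needed for an exact-zero 25th
  percentile); the discrepancy is confined to that cell's lowest quantiles.
* Intake distributions resolve to age bands, so within-band ageing is a
  step function.
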