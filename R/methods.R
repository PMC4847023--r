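#' @export
print.arsenic_risk <- function(x, digits = 2, ...) {
  cat("Monte Carlo risk assessment of dietary inorganic arsenic\n")
  cat(sprintf("  %s iterations, seed %d, CSF %g (mg/kg/day)^-1\n",
              format(x$n_iterations, big.mark = ","), x$seed, x$csf))
  cat(sprintf("  config digest %s\n\n", x$manifest$config_digest))
  cat("Dose and risk summary (columns: percentiles):\n")
  for (s in dimnames(x$metrics)[[2]]) {
    cat(sprintf("  %s:\n", s))
    print(signif(x$metrics[, s, ], digits))
  }
  cat("\nSource shares of the median dose composition (%):\n")
  sh <- round(x$shares, 1)
  attributes(sh) <- attributes(sh)["names"]
  print(sh)
  cat("\nRice-cereal MCL (protective", paste0(x$mcl$acute$percentile_basis, "th"),
      "percentile):\n  acute:   ")
  print(x$mcl$acute)
  cat("  chronic: ")
  print(x$mcl$chronic)
  invisible(x)
}

#' Summarize a risk-assessment run
#'
#' @param object an [arsenic_risk()] result.
#' @param digits significant digits for printing.
#' @param ... unused.
#' @return `object`, invisibly; prints the full dose table by age band and
#'   source in addition to the headline metrics.
#' @export
summary.arsenic_risk <- function(object, digits = 2, ...) {
  print(object, digits = digits)
  cat("\nAverage daily dose (mg/kg/day) by age band and source:\n")
  for (p in dimnames(object$add_table)[[3]]) {
    cat(sprintf("  %s:\n", p))
    print(signif(object$add_table[, , p], digits))
  }
  invisible(object)
}

#' Extract result tables as data frames
#'
#' @param x an [arsenic_risk()] result.
#' @param table which table: `"add"` (band x source x percentile doses),
#'   `"metrics"` (dose/risk summary), `"shares"`, or `"mcl"`.
#' @param ... unused.
#' @return a long-format `data.frame`.
#' @export
as.data.frame.arsenic_risk <- function(x, table = c("add", "metrics",
                                                    "shares", "mcl"), ...) {
  table <- match.arg(table)
  switch(table,
    add = {
      d <- as.data.frame.table(x$add_table, stringsAsFactors = FALSE)
      names(d) <- c("band", "source", "percentile", "add_mg_kg_day")
      d
    },
    metrics = {
      d <- as.data.frame.table(x$metrics, stringsAsFactors = FALSE)
      names(d) <- c("metric", "scope", "percentile", "value")
      d
    },
    shares = data.frame(source = names(x$shares),
                        share_pct = unname(x$shares),
                        mean_share_pct = unname(attr(x$shares, "mean_share")),
                        row.names = NULL),
    mcl = data.frame(
      endpoint = c("acute", "chronic"),
      mcl_mg_per_g = c(x$mcl$acute$mcl, x$mcl$chronic$mcl),
      raw_mg_per_g = c(x$mcl$acute$raw, x$mcl$chronic$raw),
      clamped = c(x$mcl$acute$clamped, x$mcl$chronic$clamped),
      percentile_basis = c(x$mcl$acute$percentile_basis,
                           x$mcl$chronic$percentile_basis)))
}

#' Plot median doses by age band, stacked by source
#'
#' A stacked bar chart of the median (or other reported percentile) average
#' daily dose per age band, decomposed by exposure source.
#'
#' @param x an [arsenic_risk()] result.
#' @param percentile which reported percentile to draw (default 50).
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot.arsenic_risk <- function(x, percentile = 50, ...) {
  pn <- paste0("p", percentile)
  if (!pn %in% dimnames(x$add_table)[[3]])
    stop(sprintf("percentile %g was not reported by this run", percentile))
  m <- t(x$add_table[, SOURCES, pn])
  cols <- grDevices::hcl.colors(length(SOURCES), "Zissou 1")
  mid <- graphics::barplot(m, col = cols, border = NA,
                           xlab = "Age (months)",
                           ylab = sprintf("ADD at %sth percentile (mg/kg/day)",
                                          percentile),
                           legend.text = rownames(m),
                           args.legend = list(x = "topleft", bty = "n"), ...)
  invisible(mid)
}

#' Draw fresh per-iteration dose and risk realizations
#'
#' Re-runs the fitted scenario for `nsim` fresh iterations and returns the
#' per-iteration metrics, for diagnostics beyond the stored percentile
#' summaries.
#'
#' @param object an [arsenic_risk()] result.
#' @param nsim number of iterations to draw.
#' @param seed seed for the new draws (defaults to the object's seed + 1 so
#'   simulations do not replay the fitting draws).
#' @param ... unused.
#' @return a `data.frame` with one row per iteration: CDI, ADD_max, LADD,
#'   HQ_acute, HQ_chronic and ILCR for the rice-cereal and total scopes.
#' @export
simulate.arsenic_risk <- function(object, nsim = 1000, seed = NULL, ...) {
  seed <- seed %||% (object$seed + 1L)
  re <- arsenic_risk(object$scenario, n_iterations = nsim, seed = seed,
                     csf = object$csf, percentiles = object$percentiles,
                     concentration_mode = object$settings$concentration_mode,
                     serving_mode = object$settings$serving_mode,
                     mcl_rice_intake = object$settings$mcl_rice_intake,
                     mcl_aggregation = object$settings$mcl_aggregation,
                     keep_draws = TRUE)
  out <- data.frame(iteration = seq_len(nsim))
  for (s in c("rice_cereal", "total"))
    for (m in c("cdi", "add_max", "ladd", "hq_acute", "hq_chronic", "ilcr"))
      out[[paste(s, m, sep = ".")]] <- re$draws[[s]][[m]]
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> digest %s, seed %d, %s iterations, v%s, %s\n",
              x$config_digest, x$seed, format(x$n_iterations, big.mark = ","),
              x$package_version, x$timestamp))
  invisible(x)
}
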