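#' Machine-readable output bundle
#'
#' [write_risk_tables()] writes a completed run to a directory of delimited
#' text files — `add_table.csv` (dose table by band, source and percentile),
#' `metrics.csv` (dose/risk summary), `shares.csv`, `mcl.csv` — plus a YAML
#' `manifest.yaml` recording the configuration digest, seed and iteration
#' count. Numeric columns are written with 17 significant digits so the
#' files round-trip to the in-memory tables without loss;
#' [read_risk_tables()] reads a bundle back.
#'
#' @param x an [arsenic_risk()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_risk_tables <- function(x, dir) {
  stopifnot(inherits(x, "arsenic_risk"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(d, file) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(col) format(col, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE))
    utils::write.csv(d, file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  emit(as.data.frame(x, "add"), "add_table.csv")
  emit(as.data.frame(x, "metrics"), "metrics.csv")
  emit(as.data.frame(x, "shares"), "shares.csv")
  emit(as.data.frame(x, "mcl"), "mcl.csv")
  yaml::write_yaml(unclass(x$manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_risk_tables
#' @return `read_risk_tables()`: a list with data frames `add`, `metrics`,
#'   `shares`, `mcl` and the `manifest` list.
#' @export
read_risk_tables <- function(dir) {
  rd <- function(file) utils::read.csv(file.path(dir, file))
  list(add = rd("add_table.csv"), metrics = rd("metrics.csv"),
       shares = rd("shares.csv"), mcl = rd("mcl.csv"),
       manifest = yaml::read_yaml(file.path(dir, "manifest.yaml")))
}
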