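#' Household-measure unit conversions for infant foods
#'
#' Gram equivalents used to convert published serving sizes (tablespoons,
#' cups, fluid ounces, ounces) to the gram or gram-dry-weight amounts the
#' dose equations use: dry rice cereal 4.6 g/tbsp and 73.6 g/cup; fruits and
#' vegetables 16.3 g/tbsp and 26.08 g/cup (stored exactly as published even
#' though the two are mutually inconsistent — see the package vignette);
#' meats 16.3 g/tbsp and 28.35 g/oz; infant formula 4.3 g dry per fluid
#' ounce.
#'
#' @return a named list of conversion constants, grams per unit, keyed
#'   `"<food>.<unit>"`.
#' @export
unit_conversions <- function() {
  list(
    dry_cereal.tbsp = 4.6,
    dry_cereal.cup  = 73.6,
    fruit_veg.tbsp  = 16.3,
    fruit_veg.cup   = 26.08,
    meat.tbsp       = 16.3,
    meat.oz         = 28.35,
    formula.fl_oz   = 4.3
  )
}

#' Convert a household measure to grams
#'
#' @param amount numeric amount in the given unit.
#' @param unit one of `"tbsp"`, `"cup"`, `"oz"`, `"fl_oz"`.
#' @param food one of `"dry_cereal"`, `"fruit_veg"`, `"meat"`, `"formula"`.
#' @return grams (grams dry weight for `"dry_cereal"` and `"formula"`).
#' @examples
#' convert_units(1, "tbsp", "dry_cereal")  # 4.6 g
#' convert_units(2, "fl_oz", "formula")    # 8.6 g dry
#' @export
convert_units <- function(amount, unit, food) {
  key <- paste(food, unit, sep = ".")
  const <- unit_conversions()[[key]]
  if (is.null(const))
    stop(sprintf("no conversion defined for unit '%s' of food '%s'", unit, food))
  amount * const
}
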