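# Canonical base units per dimension: ng/L (concentration), L/day (flow),
# ng/day (mass rate). Factors are exact powers of ten so conversions are a
# single multiply or divide and round-trip cleanly.
.pfas_units <- list(
  concentration = c("ng/L" = 1, "ug/L" = 1e3, "ng/mL" = 1e3, "mg/L" = 1e6),
  flow          = c("L/day" = 1),
  mass_rate     = c("ng/day" = 1, "ug/day" = 1e3, "mg/day" = 1e6)
)

.unit_lookup <- function(unit) {
  for (dim in names(.pfas_units)) {
    f <- .pfas_units[[dim]]
    if (unit %in% names(f)) return(list(dim = dim, factor = unname(f[unit])))
  }
  stop("unsupported unit: '", unit, "'", call. = FALSE)
}

#' Convert between the pipeline's supported units
#'
#' Exact decimal scaling within one dimension (concentration, flow, or
#' mass rate). Conversions across dimensions (e.g. ng/L to mg/day) are an
#' error: they need a flow or volume and belong to [daily_load()] /
#' [pndl()].
#'
#' @param value numeric vector.
#' @param from,to unit strings; supported: `"ng/L"`, `"ug/L"`, `"ng/mL"`,
#'   `"mg/L"`, `"L/day"`, `"ng/day"`, `"ug/day"`, `"mg/day"`.
#' @return numeric vector in `to` units.
#' @examples
#' convert_units(0.01, "ug/L", "ng/L") # 10
#' convert_units(1.935e9, "ng/day", "mg/day") # 1935
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  uf <- .unit_lookup(from)
  ut <- .unit_lookup(to)
  if (uf$dim != ut$dim) {
    stop("cannot convert '", from, "' to '", to,
         "': different dimensions (", uf$dim, " vs ", ut$dim, ")",
         call. = FALSE)
  }
  if (uf$factor >= ut$factor) value * (uf$factor / ut$factor)
  else value / (ut$factor / uf$factor)
}
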