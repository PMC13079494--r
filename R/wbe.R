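# Wastewater-based-epidemiology aggregation: censoring substitution,
# detection frequencies, daily loads and population-normalised loads.

.censor_levels <- c("detected", "below_LOQ", "below_LOD")

.check_censor <- function(censor) {
  bad <- setdiff(unique(censor), .censor_levels)
  if (length(bad) > 0L) {
    stop("invalid censor mark(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible()
}

#' Numeric contribution of a possibly censored concentration
#'
#' Days below the detection or quantification limit contribute zero to
#' cumulative sums (substitution at zero). This is the convention that
#' makes aggregated campaign tables reconcile exactly with their per-day
#' entries; LOD/2-style substitutions are deliberately not offered.
#'
#' @param value concentration in ng/L (`NA` allowed when censored).
#' @param censor `"detected"`, `"below_LOQ"` or `"below_LOD"`.
#' @return numeric vector, 0 for censored entries.
#' @export
censor_for_aggregation <- function(value, censor) {
  .check_censor(censor)
  n <- max(length(value), length(censor))
  value <- rep_len(value, n)
  censor <- rep_len(censor, n)
  if (any(censor == "detected" & is.na(value))) {
    stop("detected entries must carry a value", call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ifelse(censor == "detected", value, 0)
}

#' Detection frequency over a set of days
#'
#' Counts days on which the analyte was detected at all -- a `<LOQ` day
#' (detected but not quantifiable) counts, a `<LOD` day does not.
#'
#' @param censor vector of censor marks.
#' @return integer count.
#' @export
detection_frequency <- function(censor) {
  .check_censor(censor)
  sum(censor != "below_LOD")
}

#' Daily mass load entering the treatment works
#'
#' `DL (mg/day) = C (mg/L) * V (L/day)`; the concentration is supplied
#' in ng/L and converted explicitly.
#'
#' @param conc_ngL concentration, ng/L, >= 0.
#' @param flow_L_day flow entering the works, L/day, >= 0.
#' @return load in mg/day.
#' @examples
#' daily_load(50, 1e8)  # 5000 mg/day
#' @export
daily_load <- function(conc_ngL, flow_L_day) {
  if (any(conc_ngL < 0) || any(flow_L_day < 0)) {
    stop("concentration and flow must be >= 0", call. = FALSE)
  }
  convert_units(conc_ngL, "ng/L", "mg/L") * flow_L_day
}

#' Population-normalised daily load
#'
#' `PNDL = DL / P * 1000`, reported in ug/day per 1000 inhabitants (the
#' unit campaign tables are reported in), with the mg-to-ug conversion
#' made explicitly.
#'
#' @param dl_mg_day daily load, mg/day.
#' @param population inhabitants served, > 0.
#' @return ug/day per 1000 inhabitants.
#' @export
pndl <- function(dl_mg_day, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  convert_units(dl_mg_day, "mg/day", "ug/day") / population * 1000
}

#' Aggregate an influent campaign into loads per analyte
#'
#' For each analyte: detection frequency, cumulative concentration
#' (censored days contribute zero), cumulative daily load using each
#' day's own flow, and cumulative population-normalised daily load. The
#' `+- sd` columns are the standard deviation across the detected
#' per-day values (and their loads), zero when fewer than two days were
#' detected -- the dispersion measure the campaign tables report.
#'
#' @param conc tibble with `analyte_name`, `day_id`, `value_ngL`,
#'   `censor`.
#' @param site_days tibble from [load_site_days()]; every detected day
#'   must have a flow record.
#' @return tibble, one row per analyte: `detection_frequency`,
#'   `cumulative_conc` (ng/L) `+- conc_sd`, `cumulative_dl` (mg/day)
#'   `+- dl_sd`, `cumulative_pndl` (ug/day/1000 inh) `+- pndl_sd`.
#' @export
aggregate_campaign <- function(conc, site_days) {
  stopifnot(all(c("analyte_name", "day_id", "value_ngL", "censor") %in%
                  names(conc)),
            all(c("day_id", "flow_L_day", "population") %in% names(site_days)))
  .check_censor(conc$censor)
  idx <- match(conc$day_id, site_days$day_id)
  missing_day <- conc$censor == "detected" & is.na(idx)
  if (any(missing_day)) {
    stop("no site record (flow/population) for detected day(s): ",
         paste(unique(conc$day_id[missing_day]), collapse = ", "),
         call. = FALSE)
  }
  conc$flow <- site_days$flow_L_day[idx]
  conc$pop <- site_days$population[idx]

  one <- function(d) {
    v <- censor_for_aggregation(d$value_ngL, d$censor)
    det <- d$censor == "detected"
    dl <- numeric(nrow(d))
    dl[det] <- daily_load(v[det], d$flow[det])
    pn <- numeric(nrow(d))
    pn[det] <- pndl(dl[det], d$pop[det])
    sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else 0
    tibble::tibble(
      analyte_name = d$analyte_name[1L],
      detection_frequency = detection_frequency(d$censor),
      cumulative_conc = sum(v), conc_sd = sd0(v[det]),
      cumulative_dl = sum(dl), dl_sd = sd0(dl[det]),
      cumulative_pndl = sum(pn), pndl_sd = sd0(pn[det]))
  }
  parts <- lapply(split(conc, factor(conc$analyte_name,
                                     levels = unique(conc$analyte_name))),
                  one)
  dplyr::bind_rows(parts)
}
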