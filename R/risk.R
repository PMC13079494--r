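# Environmental risk quotients against the freshwater PNEC registry.

#' Risk quotient
#'
#' `RQ = MEC / PNEC`, optionally under a dilution scenario (the measured
#' environmental concentration divided by `dilution` before the
#' quotient; a tenfold dilution into the receiving water is a common
#' assumption for combined sewer overflows). Censored days enter with
#' `MEC = 0` and yield `RQ = 0`.
#'
#' @param mec measured environmental concentration, ng/L, >= 0.
#' @param pnec predicted no-effect concentration, ng/L, > 0.
#' @param dilution dilution factor, >= 1 (default 1 = undiluted).
#' @return dimensionless RQ.
#' @examples
#' risk_quotient(176.2, 73.3)  # 2.40...
#' @export
risk_quotient <- function(mec, pnec, dilution = 1) {
  if (any(pnec <= 0)) stop("pnec must be > 0", call. = FALSE)
  if (any(dilution < 1)) stop("dilution must be >= 1", call. = FALSE)
  if (any(mec < 0)) stop("mec must be >= 0", call. = FALSE)
  mec / dilution / pnec
}

#' Risk band from a risk quotient
#'
#' Low risk for RQ < 0.1, medium for 0.1 <= RQ < 1, high for RQ >= 1
#' (half-open intervals; the boundaries 0.1 and 1 belong to the upper
#' band).
#'
#' @param rq risk quotient, >= 0.
#' @return character vector: `"low"`, `"medium"`, `"high"`.
#' @export
classify_risk <- function(rq) {
  if (any(rq < 0)) stop("rq must be >= 0", call. = FALSE)
  ifelse(rq >= 1, "high", ifelse(rq >= 0.1, "medium", "low"))
}

#' Risk-assess an influent campaign against the PNEC registry
#'
#' Computes a per-day risk quotient for every analyte present in the
#' PNEC registry (other analytes are not assessable and are dropped with
#' a message). Censored days enter at MEC 0. The highest single-day RQ
#' per analyte is flagged as the headline value -- single-day measured
#' concentrations are environmental concentrations, cumulative sums
#' across days are not. `rq_2sf` carries the display rounding (two
#' significant figures); `rq` keeps full precision.
#'
#' @param conc tibble with `analyte_name`, `day_id`, `value_ngL`,
#'   `censor`.
#' @param pnec_registry tibble from [load_pnec_registry()].
#' @param dilution dilution factor applied to every MEC.
#' @return tibble: `analyte_name`, `day_id`, `mec`, `pnec`,
#'   `dilution_factor`, `rq`, `rq_2sf`, `band`, `headline`.
#' @export
assess_campaign <- function(conc, pnec_registry, dilution = 1) {
  stopifnot(all(c("analyte_name", "day_id", "value_ngL", "censor") %in%
                  names(conc)),
            all(c("analyte_name", "pnec_ngL") %in% names(pnec_registry)))
  known <- conc$analyte_name %in% pnec_registry$analyte_name
  skipped <- setdiff(unique(conc$analyte_name[!known]),
                     pnec_registry$analyte_name)
  if (length(skipped) > 0L) {
    message(length(skipped),
            " analyte(s) without a PNEC record not assessed")
  }
  d <- conc[known, ]
  if (nrow(d) == 0L) {
    return(tibble::tibble(analyte_name = character(), day_id = integer(),
                          mec = numeric(), pnec = numeric(),
                          dilution_factor = numeric(), rq = numeric(),
                          rq_2sf = numeric(), band = character(),
                          headline = logical()))
  }
  d$mec <- censor_for_aggregation(d$value_ngL, d$censor)
  d$pnec <- pnec_registry$pnec_ngL[match(d$analyte_name,
                                         pnec_registry$analyte_name)]
  d$rq <- risk_quotient(d$mec, d$pnec, dilution)
  out <- tibble::tibble(
    analyte_name = d$analyte_name, day_id = d$day_id, mec = d$mec,
    pnec = d$pnec, dilution_factor = dilution, rq = d$rq,
    rq_2sf = signif(d$rq, 2), band = classify_risk(d$rq))
  out$headline <- FALSE
  for (a in unique(out$analyte_name)) {
    rows <- which(out$analyte_name == a)
    out$headline[rows[which.max(out$rq[rows])]] <- TRUE
  }
  out
}
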