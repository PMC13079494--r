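# Instrumental limits from replicate S/N data, and their conversion to
# in-sample method limits through recovery and the matrix concentration
# factor.

#' Determine the instrumental quantification limit (IQL)
#'
#' The IQL is the lowest measured concentration at which the majority of
#' replicate injections show a quantification trace with S/N >= 10 and a
#' confirmation trace with S/N >= 3.3. "The most injections" is read as
#' a strict majority: ties at exactly half fail. One-transition
#' compounds (qualifier S/N `NA`) are judged on the quantifier alone.
#'
#' @param conc nominal concentration (ug/L) of each injection.
#' @param sn_quant quantifier S/N per injection.
#' @param sn_qual confirmation S/N per injection, or `NA`/`NULL` when the
#'   compound has a single transition.
#' @param sn_quant_min,sn_qual_min S/N thresholds (defaults 10 and 3.3).
#' @return the IQL in ug/L, or `NA` when no level qualifies; the
#'   per-level pass table is attached as attribute `"diagnostics"`.
#' @examples
#' # 2-of-3 majority at 0.1; 0-of-3 at 0.01
#' determine_iql(conc = rep(c(0.01, 0.1), each = 3),
#'               sn_quant = c(4, 3, 2, 12, 11, 8),
#'               sn_qual = rep(5, 6))  # 0.1
#' @export
determine_iql <- function(conc, sn_quant, sn_qual = NULL,
                          sn_quant_min = 10, sn_qual_min = 3.3) {
  stopifnot(is.numeric(conc), is.numeric(sn_quant),
            length(conc) == length(sn_quant))
  if (is.null(sn_qual)) sn_qual <- rep(NA_real_, length(conc))
  pass <- sn_quant >= sn_quant_min & (is.na(sn_qual) | sn_qual >= sn_qual_min)
  levels <- sort(unique(conc))
  n_inj <- vapply(levels, function(l) sum(conc == l), integer(1))
  n_pass <- vapply(levels, function(l) sum(pass[conc == l]), integer(1))
  diag <- tibble::tibble(conc = levels, n = n_inj, n_pass = n_pass)
  diag$majority <- diag$n_pass > diag$n / 2
  iql <- if (any(diag$majority)) min(diag$conc[diag$majority]) else NA_real_
  attr(iql, "diagnostics") <- diag
  iql
}

#' Instrumental detection limit from the IQL
#'
#' `IDL = IQL * 0.33`, the ratio of the detection (3.3) to
#' quantification (10) signal-to-noise criteria. This is the relation
#' every published IDL/IQL pair satisfies; it is fixed here rather than
#' configurable.
#'
#' @param iql instrumental quantification limit, ug/L.
#' @return IDL in ug/L.
#' @examples
#' derive_idl(0.1)  # 0.033
#' derive_idl(0.5)  # 0.165
#' @export
derive_idl <- function(iql) {
  stopifnot(all(is.na(iql) | iql > 0))
  iql * 0.33
}

#' Convert an instrumental limit to a method limit
#'
#' `MQL (ng/L) = IQL (ng/L) * 100 / (Recovery (%) * Cf)`, with the MDL
#' obtained identically from the IDL. Instrumental limits are in-vial
#' ug/L and are converted to ng/L explicitly before the formula is
#' applied; `Cf` is the matrix concentration factor (100 for influent
#' wastewater). Compounds that cannot be recovered (recovery <= 0 or
#' missing) have no defined method limit and return `NA`.
#'
#' @param instr_limit_ugL instrumental limit (IQL or IDL), ug/L in vial.
#' @param recovery method recovery in percent (may exceed 100).
#' @param cf matrix concentration factor.
#' @return method limit in ng/L (in sample), `NA` when undefined.
#' @examples
#' method_limit(0.01, 118.2)    # 0.0846 -> the published 0.08 (PFBS MQL)
#' method_limit(100, 43.6)      # 2293.6 (MeFOSA MQL)
#' @export
method_limit <- function(instr_limit_ugL, recovery, cf = 100) {
  stopifnot(all(is.na(instr_limit_ugL) | instr_limit_ugL > 0), cf > 0)
  out <- rep(NA_real_, length(instr_limit_ugL))
  recovery <- rep_len(recovery, length(instr_limit_ugL))
  ok <- !is.na(recovery) & recovery > 0 & !is.na(instr_limit_ugL)
  instr_ngL <- convert_units(instr_limit_ugL[ok], "ug/L", "ng/L")
  out[ok] <- instr_ngL * 100 / (recovery[ok] * cf)
  out
}

#' Assemble the full limit set for one analyte
#'
#' @param analyte_name label.
#' @param iql_ugL instrumental quantification limit, ug/L.
#' @param recovery method recovery, percent.
#' @param cf matrix concentration factor.
#' @return one-row tibble: `idl_ugL`, `iql_ugL`, `mdl_ngL`, `mql_ngL`,
#'   `cf`, `recovery_used`.
#' @export
limit_set <- function(analyte_name, iql_ugL, recovery, cf = 100) {
  idl <- derive_idl(iql_ugL)
  tibble::tibble(
    analyte_name = analyte_name,
    idl_ugL = idl, iql_ugL = iql_ugL,
    mdl_ngL = method_limit(idl, recovery, cf),
    mql_ngL = method_limit(iql_ugL, recovery, cf),
    cf = cf, recovery_used = recovery)
}
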