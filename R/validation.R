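# Validation metrics (accuracy, precision, recovery), quantification
# status classification, and treatment-comparison suitability assessment.

#' Accuracy as percent of the theoretical concentration
#'
#' `Accuracy (%) = C_exp / C_theo * 100`. Unbounded: values above 100%
#' (over-recovery) and, in principle, negative back-calculations pass
#' through unchanged.
#'
#' @param c_exp experimentally derived concentration.
#' @param c_theo spiked (theoretical) concentration, > 0.
#' @return percent.
#' @export
accuracy_pct <- function(c_exp, c_theo) {
  if (any(c_theo <= 0)) stop("c_theo must be > 0", call. = FALSE)
  c_exp / c_theo * 100
}

#' Precision as relative standard deviation (percent)
#'
#' Sample standard deviation of replicate concentrations divided by
#' their mean, times 100. (The source formula is labelled RSD and
#' reported in percent even though it is written as an absolute standard
#' deviation; the relative reading is the one consistent with every
#' reported value.)
#'
#' @param replicate_concs numeric vector, length >= 2.
#' @return percent RSD; `NA` with a warning when the mean is zero.
#' @examples
#' precision_rsd(c(90, 100, 110))  # 10
#' @export
precision_rsd <- function(replicate_concs) {
  if (length(replicate_concs) < 2L) {
    stop("precision needs >= 2 replicates", call. = FALSE)
  }
  m <- mean(replicate_concs)
  if (m == 0) {
    warning("mean of replicates is zero; RSD undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(replicate_concs) / m * 100
}

#' Method recovery as percent of the spiked concentration
#'
#' `Recovery (%) = (C_ss - C_us) / C_theo * 100`, where `C_ss` is the
#' measured concentration of the spiked matrix sample and `C_us` that of
#' the unspiked sample (native background). May exceed 100% (matrix
#' enhancement) or go negative (analyte lost to the point that the
#' unspiked sample out-measures the spiked one).
#'
#' @param c_ss spiked-sample concentration.
#' @param c_us unspiked-sample concentration.
#' @param c_theo spiked concentration, > 0.
#' @return percent.
#' @export
recovery_pct <- function(c_ss, c_us, c_theo) {
  if (any(c_theo <= 0)) stop("c_theo must be > 0", call. = FALSE)
  (c_ss - c_us) / c_theo * 100
}

#' Classify quantification status from accuracy and precision
#'
#' Band rules: fully quantitative for accuracy 50-120% and precision
#' < 30%; semi-quantitative for accuracy 30-50% or precision 30-50%;
#' qualitative beyond these. A compound lacking a confirmation
#' transition can additionally be capped at semi-quantitative: the cap
#' is applied per analyte (via `enforce_one_transition_cap`) rather than
#' globally, because published target lists apply it to some
#' one-transition compounds and not others.
#'
#' Boundary conventions (pinned by tests): accuracy 50 and 120 are
#' quantitative; accuracy 30 and precision 30 and 50 are
#' semi-quantitative; precision 30 is not quantitative.
#'
#' @param accuracy mean accuracy, percent.
#' @param precision mean precision (RSD), percent.
#' @param has_two_transitions logical; `FALSE` for one-transition
#'   compounds.
#' @param enforce_one_transition_cap logical; when `TRUE` a compound
#'   without a second transition is at most semi-quantitative.
#' @return character vector: `"quantitative"`, `"semi_quantitative"` or
#'   `"qualitative"`.
#' @export
classify_quantification <- function(accuracy, precision,
                                    has_two_transitions = TRUE,
                                    enforce_one_transition_cap = FALSE) {
  n <- max(length(accuracy), length(precision))
  accuracy <- rep_len(accuracy, n)
  precision <- rep_len(precision, n)
  has_two_transitions <- rep_len(has_two_transitions, n)
  enforce_one_transition_cap <- rep_len(enforce_one_transition_cap, n)

  meets_quant <- accuracy >= 50 & accuracy <= 120 & precision < 30
  capped <- enforce_one_transition_cap & !has_two_transitions
  semi_bands <- (accuracy >= 30 & accuracy < 50) |
    (precision >= 30 & precision <= 50)
  ifelse(meets_quant & !capped, "quantitative",
  ifelse((meets_quant & capped) | semi_bands, "semi_quantitative",
         "qualitative"))
}

#' Compare a sample-handling treatment against its reference
#'
#' Assesses whether a preparation step (drying down in silanised glass,
#' standing in an HDPE bottle, an alternative elution solvent) loses
#' analyte, by the drop in accuracy relative to the reference
#' preparation. The drop counts as significant only when it falls
#' outside the standard deviations of both measurements; material
#' suitability is then banded on the absolute drop: suitable (< 15
#' points), medium (15 to < 30) and potentially unsuitable (>= 30).
#'
#' @param acc_treatment,sd_treatment accuracy (percent) and its sd under
#'   the treatment.
#' @param acc_reference,sd_reference accuracy and sd of the reference.
#' @param analyte_name,treatment,reference optional labels.
#' @return one-row tibble with `delta_accuracy` (reference minus
#'   treatment, positive = loss), `significant` and `suitability`
#'   (`"not_assessed"` when not significant).
#' @export
compare_treatments <- function(acc_treatment, sd_treatment,
                               acc_reference, sd_reference,
                               analyte_name = NA_character_,
                               treatment = NA_character_,
                               reference = NA_character_) {
  delta <- acc_reference - acc_treatment
  significant <- abs(delta) > sd_treatment & abs(delta) > sd_reference
  suitability <- ifelse(!significant, "not_assessed",
                 ifelse(abs(delta) < 15, "suitable",
                 ifelse(abs(delta) < 30, "medium", "unsuitable")))
  tibble::tibble(analyte_name = analyte_name, treatment = treatment,
                 reference = reference, delta_accuracy = delta,
                 significant = significant, suitability = suitability)
}
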