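# Small in-code fixtures: a three-target registry with two internal
# standards, matching assay truth, and site/PNEC stubs. A1 is a
# two-transition compound with unit recovery, B1 a one-transition
# compound with 50% recovery, C1 a two-transition compound with matrix
# enhancement (120%).

toy_registry <- function() {
  tibble::tibble(
    analyte_class = c("PFSA", "PFCA", "PFCA_precursor", "ISTD", "ISTD"),
    analyte_name = c("A1", "B1", "C1", "IS1", "IS2"),
    quant_precursor_mz = c(300, 213, 427, 303, 217),
    quant_product_mz = c(99, 169, 387, 80, 172),
    quant_cone_v = 40, quant_ce_ev = 27,
    qual_precursor_mz = c(300, NA, 427, NA, NA),
    qual_product_mz = c(80, NA, 407, NA, NA),
    qual_cone_v = c(40, NA, 38, NA, NA),
    qual_ce_ev = c(28, NA, 21, NA, NA),
    istd_name = c("IS1", "IS2", "IS1", NA, NA),
    calib_low_ugL = c(0.01, 0.1, 0.5, NA, NA),
    calib_high_ugL = c(1000, 500, 600, NA, NA),
    status = c("quantitative", "quantitative", "quantitative", NA, NA))
}

toy_truth <- function(noise_cv = 0, istd_cv = 0, rt_sd = 0,
                      recovery = c(1, 0.5, 1.2), native = 0) {
  assay_truth(
    tibble::tibble(
      analyte_name = c("A1", "B1", "C1"),
      istd_name = c("IS1", "IS2", "IS1"),
      response_factor = c(2, 0.5, 1),
      true_recovery = recovery,
      ion_ratio_true = c(0.52, NA, 2),
      noise_cv = noise_cv,
      sn_per_conc = c(12 / 0.01, 12 / 0.1, 12 / 0.5),
      rt_true = c(7.8, 6.99, 9.69), rt_sd = rt_sd,
      native_conc = native),
    tibble::tibble(istd_name = c("IS1", "IS2"), area_mean = 1e5,
                   area_cv = istd_cv, rt = c(7.8, 10.28)))
}

toy_site_days <- function() {
  tibble::tibble(day_id = 1:3, flow_L_day = 1e8, population = 1e6)
}

toy_pnec <- function() {
  tibble::tibble(analyte_name = c("A1", "C1"), pnec_ngL = c(10, 5000),
                 organism = "Fish, Pimephales promelas",
                 exposure_type = "acute")
}

toy_influent <- function() {
  tibble::tibble(
    analyte_name = rep(c("A1", "B1", "C1"), each = 3),
    day_id = rep(1:3, 3),
    true_conc_ngL = c(50, 20, 80, 1000, 800, 1200, 3000, 2500, 3500))
}

# Packaged published tables, loaded once per test file.
fixture_instrument <- function() {
  utils::read.csv(pfas_extdata("instrument_performance.csv"),
                  check.names = FALSE)
}
fixture_method <- function() {
  utils::read.csv(pfas_extdata("method_performance.csv"), check.names = FALSE)
}
fixture_influent_days <- function() {
  utils::read.csv(pfas_extdata("influent_days.csv"), check.names = FALSE)
}
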