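test_that("zero-noise campaigns reproduce the response model exactly", {
  camp <- generate_campaign(toy_truth(), campaign_design(seed = 7))
  inj <- camp$injections

  a1 <- inj[inj$analyte_name == "A1" & inj$sample_type == "calibration", ]
  expect_equal(a1$quant_area / a1$istd_area, 2 * a1$nominal_conc,
               tolerance = 1e-12)
  expect_true(all(a1$istd_area == 1e5))
  expect_equal(a1$quant_area / a1$qual_area, rep(0.52, nrow(a1)),
               tolerance = 1e-12)
  expect_equal(a1$sn_quant, 12 / 0.01 * a1$nominal_conc, tolerance = 1e-12)
  expect_equal(a1$sn_qual, 0.33 * a1$sn_quant, tolerance = 1e-12)
  expect_true(all(a1$rt == 7.8))
  expect_true(all(a1$rt_istd == 7.8))

  # one-transition compound: no qualifier trace at all
  b1 <- inj[inj$analyte_name == "B1", ]
  expect_true(all(is.na(b1$qual_area)))
  expect_true(all(is.na(b1$sn_qual)))

  # recovery enters matrix samples but not calibration/QC
  c1 <- inj[inj$analyte_name == "C1" & inj$sample_type == "matrix_spiked", ]
  expect_equal(c1$quant_area / c1$istd_area, 1 * 1.2 * c1$nominal_conc,
               tolerance = 1e-12)
  qc <- inj[inj$analyte_name == "C1" & inj$sample_type == "qc", ]
  expect_equal(qc$quant_area / qc$istd_area, qc$nominal_conc,
               tolerance = 1e-12)
})

test_that("a fixed seed gives identical campaigns and substreams are stable", {
  tr <- toy_truth(noise_cv = 0.1, istd_cv = 0.05, rt_sd = 0.02)
  des <- campaign_design(seed = 11)
  c1 <- generate_campaign(tr, des, influent = toy_influent())
  c2 <- generate_campaign(tr, des, influent = toy_influent())
  expect_identical(c1$injections, c2$injections)
  expect_identical(c1$samples, c2$samples)

  # dropping an analyte must not perturb the remaining analytes' draws
  tr_sub <- tr
  tr_sub$analytes <- tr$analytes[tr$analytes$analyte_name != "C1", ]
  c3 <- generate_campaign(tr_sub, des, influent = toy_influent())
  keep <- c1$injections[c1$injections$analyte_name != "C1", ]
  expect_equal(as.data.frame(keep), as.data.frame(c3$injections))

  # a different seed changes the draws
  c4 <- generate_campaign(tr, campaign_design(seed = 12),
                          influent = toy_influent())
  expect_false(identical(c1$injections$quant_area,
                         c4$injections$quant_area))
})

test_that("back-calculated recovery converges to truth (LLN, n = 1000)", {
  tr <- toy_truth(noise_cv = 0.05, istd_cv = 0.05,
                  recovery = c(0.5, 0.5, 0.5))
  des <- campaign_design(spike_levels = 200, n_matrix_replicates = 1000,
                         seed = 3)
  inj <- generate_campaign(tr, des)$injections
  a1 <- inj[inj$analyte_name == "A1", ]
  rf <- 2  # ground truth, independent of any fitted calibration
  c_ss <- mean(a1$quant_area[a1$sample_type == "matrix_spiked"] /
                 a1$istd_area[a1$sample_type == "matrix_spiked"]) / rf
  c_us <- mean(a1$quant_area[a1$sample_type == "matrix_unspiked"] /
                 a1$istd_area[a1$sample_type == "matrix_unspiked"]) / rf
  rec <- recovery_pct(c_ss, c_us, 200)
  expect_lt(abs(rec - 50) / 50, 0.01)
})

test_that("influent truth censoring marks follow the supplied limits", {
  tr <- toy_truth()
  des <- campaign_design(seed = 5)
  limits <- tibble::tibble(analyte_name = c("A1", "B1", "C1"),
                           mdl_ngL = 10, mql_ngL = 20)

  # constant concentrations constructed around the limits
  inf <- generate_influent_truth(tr, des, limits = limits,
                                 meanlog = log(c(1e-9, 15, 100)), sdlog = 0)
  expect_true(all(inf$censor[inf$analyte_name == "A1"] == "below_LOD"))
  expect_true(all(inf$censor[inf$analyte_name == "B1"] == "below_LOQ"))
  expect_true(all(inf$censor[inf$analyte_name == "C1"] == "detected"))

  # far above the MQL: detection frequency equals the number of days
  inf_hi <- generate_influent_truth(tr, des, limits = limits,
                                    meanlog = log(1e6), sdlog = 0.5)
  expect_equal(detection_frequency(inf_hi$censor[
    inf_hi$analyte_name == "A1"]), 3)

  # random draws: marks always consistent with the limit comparison
  inf_rnd <- generate_influent_truth(tr, des, limits = limits,
                                     meanlog = log(15), sdlog = 1)
  expected <- ifelse(inf_rnd$true_conc_ngL < 10, "below_LOD",
              ifelse(inf_rnd$true_conc_ngL < 20, "below_LOQ", "detected"))
  expect_identical(inf_rnd$censor, expected)

  # uncensored truth is retained for every day
  expect_true(all(is.finite(inf_rnd$true_conc_ngL)))
})

test_that("assay truth constructors validate their invariants", {
  expect_error(toy_truth(noise_cv = 1.5), "noise_cv")
  bad <- toy_truth()
  bad$analytes$istd_name[1] <- "nope"
  expect_error(assay_truth(bad$analytes, bad$istds), "no ISTD truth")
  expect_error(campaign_design(calib_levels = c(10, 1)), "strictly")
  expect_error(campaign_design(n_injection_replicates = 0))

  reg <- load_analyte_registry(pfas_extdata("analytes.csv"))
  tr <- default_assay_truth(reg)
  expect_equal(nrow(tr$analytes), 35)
  expect_equal(nrow(tr$istds), 8)
  # one-transition compounds have no true ion ratio
  expect_true(all(is.na(tr$analytes$ion_ratio_true[
    tr$analytes$analyte_name %in% c("PFBA", "PFOPA", "PFDPA", "8:8 PFPiA")])))
  # S/N scaling pinned to the published IQLs (e.g. PFBS 0.01 ug/L)
  expect_equal(tr$analytes$sn_per_conc[tr$analytes$analyte_name == "PFBS"],
               12 / 0.01)
})
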