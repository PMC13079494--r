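# Synthetic measurement-campaign generator. Emulates the measurement
# process behind a targeted MRM assay -- linear ISTD-normalised response,
# multiplicative (lognormal, heteroscedastic) area noise, concentration-
# proportional S/N, per-compound recovery losses, ion ratios and
# below-limit censoring -- with known ground truth for every stage.

# Unbiased multiplicative lognormal noise: E[noise] = 1, CV = cv.
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

# Deterministic substream seed from the global seed and a stream key, so
# that adding analytes (new keys) never perturbs existing streams.
# FNV-style accumulation kept below 2^26 so all arithmetic is exact in
# doubles; final seed < 2^31 as required by set.seed().
.substream_seed <- function(seed, key) {
  h <- 21788233
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 67108859
  (seed %% 2147483647 + h * 97) %% 2147483647
}

#' Assay ground truth for the synthetic campaign generator
#'
#' Bundles per-analyte truth (ISTD-normalised response factor in
#' (area ratio)/(ug/L), fractional recovery through sample preparation,
#' true quantifier/qualifier ion ratio, area noise CV, S/N per unit
#' concentration, retention time) with per-ISTD truth (mean area, area
#' CV, retention time). Recovery may exceed 1 (matrix enhancement) and
#' ion ratio is `NA` for one-transition compounds.
#'
#' @param analytes tibble with columns `analyte_name`, `istd_name`,
#'   `response_factor`, `true_recovery`, `ion_ratio_true`, `noise_cv`,
#'   `sn_per_conc`, `rt_true`, `rt_sd`, `native_conc` (native background
#'   expressed as the vial-equivalent ug/L present before recovery
#'   losses; default 0).
#' @param istds tibble with columns `istd_name`, `area_mean`, `area_cv`,
#'   `rt`.
#' @return an object of class `assay_truth`.
#' @seealso [default_assay_truth()] for truth parameterised from the
#'   packaged performance tables.
#' @export
assay_truth <- function(analytes, istds) {
  analytes <- tibble::as_tibble(analytes)
  istds <- tibble::as_tibble(istds)
  if (!"native_conc" %in% names(analytes)) analytes$native_conc <- 0
  if (!"rt_sd" %in% names(analytes)) analytes$rt_sd <- 0
  req_a <- c("analyte_name", "istd_name", "response_factor", "true_recovery",
             "ion_ratio_true", "noise_cv", "sn_per_conc", "rt_true")
  req_i <- c("istd_name", "area_mean", "area_cv", "rt")
  stopifnot(all(req_a %in% names(analytes)), all(req_i %in% names(istds)))
  with(analytes, stopifnot(
    all(response_factor > 0), all(sn_per_conc > 0), all(rt_true > 0),
    all(noise_cv >= 0 & noise_cv < 1), all(native_conc >= 0),
    all(is.na(ion_ratio_true) | ion_ratio_true > 0)))
  with(istds, stopifnot(all(area_mean > 0), all(area_cv >= 0 & area_cv < 1),
                        all(rt > 0)))
  missing_istd <- setdiff(analytes$istd_name, istds$istd_name)
  if (length(missing_istd) > 0L) {
    stop("no ISTD truth for: ", paste(missing_istd, collapse = ", "),
         call. = FALSE)
  }
  structure(list(analytes = analytes, istds = istds), class = "assay_truth")
}

# Retention times of the internal standards; the labelled PFAS co-elute
# with their native analogues, the pharmaceutical ISTDs elute per the
# relative retention times observed for their assigned analytes.
.istd_rt_defaults <- c(
  "PFBS 13C4" = 7.80, "PFBA 13C4" = 7.06, "PFOA 13C8" = 9.70,
  "6:2 FTS 13C2 D4" = 9.69, "Acetaminophen D4" = 5.36,
  "Methyl Paraben 13C6" = 7.80, "Ketoprofen D3" = 8.25,
  "Ibuprofen D3" = 10.28)

#' Default assay truth derived from the packaged performance tables
#'
#' Builds an [assay_truth()] object for every target in `registry`,
#' taking retention times, instrumental quantification limits and
#' high-band ion ratios from the packaged instrument-performance table
#' and method recoveries from the method-performance table, so the
#' synthetic campaign emulates the published assay. `sn_per_conc` is set
#' to `12 / IQL`: at the IQL the quantifier S/N sits comfortably above
#' the >= 10 rule while the next calibration level down (a factor ~1.9
#' lower on the default 19-point grid) falls below it, so the S/N rule
#' recovers the configured IQL. Analytes absent from the tables (custom
#' registries) get neutral fallbacks (recovery 1, ion ratio 2 when a
#' qualifier exists, IQL = calibration low end).
#'
#' @param registry analyte registry from [load_analyte_registry()].
#' @param noise_cv multiplicative area noise CV (default 0.05).
#' @param istd_cv ISTD area CV (per-injection efficiency; default 0.05).
#' @param istd_area_mean mean ISTD area in counts.
#' @param rt_sd retention-time jitter sd in minutes.
#' @return an `assay_truth` object.
#' @export
default_assay_truth <- function(registry, noise_cv = 0.05, istd_cv = 0.05,
                                istd_area_mean = 1e5, rt_sd = 0.02) {
  tgt <- registry[registry$analyte_class != "ISTD", ]
  istd <- registry[registry$analyte_class == "ISTD", ]
  inst <- tryCatch(
    utils::read.csv(pfas_extdata("instrument_performance.csv"),
                    check.names = FALSE), error = function(e) NULL)

  meth <- tryCatch(
    utils::read.csv(pfas_extdata("method_performance.csv"),
                    check.names = FALSE), error = function(e) NULL)

  n <- nrow(tgt)
  rf <- vapply(tgt$analyte_name, function(nm) {
    h <- 0
    for (b in utf8ToInt(nm)) h <- (h * 31 + b) %% 1000
    0.2 * 10^(h / 1000)
  }, numeric(1))

  idx_i <- if (is.null(inst)) rep(NA_integer_, n) else
    match(tgt$analyte_name, inst$analyte_name)
  idx_m <- if (is.null(meth)) rep(NA_integer_, n) else
    match(tgt$analyte_name, meth$analyte_name)

  iql <- ifelse(is.na(idx_i), tgt$calib_low_ugL, inst$iql_ugL[idx_i])
  rt <- ifelse(is.na(idx_i), 7 + 7 * seq_len(n) / n, inst$rt[idx_i])
  has_qual <- !is.na(tgt$qual_precursor_mz)
  ir <- ifelse(is.na(idx_i), 2, inst$ir_high_mean[idx_i])
  ir[!has_qual] <- NA_real_
  ir[has_qual & is.na(ir)] <- 2
  rec <- ifelse(is.na(idx_m), 100, meth$recovery[idx_m]) / 100
  rec[is.na(rec)] <- 0  # compounds that cannot be recovered

  analytes <- tibble::tibble(
    analyte_name = tgt$analyte_name, istd_name = tgt$istd_name,
    response_factor = unname(rf), true_recovery = rec, ion_ratio_true = ir,
    noise_cv = noise_cv, sn_per_conc = 12 / iql, rt_true = rt, rt_sd = rt_sd,
    native_conc = 0)
  istd_rt <- .istd_rt_defaults[istd$analyte_name]
  istd_rt[is.na(istd_rt)] <- 8
  istds <- tibble::tibble(
    istd_name = istd$analyte_name, area_mean = istd_area_mean,
    area_cv = istd_cv, rt = unname(istd_rt))
  assay_truth(analytes, istds)
}

#' Default 19-point calibration grid, 0.01 to 1000 ug/L
#'
#' Log-spaced across five decades, rounded to three significant figures.
#' @return numeric vector of length 19.
#' @export
default_calib_levels <- function() {
  signif(10^seq(-2, 3, length.out = 19), 3)
}

#' Design of a synthetic measurement campaign
#'
#' Mirrors the published campaign layout: a 19-point calibration series
#' injected in triplicate, mobile-phase QCs and matrix spikes at 5, 20,
#' 200 and 500 ug/L (in-vial), unspiked matrix replicates, and optional
#' influent days.
#'
#' @param calib_levels calibration concentrations, ug/L, ascending.
#' @param n_injection_replicates injections per calibration/QC level.
#' @param qc_levels mobile-phase QC concentrations, ug/L.
#' @param spike_levels matrix spike concentrations, ug/L.
#' @param n_matrix_replicates replicates per matrix/influent sample.
#' @param site_days optional tibble from [load_site_days()].
#' @param seed integer master seed; every random stream is derived from
#'   it (see [generate_campaign()]).
#' @return an object of class `campaign_design`.
#' @export
campaign_design <- function(calib_levels = default_calib_levels(),
                            n_injection_replicates = 3,
                            qc_levels = c(5, 20, 200, 500),
                            spike_levels = c(5, 20, 200, 500),
                            n_matrix_replicates = 3,
                            site_days = NULL,
                            seed = 1L) {
  stopifnot(is.numeric(calib_levels), length(calib_levels) >= 1,
            !is.unsorted(calib_levels, strictly = TRUE),
            all(calib_levels > 0),
            !is.unsorted(qc_levels, strictly = TRUE),
            !is.unsorted(spike_levels, strictly = TRUE),
            n_injection_replicates >= 1, n_matrix_replicates >= 1,
            length(seed) == 1, is.finite(seed))
  structure(list(calib_levels = calib_levels,
                 n_injection_replicates = as.integer(n_injection_replicates),
                 qc_levels = qc_levels, spike_levels = spike_levels,
                 n_matrix_replicates = as.integer(n_matrix_replicates),
                 site_days = site_days, seed = as.integer(seed)),
            class = "campaign_design")
}

#' Generate a synthetic measurement campaign
#'
#' For every analyte and sample, draws per-injection areas around the
#' linear model `ratio = response_factor * conc` with multiplicative
#' lognormal noise (mean 1, CV `noise_cv`): a shared per-injection
#' efficiency (CV `area_cv` of the ISTD) scales both the analyte and
#' ISTD areas, so the ISTD-normalised ratio cancels it -- the reason the
#' assay uses internal standards. The effective concentration includes
#' `true_recovery` for matrix and influent samples and the native
#' background for unspiked matrix; influent concentrations (ng/L
#' in-sample) are mapped to vial ug/L through recovery and the matrix
#' concentration factor `cf`. Qualifier areas follow the true ion ratio
#' with independent noise; the quantifier S/N is `sn_per_conc * conc`
#' with the confirmation trace at 0.33 of it, so the two S/N rules
#' (>= 10 and >= 3.3) coincide at the same level.
#'
#' Each analyte draws from its own seeded substream (derived from
#' `design$seed` and the analyte name), so output is byte-identical for
#' a fixed seed and unchanged for existing analytes when new ones are
#' added.
#'
#' @param truth an [assay_truth()] object.
#' @param design a [campaign_design()] object.
#' @param influent optional tibble with `analyte_name`, `day_id`,
#'   `true_conc_ngL` (e.g. from [generate_influent_truth()]).
#' @param cf matrix concentration factor (100 for influent wastewater).
#' @return a list with `injections` (one row per injection per analyte),
#'   `samples` (sample metadata) and `truth` (the ground-truth ledger:
#'   `truth`, `design`, `influent` as supplied).
#' @export
generate_campaign <- function(truth, design, influent = NULL, cf = 100) {
  stopifnot(inherits(truth, "assay_truth"), inherits(design, "campaign_design"))
  if (!is.null(influent)) {
    stopifnot(all(c("analyte_name", "day_id", "true_conc_ngL") %in%
                    names(influent)))
  }

  per_analyte <- lapply(seq_len(nrow(truth$analytes)), function(i) {
    a <- truth$analytes[i, ]
    istd <- truth$istds[truth$istds$istd_name == a$istd_name, ]
    cond <- .campaign_conditions(a, design, influent, cf)
    set.seed(.substream_seed(design$seed, paste0("campaign:", a$analyte_name)))
    n <- nrow(cond)
    inj_eff <- .lnoise(n, istd$area_cv)
    eps_q <- .lnoise(n, a$noise_cv)
    eps_q2 <- .lnoise(n, a$noise_cv)
    eps_sn <- .lnoise(n, a$noise_cv)
    rt_jit <- if (a$rt_sd > 0) stats::rnorm(n, 0, a$rt_sd) else numeric(n)
    rt_jit_istd <- if (a$rt_sd > 0) stats::rnorm(n, 0, a$rt_sd) else numeric(n)

    istd_area <- istd$area_mean * inj_eff
    base <- a$response_factor * cond$effective_conc * istd$area_mean * inj_eff
    quant_area <- base * eps_q
    if (is.na(a$ion_ratio_true)) {
      qual_area <- rep(NA_real_, n)
      sn_qual <- rep(NA_real_, n)
    } else {
      qual_area <- base / a$ion_ratio_true * eps_q2
      sn_qual <- NULL  # filled below
    }
    sn_quant <- a$sn_per_conc * cond$effective_conc * eps_sn
    if (is.null(sn_qual)) sn_qual <- 0.33 * sn_quant

    tibble::tibble(
      sample_id = cond$sample_id, sample_type = cond$sample_type,
      analyte_name = a$analyte_name, replicate = cond$replicate,
      nominal_conc = cond$nominal_conc, day_id = cond$day_id,
      quant_area = quant_area, qual_area = qual_area, istd_area = istd_area,
      sn_quant = sn_quant, sn_qual = sn_qual,
      rt = a$rt_true + rt_jit, rt_istd = istd$rt + rt_jit_istd)
  })
  injections <- dplyr::bind_rows(per_analyte)
  samples <- dplyr::distinct(
    injections[, c("sample_id", "sample_type", "nominal_conc", "day_id")])
  list(injections = injections, samples = samples,
       truth = list(truth = truth, design = design, influent = influent,
                    cf = cf))
}

# One row per injection: sample identity plus the true concentration in
# the vial ("effective_conc", ug/L) that the detector responds to.
.campaign_conditions <- function(a, design, influent, cf) {
  rec <- a$true_recovery
  blocks <- list(
    .cond_block("calibration", "cal", design$calib_levels,
                design$n_injection_replicates, eff = function(lv) lv),
    .cond_block("qc", "qc", design$qc_levels, design$n_injection_replicates,
                eff = function(lv) lv),
    .cond_block("matrix_spiked", "mxs", design$spike_levels,
                design$n_matrix_replicates,
                eff = function(lv) rec * (a$native_conc + lv)),
    .cond_block("matrix_unspiked", "mxu", 0, design$n_matrix_replicates,
                eff = function(lv) rec * a$native_conc))
  cond <- dplyr::bind_rows(blocks)
  cond$day_id <- NA_integer_
  if (!is.null(influent)) {
    inf_a <- influent[influent$analyte_name == a$analyte_name, ]
    if (nrow(inf_a) > 0L) {
      reps <- design$n_matrix_replicates
      inf <- tibble::tibble(
        sample_type = "influent",
        sample_id = rep(paste0("influent_d", inf_a$day_id), each = reps),
        nominal_conc = NA_real_,
        replicate = rep(seq_len(reps), times = nrow(inf_a)),
        effective_conc =
          rep(inf_a$true_conc_ngL, each = reps) * rec * cf / 1000,
        day_id = rep(as.integer(inf_a$day_id), each = reps))
      cond <- dplyr::bind_rows(cond, inf)
    }
  }
  cond
}

.cond_block <- function(type, prefix, levels, reps, eff) {
  tibble::tibble(
    sample_type = type,
    sample_id = rep(paste0(prefix, "_", format(levels, trim = TRUE,
                                               scientific = FALSE)),
                    each = reps),
    nominal_conc = rep(levels, each = reps),
    replicate = rep(seq_len(reps), times = length(levels)),
    effective_conc = eff(rep(levels, each = reps)))
}

#' Generate per-day influent ground truth with censoring marks
#'
#' Draws one true in-sample concentration (ng/L) per analyte per site
#' day from a lognormal, then marks each day `below_LOD` (< MDL),
#' `below_LOQ` (< MQL) or `detected` against the supplied method limits.
#' The uncensored truth is retained so downstream censoring logic can be
#' verified against it.
#'
#' @param truth an [assay_truth()] object (names drive the substreams).
#' @param design a [campaign_design()] with `site_days` set (or pass
#'   `n_days`).
#' @param limits optional tibble with `analyte_name`, `mdl_ngL`,
#'   `mql_ngL`; without it every day is marked `detected`.
#' @param meanlog,sdlog lognormal parameters of the day-to-day
#'   concentration distribution; scalars or one value per analyte.
#' @param n_days number of days when `design$site_days` is `NULL`.
#' @return tibble with `analyte_name`, `day_id`, `true_conc_ngL`,
#'   `censor`.
#' @export
generate_influent_truth <- function(truth, design, limits = NULL,
                                    meanlog = log(20), sdlog = 1,
                                    n_days = 3L) {
  stopifnot(inherits(truth, "assay_truth"), inherits(design, "campaign_design"))
  days <- if (!is.null(design$site_days)) design$site_days$day_id
          else seq_len(n_days)
  nms <- truth$analytes$analyte_name
  meanlog <- rep_len(meanlog, length(nms))
  sdlog <- rep_len(sdlog, length(nms))
  out <- lapply(seq_along(nms), function(i) {
    set.seed(.substream_seed(design$seed, paste0("influent:", nms[i])))
    conc <- if (sdlog[i] == 0) rep(exp(meanlog[i]), length(days))
            else stats::rlnorm(length(days), meanlog[i], sdlog[i])
    tibble::tibble(analyte_name = nms[i], day_id = as.integer(days),
                   true_conc_ngL = conc)
  })
  out <- dplyr::bind_rows(out)
  out$censor <- "detected"
  if (!is.null(limits)) {
    idx <- match(out$analyte_name, limits$analyte_name)
    mdl <- limits$mdl_ngL[idx]
    mql <- limits$mql_ngL[idx]
    out$censor <- ifelse(!is.na(mdl) & out$true_conc_ngL < mdl, "below_LOD",
                  ifelse(!is.na(mql) & out$true_conc_ngL < mql, "below_LOQ",
                         "detected"))
  }
  out
}
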