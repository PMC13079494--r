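# Internal-standard calibration, back-calculation, ion-ratio statistics
# and retention-time diagnostics.

#' ISTD-normalised response ratio
#'
#' @param quant_area quantifier peak area (counts).
#' @param istd_area internal-standard peak area (counts); must be > 0.
#' @return numeric vector `quant_area / istd_area`.
#' @export
response_ratio <- function(quant_area, istd_area) {
  stopifnot(is.numeric(quant_area), is.numeric(istd_area))
  if (any(istd_area <= 0, na.rm = TRUE)) {
    stop("istd_area must be > 0 for quantifiable injections", call. = FALSE)
  }
  quant_area / istd_area
}

#' Fit an internal-standard calibration line
#'
#' Least-squares fit of the ISTD-normalised response ratio
#' `y = quant_area / istd_area` against the nominal concentration.
#' Replicate injections enter as individual points (not level means),
#' preserving the triplicate design's variance structure. Weighting is
#' ordinary least squares by default, with `1/x` weighting available --
#' the choice shifts low-end accuracy and is therefore exposed rather
#' than fixed.
#'
#' Injections with zero (or missing) ISTD area cannot be normalised and
#' are excluded with a warning. At least three distinct concentration
#' levels are required.
#'
#' @param records data frame with columns `conc` (nominal ug/L),
#'   `quant_area`, `istd_area`.
#' @param weighting `"none"` (default) or `"one_over_x"`.
#' @param analyte_name optional label carried into the result.
#' @return an object of class `calibration_fit`: slope, intercept,
#'   `r_squared`, `weighting`, `level_range`, `n_points`.
#' @examples
#' pts <- data.frame(conc = c(1, 10, 100), quant_area = c(2, 20, 200),
#'                   istd_area = 1)
#' fit <- fit_calibration(pts)
#' fit$slope      # 2
#' fit$r_squared  # 1
#' @export
fit_calibration <- function(records, weighting = c("none", "one_over_x"),
                            analyte_name = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc", "quant_area", "istd_area") %in% names(records)))
  bad <- is.na(records$istd_area) | records$istd_area <= 0
  if (any(bad)) {
    warning(sum(bad), " injection(s) with zero/missing ISTD area excluded",
            call. = FALSE)
    records <- records[!bad, ]
  }
  if (length(unique(records$conc)) < 3L) {
    stop("calibration needs >= 3 distinct concentration levels",
         call. = FALSE)
  }
  d <- data.frame(x = records$conc,
                  y = records$quant_area / records$istd_area)
  w <- if (weighting == "one_over_x") 1 / d$x else rep(1, nrow(d))
  fit <- stats::lm(y ~ x, data = d, weights = w)
  # computed directly (not via summary.lm, which warns on exact fits)
  ybar <- sum(w * d$y) / sum(w)
  sst <- sum(w * (d$y - ybar)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(w * stats::residuals(fit)^2) / sst
  structure(list(
    analyte_name = analyte_name %||% NA_character_,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    weighting = weighting,
    level_range = range(d$x),
    n_points = nrow(d)), class = "calibration_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration fit%s: ratio = %.6g + %.6g * conc, r^2 = %.6f\n",
    if (is.na(x$analyte_name)) "" else paste0(" [", x$analyte_name, "]"),
    x$intercept, x$slope, x$r_squared))
  cat(sprintf("  %d points over %g-%g ug/L, weighting: %s\n",
              x$n_points, x$level_range[1], x$level_range[2], x$weighting))
  invisible(x)
}

#' Back-calculate concentration from a response ratio
#'
#' Inverts the calibration line: `conc = (ratio - intercept) / slope`.
#' Values below the fitted range are flagged `extrapolated_low`, above it
#' `extrapolated_high`, and negative back-calculations are reported as
#' computed and flagged `negative` -- they are needed as inputs to the
#' recovery formula, which can legitimately go negative when the
#' unspiked sample out-measures the spiked one.
#'
#' @param fit a `calibration_fit`.
#' @param ratio numeric vector of ISTD-normalised response ratios.
#' @return tibble with `conc` (ug/L) and `flag`
#'   (`ok`/`extrapolated_low`/`extrapolated_high`/`negative`).
#' @export
back_calculate <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"), is.numeric(ratio))
  if (fit$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (ratio - fit$intercept) / fit$slope
  flag <- rep("ok", length(conc))
  flag[conc < fit$level_range[1L]] <- "extrapolated_low"
  flag[conc > fit$level_range[2L]] <- "extrapolated_high"
  flag[conc < 0] <- "negative"
  tibble::tibble(conc = conc, flag = flag)
}

#' Quantifier-to-qualifier ion ratio
#'
#' Defined here as quantifier area / qualifier area (the more abundant
#' transition over the confirmation transition). One-transition
#' compounds have no qualifier and return `NA`.
#'
#' @param quant_area,qual_area peak areas; `qual_area` may be `NA`.
#' @return numeric vector; `NA` where the qualifier is absent.
#' @export
ion_ratio <- function(quant_area, qual_area) {
  stopifnot(is.numeric(quant_area))
  out <- rep(NA_real_, length(quant_area))
  ok <- !is.na(qual_area)
  if (any(qual_area[ok] <= 0)) {
    warning("non-positive qualifier area(s); returning NA", call. = FALSE)
    ok <- ok & qual_area > 0
  }
  out[ok] <- quant_area[ok] / qual_area[ok]
  out
}

#' Ion-ratio summary over a concentration band
#'
#' Because ion-ratio variability grows near the quantification limit,
#' ratios are summarised in two bands: `"low"` (IQL to 100 ug/L) and
#' `"high"` (100 to 1000 ug/L). Returns mean and sd of the
#' per-injection ratios plus a flag that is `TRUE` iff every ratio lies
#' within `window_pct` percent of the band mean (the identification
#' window, 40% by default, configurable to 50%).
#'
#' @param conc nominal concentrations (ug/L) per injection.
#' @param ratio per-injection ion ratios (from [ion_ratio()]).
#' @param band `"low"` or `"high"`.
#' @param iql lower edge of the low band (the analyte's IQL).
#' @param band_break,band_max band edges, ug/L.
#' @param window_pct identification window, percent of the band mean.
#' @return one-row tibble (`band`, `n`, `mean_ratio`, `sd_ratio`,
#'   `within_window`), or `NULL` when fewer than two in-band ratios
#'   exist.
#' @export
ion_ratio_summary <- function(conc, ratio, band = c("low", "high"),
                              iql = 0, band_break = 100, band_max = 1000,
                              window_pct = 40) {
  band <- match.arg(band)
  stopifnot(length(conc) == length(ratio), window_pct > 0, window_pct <= 100)
  keep <- if (band == "low") conc >= iql & conc <= band_break
          else conc > band_break & conc <= band_max
  r <- ratio[keep & !is.na(ratio)]
  if (length(r) < 2L) return(NULL)
  m <- mean(r)
  tibble::tibble(band = band, n = length(r), mean_ratio = m,
                 sd_ratio = stats::sd(r),
                 within_window = all(abs(r - m) <= window_pct / 100 * abs(m)))
}

#' Relative retention time
#'
#' Analyte retention time divided by the retention time of its assigned
#' internal standard, a unitless identification aid that is robust to
#' run-to-run drift.
#'
#' @param rt_analyte,rt_istd retention times in minutes, both > 0.
#' @return numeric vector.
#' @export
relative_retention_time <- function(rt_analyte, rt_istd) {
  stopifnot(all(rt_analyte > 0), all(rt_istd > 0))
  rt_analyte / rt_istd
}
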