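# Registry loaders: analyte/MRM registry, PNEC registry, site-day records.
# All readers take UTF-8 comma-separated files with a mandatory header row,
# validate invariants eagerly, and report the offending row/analyte.

.read_registry_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warning("empty file: ", path, "; returning empty registry", call. = FALSE)
    return(NULL)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("no data rows in ", basename(path), "; returning empty registry",
            call. = FALSE)
  }
  df
}

# Numeric parse with row numbers in the error; blanks stay NA.
.parse_num <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("malformed numeric in column '", col, "' of ", basename(path),
         ", row ", bad[1L], ": '", x[bad[1L]], "'", call. = FALSE)
  }
  out
}

#' Analyte classes and quantification statuses recognised by the registry
#' @name registry-enums
#' @keywords internal
NULL

.analyte_classes <- c("PFSA", "PFSA_precursor", "PFCA", "PFCA_precursor",
                      "phosphonic_phosphinic", "novel_emerging", "ISTD")
.statuses <- c("quantitative", "semi_quantitative", "qualitative")

#' Load the analyte/MRM registry
#'
#' Reads the target-list registry: one row per compound (targets and
#' isotopically labelled internal standards), with MRM quantifier and
#' optional qualifier transitions, the assigned ISTD, the calibration
#' range (in-vial ug/L) and the quantification status. Validates that
#' transitions have `precursor m/z > product m/z > 0`, that calibration
#' ranges satisfy `0 < low < high`, that every `istd_name` resolves to a
#' registry row of class `ISTD`, and that names are unique (matching is
#' exact and case-sensitive throughout the package, since PFAS short
#' names collide easily across naming conventions).
#'
#' @param path CSV file; see `analytes.csv` under the package's
#'   `extdata/` for the column schema, which mirrors a published
#'   35-compound PFAS target list.
#' @return a tibble with one row per compound, in file order.
#' @seealso [pfas_extdata()] for the packaged registry.
#' @export
load_analyte_registry <- function(path) {
  req <- c("analyte_class", "analyte_name",
           "quant_precursor_mz", "quant_product_mz", "quant_cone_v", "quant_ce_ev",
           "qual_precursor_mz", "qual_product_mz", "qual_cone_v", "qual_ce_ev",
           "istd_name", "calib_low_ugL", "calib_high_ugL", "status")
  df <- .read_registry_csv(path, req)
  if (is.null(df)) {
    empty <- stats::setNames(
      data.frame(matrix(character(), ncol = length(req))), req)
    return(tibble::as_tibble(empty))
  }
  num_cols <- grep("_mz$|_v$|_ev$|_ugL$", req, value = TRUE)
  for (col in num_cols) df[[col]] <- .parse_num(df[[col]], col, path)

  dup <- df$analyte_name[duplicated(df$analyte_name)]
  if (length(dup) > 0L) {
    stop("duplicate analyte name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(df$analyte_class), .analyte_classes)
  if (length(bad_class) > 0L) {
    stop("unknown analyte class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }

  is_istd <- df$analyte_class == "ISTD"
  istd_names <- df$analyte_name[is_istd]
  tgt <- df[!is_istd, ]

  unresolved <- tgt$analyte_name[!(tgt$istd_name %in% istd_names)]
  if (length(unresolved) > 0L) {
    stop("internal standard not found in registry for analyte(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  bad_status <- tgt$analyte_name[!(tgt$status %in% .statuses)]
  if (length(bad_status) > 0L) {
    stop("invalid quantification status for: ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  bad_range <- tgt$analyte_name[
    !(tgt$calib_low_ugL > 0 & tgt$calib_high_ugL > tgt$calib_low_ugL)]
  if (length(bad_range) > 0L) {
    stop("calibration range must satisfy 0 < low < high for: ",
         paste(bad_range, collapse = ", "), call. = FALSE)
  }
  .check_transition(df, "quant", path)
  has_qual <- !is.na(df$qual_precursor_mz)
  .check_transition(df[has_qual, ], "qual", path)

  tibble::as_tibble(df)
}

.check_transition <- function(df, which, path) {
  if (nrow(df) == 0L) return(invisible())
  pre <- df[[paste0(which, "_precursor_mz")]]
  prod <- df[[paste0(which, "_product_mz")]]
  bad <- df$analyte_name[is.na(pre) | is.na(prod) | !(pre > prod & prod > 0)]
  if (length(bad) > 0L) {
    stop(which, " transition must satisfy precursor m/z > product m/z > 0 ",
         "for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible()
}

#' Load the freshwater PNEC registry
#'
#' Predicted no-effect concentrations (ng/L, lowest recorded freshwater
#' values) per analyte, with the test organism and exposure type. Only
#' analytes present here can be risk-assessed by [assess_campaign()].
#'
#' @param path CSV with columns `analyte_name`, `pnec_ngL`, `organism`,
#'   `exposure_type` (`acute`, `chronic` or `unrecorded`).
#' @return a tibble.
#' @export
load_pnec_registry <- function(path) {
  req <- c("analyte_name", "pnec_ngL", "organism", "exposure_type")
  df <- .read_registry_csv(path, req)
  if (is.null(df)) {
    return(tibble::tibble(analyte_name = character(), pnec_ngL = numeric(),
                          organism = character(), exposure_type = character()))
  }
  df$pnec_ngL <- .parse_num(df$pnec_ngL, "pnec_ngL", path)
  if (any(is.na(df$pnec_ngL) | df$pnec_ngL <= 0)) {
    stop("pnec_ngL must be > 0 for every row", call. = FALSE)
  }
  bad <- setdiff(unique(df$exposure_type), c("acute", "chronic", "unrecorded"))
  if (length(bad) > 0L) {
    stop("invalid exposure_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$analyte_name)) {
    stop("duplicate analyte in PNEC registry", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Load site-day records (flow and population)
#'
#' One row per sampling day: influent flow entering the treatment works
#' (L/day) and the population served. Used by [aggregate_campaign()] to
#' turn concentrations into daily and population-normalised daily loads.
#'
#' @param path CSV with columns `day_id`, `flow_L_day`, `population`.
#' @return a tibble.
#' @export
load_site_days <- function(path) {
  req <- c("day_id", "flow_L_day", "population")
  df <- .read_registry_csv(path, req)
  if (is.null(df)) {
    return(tibble::tibble(day_id = integer(), flow_L_day = numeric(),
                          population = numeric()))
  }
  df$day_id <- as.integer(.parse_num(df$day_id, "day_id", path))
  df$flow_L_day <- .parse_num(df$flow_L_day, "flow_L_day", path)
  df$population <- .parse_num(df$population, "population", path)
  if (any(is.na(df$flow_L_day) | df$flow_L_day <= 0)) {
    stop("flow_L_day must be > 0", call. = FALSE)
  }
  if (any(is.na(df$population) | df$population <= 0 |
          df$population != round(df$population))) {
    stop("population must be a positive integer count", call. = FALSE)
  }
  if (anyDuplicated(df$day_id)) stop("duplicate day_id", call. = FALSE)
  tibble::as_tibble(df)
}

#' Path to a packaged example data file
#'
#' The package ships the published registry and performance tables as
#' plain-text fixtures: `analytes.csv` (MRM target list with calibration
#' ranges), `instrument_performance.csv`, `method_performance.csv`,
#' `pnec.csv`, `influent_days.csv`, `influent_summary.csv`, and
#' `site_days_synthetic.csv` (synthetic flows/population back-derived
#' from the reported loads; the real site records are not public).
#'
#' @param file file name under `extdata/`; with no argument, lists the
#'   available files.
#' @return a file path (or a character vector of file names).
#' @export
pfas_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pfastrace")))
  }
  path <- system.file("extdata", file, package = "pfastrace")
  if (identical(path, "")) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
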