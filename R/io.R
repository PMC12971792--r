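# CSV and JSON readers for the study schemas. All tabular I/O is plain CSV
# (RFC 4180 via utils::read.csv/write.csv); structured config is JSON.

#' @noRd
read_csv_checked <- function(path, cols, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, cols, sprintf("%s (%s)", what, basename(path)))
  df
}

#' @noRd
coerce_censored <- function(df, path) {
  df$censored <- as.logical(df$censored)
  if (any(is.na(df$censored)))
    stop(sprintf("'censored' column of %s has non-boolean entries",
                 basename(path)), call. = FALSE)
  bad <- !df$censored & (is.na(df$value) | df$value < 0)
  if (any(bad))
    stop(sprintf("%s: row %d has a missing/negative value but censored=FALSE",
                 basename(path), which(bad)[1]), call. = FALSE)
  bad_lod <- df$censored & (is.na(df$lod) | df$lod <= 0)
  if (any(bad_lod))
    stop(sprintf("%s: row %d is censored without a positive lod",
                 basename(path), which(bad_lod)[1]), call. = FALSE)
  df
}

#' Read study tables from CSV
#'
#' Validating readers for the study's CSV schemas:
#' * `soils.csv`: site_id, distance_km, timepoint, metal, concentration, sd
#' * `fractions.csv`: site_id, metal, schema, fraction_id, percent
#' * `tissues.csv`: plant_id, site_id, organ, metal, value, censored, lod
#' * `fruits.csv`: site_id, harvest_id, metal, value, censored, lod
#' * `absorbances.csv`: sample_id, a663, a647, a470
#' * `blanks.csv`: analyte, replicate, value (optional matrix_type)
#' * `crm.csv`: analyte, certified, certified_u, measured, measured_sd, n_reps
#' Schema violations raise errors naming the file and offending row/column.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @name readers
NULL

#' @rdname readers
#' @export
read_soils <- function(path) {
  df <- read_csv_checked(path, c("site_id", "distance_km", "timepoint",
                                 "metal", "concentration"), "soils table")
  if (any(!df$metal %in% .metals))
    stop(sprintf("%s: unknown metal '%s'", basename(path),
                 setdiff(df$metal, .metals)[1]), call. = FALSE)
  if (any(!df$timepoint %in% c("initial", "final")))
    stop(sprintf("%s: timepoint must be initial/final", basename(path)),
         call. = FALSE)
  if (any(df$concentration < 0, na.rm = TRUE))
    stop(sprintf("%s: negative concentration", basename(path)), call. = FALSE)
  df
}

#' @rdname readers
#' @export
read_fractions <- function(path) {
  df <- read_csv_checked(path, c("site_id", "metal", "schema", "fraction_id",
                                 "percent"), "fractions table")
  if (any(df$percent < 0 | df$percent > 100))
    stop(sprintf("%s: 'percent' outside [0, 100] at row %d", basename(path),
                 which(df$percent < 0 | df$percent > 100)[1]), call. = FALSE)
  # exercise the type validators on each site/metal F1-F2 pair
  keys <- unique(df[, c("site_id", "metal", "schema")])
  for (i in seq_len(nrow(keys))) {
    sel <- df$site_id == keys$site_id[i] & df$metal == keys$metal[i]
    f1 <- df$percent[sel & df$fraction_id == "F1"]
    f2 <- df$percent[sel & df$fraction_id == "F2"]
    if (length(f1) == 1 && length(f2) == 1)
      fraction_profile(keys$metal[i], keys$schema[i], f1, f2)
  }
  df
}

#' @rdname readers
#' @export
read_tissues <- function(path) {
  df <- read_csv_checked(path, c("plant_id", "site_id", "organ", "metal",
                                 "value", "censored", "lod"), "tissues table")
  if (any(!df$organ %in% .organs))
    stop(sprintf("%s: unknown organ", basename(path)), call. = FALSE)
  if (any(!df$metal %in% .metals))
    stop(sprintf("%s: unknown metal", basename(path)), call. = FALSE)
  coerce_censored(df, path)
}

#' @rdname readers
#' @export
read_fruits <- function(path) {
  df <- read_csv_checked(path, c("site_id", "harvest_id", "metal", "value",
                                 "censored", "lod"), "fruits table")
  if (any(!df$metal %in% .metals))
    stop(sprintf("%s: unknown metal", basename(path)), call. = FALSE)
  coerce_censored(df, path)
}

#' @rdname readers
#' @export
read_absorbances <- function(path) {
  df <- read_csv_checked(path, c("sample_id", "a663", "a647", "a470"),
                         "absorbance table")
  if (any(df$a663 < 0 | df$a647 < 0 | df$a470 < 0))
    stop(sprintf("%s: negative absorbance", basename(path)), call. = FALSE)
  df
}

#' @rdname readers
#' @export
read_blanks <- function(path) {
  read_csv_checked(path, c("analyte", "replicate", "value"), "blanks table")
}

#' @rdname readers
#' @export
read_crm <- function(path) {
  df <- read_csv_checked(path, c("analyte", "certified", "measured"),
                         "CRM table")
  if (any(df$certified <= 0))
    stop(sprintf("%s: certified value must be > 0", basename(path)),
         call. = FALSE)
  df
}

#' Read an exposure scenario and reference values from a JSON config
#'
#' The config carries an `"scenario"` block (fir_g_day, bw_kg, ef_days_yr,
#' ed_years, at_days) and a `"reference_values"` block (rfd, csf, bmdl,
#' ptwi, mac, each keyed by metal), plus free-text authority provenance.
#'
#' @param path Path to the JSON file.
#' @return A list with `scenario` ([exposure_scenario()]) and `refvals`
#'   ([reference_values()]).
#' @export
read_risk_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- cfg$scenario
  scenario <- exposure_scenario(fir_g_day = sc$fir_g_day, bw_kg = sc$bw_kg,
                                ef_days_yr = sc$ef_days_yr,
                                ed_years = sc$ed_years, at_days = sc$at_days)
  rv <- cfg$reference_values
  refvals <- reference_values(
    rfd = unlist(rv$rfd), csf = unlist(rv$csf),
    bmdl = lapply(rv$bmdl, unlist),
    ptwi = unlist(rv$ptwi),
    mac = lapply(rv$mac, unlist))
  list(scenario = scenario, refvals = refvals,
       provenance = cfg$provenance %||% NULL)
}

#' Path to the bundled example study
#'
#' A small screen-house study of sweet pepper (*Capsicum annuum*) grown on
#' three soils along a distance gradient from artisanal gold-mining
#' activity (Bolivar, Colombia): soil totals and physicochemistry,
#' sequential-extraction fractions, root tissue concentrations, four fruit
#' harvests with left-censored Pb/As entries, CRM checks, and the exposure
#' scenario and reference values used for risk characterization. See the
#' `NOTES.md` file in the directory for provenance of each table.
#'
#' @param file Optional file within the example directory.
#' @return A filesystem path.
#' @examples
#' read_fruits(example_study("fruits.csv"))
#' @export
example_study <- function(file = "") {
  system.file("extdata", "capsicum_study", file, package = "phytorisk",
              mustWork = TRUE)
}
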