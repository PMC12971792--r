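# Analytical quality control: detection/quantification limits from method
# blanks, CRM recovery, and the left-censoring rules applied to all
# measured concentrations.

#' Detection and quantification limits from method blanks
#'
#' LOD = 3 x sd(blanks), LOQ = 10 x sd(blanks) with the sample (n-1)
#' standard deviation, so LOQ/LOD is exactly 10/3 for any series. The blank
#' count is data, not a constant: supply whichever series the method used
#' (e.g. 7 blanks for soils, 10 for plant tissue).
#'
#' @param values Numeric vector of blank measurements (length >= 2, finite).
#' @return A list with `lod`, `loq`, `sd` and `n`. Constant blanks give
#'   `lod = loq = 0` with a degenerate-input warning.
#' @examples
#' detection_limits(c(0.01, 0.012, 0.009, 0.011, 0.010, 0.013, 0.008))
#' @export
detection_limits <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values)))
    stop("'values' must be >= 2 finite blank measurements", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    warning("constant blank series: LOD and LOQ are 0 (degenerate input)",
            call. = FALSE)
  list(lod = 3 * s, loq = 10 * s, sd = s, n = length(values))
}

#' Percent recovery against a certified reference material
#'
#' recovery = 100 x measured / certified. Report convention is 1 decimal.
#'
#' @param measured Measured concentration (vectorized).
#' @param certified Certified concentration (> 0, recycled).
#' @return Percent recovery at full precision.
#' @examples
#' recovery(0.67, 0.63)   # 106.3% at 1-decimal report
#' @export
recovery <- function(measured, certified) {
  if (any(!is.finite(certified)) || any(certified <= 0))
    stop("'certified' must be > 0", call. = FALSE)
  if (any(measured < 0, na.rm = TRUE))
    stop("'measured' must be >= 0", call. = FALSE)
  100 * measured / certified
}

#' Censoring status of an instrument reading
#'
#' Values below the LOD are censored (no numeric value carried: consumers
#' must branch on the flag); values in \[LOD, LOQ) are semi-quantitative;
#' values at or above the LOQ are quantitative. Negative instrument
#' readings (blank-corrected noise) are censored with a warning.
#'
#' @param value Instrument reading, concentration units.
#' @param lod,loq Detection and quantification limits, `lod <= loq`.
#' @return A list: `value` (`NA` when censored), `raw` (the input),
#'   `status` (ordered factor censored < semi_quantitative < quantitative),
#'   `lod`, and `label` (e.g. `"< 0.08"` for censored records).
#' @examples
#' apply_censoring(0.03, lod = 0.08, loq = 0.27)
#' @export
apply_censoring <- function(value, lod, loq) {
  assert_number(value, "value", allow_na = FALSE)
  assert_number(lod, "lod", lower = 0)
  assert_number(loq, "loq", lower = 0)
  if (lod > loq) stop("'lod' must be <= 'loq'", call. = FALSE)
  if (value < 0) {
    warning("negative instrument value censored below LOD", call. = FALSE)
    status <- "censored"
  } else if (value < lod) {
    status <- "censored"
  } else if (value < loq) {
    status <- "semi_quantitative"
  } else {
    status <- "quantitative"
  }
  censored <- status == "censored"
  list(value = if (censored) NA_real_ else value,
       raw = value,
       status = factor(status,
                       levels = c("censored", "semi_quantitative",
                                  "quantitative"),
                       ordered = TRUE),
       lod = lod,
       label = if (censored) paste0("< ", format(lod)) else format(value))
}

#' QC report: CRM recoveries against acceptance bounds
#'
#' @param crm Data frame with columns `analyte`, `certified`, `measured`
#'   (optional `certified_u`, `measured_sd`, `n_reps`).
#' @param bounds Acceptable recovery window, percent (default 90-110).
#' @return The input plus `recovery_pct` (full precision),
#'   `recovery_report` (1 decimal) and logical `pass`.
#' @export
qc_report <- function(crm, bounds = c(90, 110)) {
  assert_columns(crm, c("analyte", "certified", "measured"), "'crm'")
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("'bounds' must be an increasing pair", call. = FALSE)
  rec <- recovery(crm$measured, crm$certified)
  crm$recovery_pct <- rec
  crm$recovery_report <- round(rec, 1)
  crm$pass <- rec >= bounds[1] & rec <= bounds[2]
  crm
}
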