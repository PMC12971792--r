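# Report rendering and the end-to-end pipeline driver.

#' Render a risk value in report style
#'
#' Deterministic text rendering matching the conventions of published risk
#' tables: `NA` renders as `"NC"` (not calculated), exact zero as `"0"`,
#' magnitudes below 0.01 in scientific notation with 3 significant digits
#' (`"3.90E-04"`), everything else at 3 significant figures (`"0.132"`).
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @examples
#' render_value(c(0.00039, 0.1321, 0, NA))
#' @export
render_value <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NC")
    if (v == 0) return("0")
    if (abs(v) < 1e-2) return(toupper(formatC(v, format = "e", digits = 2)))
    format(signif(v, 3), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Render a censored concentration
#'
#' @param lod Detection limit(s).
#' @return `"< {lod}"` labels.
#' @export
render_censored <- function(lod) paste0("< ", vapply(lod, format, ""))

#' Wide risk report (one row per site x harvest)
#'
#' Reshapes a [risk_table()] result into the familiar published layout:
#' THQ per metal, HI and ILCR columns, every not-computable cell rendered
#' literally as `"NC"`.
#'
#' @param risk A `"risk_result"` from [risk_table()].
#' @return Data frame of rendered strings: `harvest_id`, `site_id`, one
#'   `thq_<metal>` column per metal present, `hi`, `ilcr`.
#' @export
risk_report <- function(risk) {
  if (!inherits(risk, "risk_result"))
    stop("'risk' must come from risk_table()", call. = FALSE)
  bm <- risk$by_metal
  bh <- risk$by_harvest
  metals <- intersect(.metals, unique(bm$metal))
  out <- bh[, c("harvest_id", "site_id")]
  for (m in metals) {
    col <- vapply(seq_len(nrow(bh)), function(i) {
      v <- bm$thq[bm$site_id == bh$site_id[i] &
                    bm$harvest_id == bh$harvest_id[i] & bm$metal == m]
      if (!length(v)) NA_real_ else v[1]
    }, numeric(1))
    out[[paste0("thq_", tolower(m))]] <- render_value(col)
  }
  out$hi <- render_value(bh$hi)
  out$ilcr <- vapply(seq_len(nrow(bh)), function(i) {
    sel <- bm$site_id == bh$site_id[i] & bm$harvest_id == bh$harvest_id[i] &
      !is.na(bm$ilcr)
    if (!any(sel)) "NC" else render_value(max(bm$ilcr[sel]))
  }, character(1))
  out
}

#' Fruit-concentration report with MAC screening
#'
#' One row per site x harvest x metal with the concentration rendered
#' (censored entries as `"< {LOD}"`) and a compliance flag per authority
#' limit.
#'
#' @param fruits Long fruit table (see [read_fruits()]).
#' @param refvals A [reference_values()] carrying the MAC tables.
#' @return Data frame: identifiers, `concentration` (rendered), then one
#'   status column per authority found in the MAC tables.
#' @export
fruit_mac_report <- function(fruits, refvals = default_reference_values()) {
  assert_columns(fruits, c("site_id", "harvest_id", "metal", "value",
                           "censored"), "'fruits'")
  authorities <- unique(unlist(lapply(refvals$mac, names)))
  out <- fruits[, c("site_id", "harvest_id", "metal")]
  out$concentration <- ifelse(fruits$censored, render_censored(fruits$lod),
                              vapply(fruits$value, format, ""))
  for (auth in authorities) {
    out[[auth]] <- vapply(seq_len(nrow(fruits)), function(i) {
      mac <- refvals$mac[[fruits$metal[i]]]
      if (is.null(mac) || !auth %in% names(mac)) return("NC")
      screen_mac(if (fruits$censored[i]) NA else fruits$value[i],
                 mac[auth], censored = fruits$censored[i])$status
    }, character(1))
  }
  out
}

#' RAC report from a long fractions table
#'
#' @param fractions Long table (see [read_fractions()]).
#' @param bands Band edges from [rac_bands()].
#' @return Data frame: `site_id`, `metal`, `schema`, `f1_pct`, `f2_pct`,
#'   `rac_pct`, `risk_band`.
#' @export
rac_report <- function(fractions, bands = rac_bands()) {
  assert_columns(fractions, c("site_id", "metal", "schema", "fraction_id",
                              "percent"), "'fractions'")
  keys <- unique(fractions[, c("site_id", "metal", "schema")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- fractions$site_id == keys$site_id[i] &
      fractions$metal == keys$metal[i]
    f1 <- fractions$percent[sel & fractions$fraction_id == "F1"]
    f2 <- fractions$percent[sel & fractions$fraction_id == "F2"]
    if (length(f1) != 1 || length(f2) != 1)
      stop(sprintf("site %s metal %s: need exactly one F1 and one F2 row",
                   keys$site_id[i], keys$metal[i]), call. = FALSE)
    r <- compute_rac(fraction_profile(keys$metal[i], keys$schema[i], f1, f2),
                     bands)
    data.frame(site_id = keys$site_id[i], metal = keys$metal[i],
               schema = keys$schema[i], f1_pct = f1, f2_pct = f2,
               rac_pct = r$rac_pct, risk_band = r$risk_band,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a study directory
#'
#' Reads the study CSVs (see [readers]) and the risk config, then chains
#' the soil, plant and dietary modules: RAC table from the fractions,
#' BCF/TF table from tissues and initial soils, MAC screening and the
#' per-harvest risk table from the fruits, and a QC recovery report when a
#' CRM table is present. Optionally writes rendered CSV reports plus a
#' machine-readable JSON summary carrying the same pre-rounding numbers
#' (single source of truth); reports are deterministic, so re-running on
#' identical inputs yields byte-identical files. Partial outputs are never
#' written: all tables are computed before the first file is emitted.
#'
#' @param input_dir Directory containing `fruits.csv` (required) and
#'   optionally `soils.csv`, `tissues.csv`, `fractions.csv`, `crm.csv`,
#'   `config.json`.
#' @param out_dir Optional output directory for rendered reports.
#' @param unit_mode ILCR unit mode, see [ilcr()].
#' @param config_file Risk config path; defaults to `config.json` in
#'   `input_dir`, falling back to package defaults when absent.
#' @return A list of class `"pipeline_result"` with `rac`, `bcf_tf`,
#'   `risk`, `risk_report`, `mac_report`, `qc`, `scenario`, `unit_mode`.
#' @export
run_full_pipeline <- function(input_dir, out_dir = NULL,
                              unit_mode = c("paper_compat", "strict_mg"),
                              config_file = file.path(input_dir,
                                                      "config.json")) {
  unit_mode <- match.arg(unit_mode)
  if (!dir.exists(input_dir)) stop("input_dir not found: ", input_dir,
                                   call. = FALSE)
  has <- function(f) file.exists(file.path(input_dir, f))
  cfg <- if (file.exists(config_file)) read_risk_config(config_file)
    else list(scenario = exposure_scenario(),
              refvals = default_reference_values())

  fruits <- read_fruits(file.path(input_dir, "fruits.csv"))
  risk <- risk_table(fruits, cfg$scenario, cfg$refvals, unit_mode)
  rendered <- risk_report(risk)
  mac_rep <- fruit_mac_report(fruits, cfg$refvals)

  rac <- if (has("fractions.csv"))
    rac_report(read_fractions(file.path(input_dir, "fractions.csv")))
  bcftf <- if (has("tissues.csv") && has("soils.csv"))
    bcf_tf_table(read_tissues(file.path(input_dir, "tissues.csv")),
                 read_soils(file.path(input_dir, "soils.csv")))
  qc <- if (has("crm.csv"))
    qc_report(read_crm(file.path(input_dir, "crm.csv")))

  res <- structure(list(rac = rac, bcf_tf = bcftf, risk = risk,
                        risk_report = rendered, mac_report = mac_rep,
                        qc = qc, scenario = cfg$scenario,
                        unit_mode = unit_mode),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rendered, file.path(out_dir, "risk_report.csv"),
                     row.names = FALSE)
    utils::write.csv(mac_rep, file.path(out_dir, "mac_report.csv"),
                     row.names = FALSE)
    if (!is.null(rac))
      utils::write.csv(rac, file.path(out_dir, "rac_report.csv"),
                       row.names = FALSE)
    if (!is.null(bcftf)) {
      tab <- bcftf
      tab$bcf <- render_value(tab$bcf_report)
      tab$tf <- render_value(tab$tf_report)
      utils::write.csv(tab[, c("site_id", "metal", "bcf", "tf",
                               "accumulator_class")],
                       file.path(out_dir, "bcf_tf_report.csv"),
                       row.names = FALSE)
    }
    if (!is.null(qc))
      utils::write.csv(qc, file.path(out_dir, "qc_report.csv"),
                       row.names = FALSE)
    summary <- list(unit_mode = unit_mode,
                    scenario = unclass(cfg$scenario),
                    risk_by_metal = risk$by_metal,
                    risk_by_harvest = risk$by_harvest)
    if (!is.null(bcftf)) summary$bcf_tf <- bcftf
    if (!is.null(rac)) summary$rac <- rac
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("Risk report (", x$unit_mode, "):\n", sep = "")
  print(x$risk_report)
  if (!is.null(x$bcf_tf)) { cat("\nBCF/TF:\n"); print(x$bcf_tf) }
  if (!is.null(x$rac)) { cat("\nRAC:\n"); print(x$rac) }
  invisible(x)
}
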