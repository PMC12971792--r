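# Dietary exposure and risk characterization: EDI, CDI, THQ, HI, ILCR,
# MOE, weekly intake vs PTWI, and MAC screening of fruit concentrations.

#' Construct an exposure scenario
#'
#' The intake parameters of the USEPA deterministic exposure model. The
#' defaults describe chronic adult consumption: 250 g of the vegetable per
#' week (35.7 g/day), 70 kg body weight, daily exposure (365 days/yr) over a
#' 70-year lifetime averaged over 25550 days. Under these defaults
#' `ef * ed == at`, so CDI equals EDI exactly.
#'
#' @param fir_g_day Food intake rate, g person^-1 day^-1.
#' @param bw_kg Body weight, kg.
#' @param ef_days_yr Exposure frequency, days year^-1.
#' @param ed_years Exposure duration, years.
#' @param at_days Averaging time, days.
#' @return An object of class `"exposure_scenario"`.
#' @examples
#' exposure_scenario()
#' @export
exposure_scenario <- function(fir_g_day = 35.7, bw_kg = 70,
                              ef_days_yr = 365, ed_years = 70,
                              at_days = 25550) {
  for (nm in c("fir_g_day", "bw_kg", "ef_days_yr", "ed_years", "at_days")) {
    v <- get(nm)
    assert_number(v, nm)
    if (v <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  structure(list(fir_g_day = fir_g_day, bw_kg = bw_kg,
                 ef_days_yr = ef_days_yr, ed_years = ed_years,
                 at_days = at_days),
            class = "exposure_scenario")
}

#' Construct a per-metal reference-value set
#'
#' Toxicological and regulatory reference values used by the risk indices:
#' oral reference doses (RfD, mg kg^-1 day^-1), oral cancer slope factors
#' (CSF, (mg kg^-1 day^-1)^-1; absent for Hg), benchmark-dose lower bounds
#' (BMDL, ug kg^-1 BW day^-1, one per endpoint), provisional tolerable
#' weekly intakes (PTWI, ug kg^-1 BW week^-1) and maximum allowed
#' concentrations in the food (MAC, mg kg^-1, one per authority).
#'
#' @param rfd Named numeric vector (metal -> RfD).
#' @param csf Named numeric vector (metal -> CSF); metals without a slope
#'   factor are simply absent.
#' @param bmdl Named list: metal -> named numeric vector endpoint -> BMDL.
#' @param ptwi Named numeric vector (metal -> PTWI).
#' @param mac Named list: metal -> named numeric vector authority -> MAC.
#' @return An object of class `"reference_values"`.
#' @seealso [default_reference_values()]
#' @export
reference_values <- function(rfd, csf = numeric(), bmdl = list(),
                             ptwi = numeric(), mac = list()) {
  chk_pos <- function(x, nm) {
    if (length(x) && (!is.numeric(x) || any(x <= 0, na.rm = TRUE)))
      stop(sprintf("'%s' values must be positive", nm), call. = FALSE)
  }
  chk_pos(rfd, "rfd"); chk_pos(csf, "csf"); chk_pos(ptwi, "ptwi")
  lapply(bmdl, chk_pos, nm = "bmdl")
  lapply(mac, chk_pos, nm = "mac")
  structure(list(rfd = rfd, csf = csf, bmdl = bmdl, ptwi = ptwi, mac = mac),
            class = "reference_values")
}

#' Default reference values for Hg, Pb and As
#'
#' USEPA RfDs (Hg and As 0.0003, Pb 0.0035 mg kg^-1 day^-1); OEHHA oral
#' slope factors (Pb 0.0085, As 1.5); EFSA lead BMDLs (children IQ 0.5,
#' adult chronic kidney disease 0.63, adult systolic blood pressure 1.50
#' ug kg^-1 BW day^-1); the JECFA PTWI for Hg (4 ug kg^-1 BW week^-1); and
#' vegetable MACs from GB 2762-2022 (Hg 0.01, Pb 0.1, As 0.5 mg kg^-1) and
#' the Codex Alimentarius (Pb 0.05 mg kg^-1).
#'
#' @return A [reference_values()] object.
#' @export
default_reference_values <- function() {
  reference_values(
    rfd = c(Hg = 0.0003, Pb = 0.0035, As = 0.0003),
    csf = c(Pb = 0.0085, As = 1.5),
    bmdl = list(Pb = c(children_iq = 0.5, adults_ckd = 0.63,
                       adults_sbp = 1.50)),
    ptwi = c(Hg = 4),
    mac = list(Hg = c(`GB 2762-2022` = 0.01),
               Pb = c(`GB 2762-2022` = 0.1, `Codex CXS 193-1995` = 0.05),
               As = c(`GB 2762-2022` = 0.5)))
}

#' Estimated daily intake (EDI)
#'
#' EDI = FIR x C / BW, the daily dose per kg body weight from consuming the
#' food at the scenario's intake rate. Returned in mg kg^-1 BW day^-1 (the
#' FIR in g/day is converted to kg/day); use [edi_ug()] for the ug-scale
#' representation.
#'
#' @param c_fruit Metal concentration in the food, mg kg^-1 (vectorized).
#' @param scenario An [exposure_scenario()].
#' @param censored Logical (recycled): censored concentrations yield `NA`
#'   (not computable) rather than a substituted number.
#' @return EDI in mg kg^-1 BW day^-1.
#' @examples
#' edi(0.090)          # Pb, first harvest
#' edi_ug(0.090)       # 0.0459 ug kg-1 BW day-1, prints as 0.046
#' @export
edi <- function(c_fruit, scenario = exposure_scenario(), censored = FALSE) {
  if (!inherits(scenario, "exposure_scenario"))
    stop("'scenario' must be an exposure_scenario", call. = FALSE)
  if (any(c_fruit < 0, na.rm = TRUE))
    stop("'c_fruit' must be >= 0", call. = FALSE)
  out <- (scenario$fir_g_day / 1000) * c_fruit / scenario$bw_kg
  out[rep_len(censored, length(out))] <- NA_real_
  out
}

#' @rdname edi
#' @export
edi_ug <- function(c_fruit, scenario = exposure_scenario(),
                   censored = FALSE) {
  1000 * edi(c_fruit, scenario, censored)
}

#' Chronic daily intake (CDI)
#'
#' CDI = EDI x EF x ED / AT. Under the default scenario (EF 365, ED 70,
#' AT 25550) the scaling factor is exactly 1, so CDI equals EDI.
#'
#' @param edi EDI, mg kg^-1 BW day^-1 (vectorized; `NA` propagates).
#' @param scenario An [exposure_scenario()].
#' @return CDI in the same units as `edi`.
#' @export
cdi <- function(edi, scenario = exposure_scenario()) {
  if (!inherits(scenario, "exposure_scenario"))
    stop("'scenario' must be an exposure_scenario", call. = FALSE)
  # single scaling factor: exactly 1 under the default scenario
  edi * (scenario$ef_days_yr * scenario$ed_years / scenario$at_days)
}

#' Target hazard quotient (THQ)
#'
#' THQ = CDI / RfD; a quotient above 1 signals potential non-carcinogenic
#' risk. Report convention is 3 significant figures (see [render_value()]).
#'
#' @param cdi Chronic daily intake, mg kg^-1 day^-1 (vectorized; `NA`
#'   propagates as NC).
#' @param rfd Oral reference dose, mg kg^-1 day^-1 (> 0).
#' @param metal Optional metal label used in error messages.
#' @return Dimensionless hazard quotient.
#' @examples
#' thq(cdi(edi(0.07)), rfd = 0.0003)   # 0.119
#' @export
thq <- function(cdi, rfd, metal = NULL) {
  if (length(rfd) != 1L || is.na(rfd) || !is.numeric(rfd) || rfd <= 0)
    stop(sprintf("missing or non-positive RfD%s",
                 if (is.null(metal)) "" else paste0(" for ", metal)),
         call. = FALSE)
  cdi / rfd
}

#' Hazard index (HI)
#'
#' HI is the sum of the THQs over metals; not-computable (NC, `NA`) metals
#' are excluded rather than imputed as zero. HI below 1 indicates
#' negligible aggregate non-carcinogenic risk.
#'
#' @param thqs Numeric vector of per-metal THQs (`NA` = NC).
#' @return A list with `hi` (`NA` when every THQ is NC) and `band`
#'   (`"negligible"`, `"potential_adverse"` or `"NC"`).
#' @examples
#' hi(c(Hg = 0.119, Pb = 0.0131))
#' @export
hi <- function(thqs) {
  computed <- thqs[!is.na(thqs)]
  if (!length(computed)) return(list(hi = NA_real_, band = "NC"))
  if (any(computed < 0)) stop("THQ values must be >= 0", call. = FALSE)
  h <- sum(computed)
  list(hi = h, band = if (h < 1) "negligible" else "potential_adverse")
}

#' Classify an incremental lifetime cancer risk value
#'
#' USEPA bands: below 1e-6 negligible; 1e-6 to 1e-4 acceptable; above 1e-4
#' potential concern; above 1e-3 moderate risk (public-health issue).
#'
#' @param x Numeric ILCR values (`NA` = NC).
#' @return Character vector of band labels.
#' @export
classify_ilcr <- function(x) {
  ifelse(is.na(x), "NC",
    ifelse(x < 1e-6, "negligible",
      ifelse(x <= 1e-4, "acceptable",
        ifelse(x <= 1e-3, "potential_concern", "moderate_risk"))))
}

#' Incremental lifetime cancer risk (ILCR)
#'
#' ILCR = CDI x CSF. Two unit modes are provided because the source risk
#' table is only reproduced when CDI enters the product expressed in
#' ug kg^-1 day^-1 against the same CSF value:
#' * `"paper_compat"` (default for reproduction runs): CDI in ug kg^-1
#'   day^-1 (i.e. 1000 x the mg-scale CDI) times CSF.
#' * `"strict_mg"`: the dimensionally standard USEPA form, CDI in mg kg^-1
#'   day^-1 times CSF. Exactly `paper_compat / 1000` for every input.
#' The 1000x gap between the modes is reported loudly at computation time
#' (`message`) the first time a conversion runs in a session.
#'
#' @param cdi Chronic daily intake in mg kg^-1 day^-1 (vectorized; `NA`
#'   propagates as NC).
#' @param csf Oral cancer slope factor; `NA` (no slope factor, e.g. Hg)
#'   yields NC with a warning.
#' @param unit_mode `"paper_compat"` or `"strict_mg"`.
#' @return Numeric ILCR values; classify with [classify_ilcr()].
#' @examples
#' ilcr(cdi(edi(0.090)), csf = 0.0085)                      # 3.90e-4
#' ilcr(cdi(edi(0.090)), csf = 0.0085, unit_mode = "strict_mg")  # 3.90e-7
#' @export
ilcr <- function(cdi, csf, unit_mode = c("paper_compat", "strict_mg")) {
  unit_mode <- match.arg(unit_mode)
  if (length(csf) != 1L || is.na(csf)) {
    warning("no cancer slope factor available: ILCR not computed (NC)",
            call. = FALSE)
    return(rep(NA_real_, length(cdi)))
  }
  if (!is.numeric(csf) || csf <= 0) stop("'csf' must be > 0", call. = FALSE)
  scale <- if (unit_mode == "paper_compat") 1000 else 1
  cdi * scale * csf
}

#' Margin of exposure (MOE)
#'
#' MOE = BMDL / EDI, both in ug kg^-1 BW day^-1, one value per benchmark
#' endpoint. Reports round to the nearest integer; an MOE below 10 flags
#' concern (EFSA threshold), and values in \[10, 15) carry a near-threshold
#' flag because they sit close to the boundary.
#'
#' @param bmdl Named numeric vector of benchmark-dose lower bounds,
#'   ug kg^-1 BW day^-1 (names are endpoints).
#' @param edi_ug Estimated daily intake, ug kg^-1 BW day^-1 (a single
#'   value; 0 yields infinite MOE reported as no-concern).
#' @return Data frame: `endpoint`, `bmdl`, `moe` (full precision),
#'   `moe_rounded`, `concern`, `near_threshold`.
#' @examples
#' moe(c(adults_sbp = 1.50, children_iq = 0.5), edi_ug(0.090))
#' @export
moe <- function(bmdl, edi_ug) {
  if (!is.numeric(bmdl) || !length(bmdl) || any(bmdl <= 0, na.rm = TRUE))
    stop("'bmdl' must be positive", call. = FALSE)
  assert_number(edi_ug, "edi_ug", lower = 0)
  m <- if (edi_ug == 0) rep(Inf, length(bmdl)) else bmdl / edi_ug
  data.frame(endpoint = names(bmdl) %||% rep(NA_character_, length(bmdl)),
             bmdl = unname(bmdl), moe = unname(m),
             moe_rounded = round(unname(m)),
             concern = unname(m) < 10,
             near_threshold = unname(m) >= 10 & unname(m) < 15,
             stringsAsFactors = FALSE)
}

#' Weekly intake and comparison with the PTWI
#'
#' Weekly intake = 7 x EDI (ug kg^-1 BW week^-1); when a provisional
#' tolerable weekly intake is available the fraction consumed of it is
#' reported.
#'
#' @param edi_ug Estimated daily intake, ug kg^-1 BW day^-1 (>= 0).
#' @param ptwi PTWI, ug kg^-1 BW week^-1, or `NA` when not established.
#' @return A list with `weekly` and `ptwi_fraction` (`NA` without a PTWI).
#' @examples
#' weekly_intake(0.037, ptwi = 4)
#' @export
weekly_intake <- function(edi_ug, ptwi = NA_real_) {
  assert_number(edi_ug, "edi_ug", lower = 0)
  assert_number(ptwi, "ptwi", allow_na = TRUE)
  weekly <- 7 * edi_ug
  list(weekly = weekly,
       ptwi_fraction = if (is.na(ptwi)) NA_real_ else weekly / ptwi)
}

#' Screen a food concentration against maximum allowed concentrations
#'
#' Exceeds when the concentration is strictly above the authority's limit;
#' equality is compliant. Censored concentrations are compliant-by-default
#' and carry a `"censored_compliant"` status.
#'
#' @param c_fruit Concentration, mg kg^-1.
#' @param mac Named numeric vector authority -> limit (mg kg^-1); an empty
#'   vector returns a single NC row.
#' @param censored Logical: is the concentration below detection?
#' @return Data frame: `authority`, `limit`, `status`.
#' @examples
#' screen_mac(0.090, c(`GB 2762-2022` = 0.1, `Codex CXS 193-1995` = 0.05))
#' @export
screen_mac <- function(c_fruit, mac, censored = FALSE) {
  if (!length(mac))
    return(data.frame(authority = NA_character_, limit = NA_real_,
                      status = "NC", stringsAsFactors = FALSE))
  if (any(mac <= 0)) stop("MAC limits must be > 0", call. = FALSE)
  status <- if (censored) rep("censored_compliant", length(mac)) else {
    assert_number(c_fruit, "c_fruit", lower = 0)
    ifelse(c_fruit > mac, "exceeds", "compliant")
  }
  data.frame(authority = names(mac) %||% rep(NA_character_, length(mac)),
             limit = unname(mac), status = status, stringsAsFactors = FALSE)
}

#' Per-harvest dietary risk table
#'
#' Runs the full index chain (EDI -> CDI -> THQ, ILCR) on a long-format
#' fruit-concentration table, one record per site x harvest x metal, and
#' aggregates HI per site x harvest. Censored concentrations propagate as
#' NC throughout (no LOD substitution by default; see `censored_policy`).
#'
#' @param fruits Data frame with columns `site_id`, `harvest_id`, `metal`,
#'   `value`, `censored` (optional `lod`).
#' @param scenario An [exposure_scenario()].
#' @param refvals A [reference_values()] object.
#' @param unit_mode ILCR unit mode, see [ilcr()].
#' @param censored_policy `"nc"` (default: censored -> NC) or `"half_lod"`
#'   (sensitivity analysis: substitute LOD/2; requires an `lod` column).
#' @return A list of class `"risk_result"`:
#'   * `by_metal` - long data frame with `c_fruit`, `censored`, `edi_mg`,
#'     `edi_ug`, `cdi_mg`, `thq`, `ilcr`, `ilcr_band` per record;
#'   * `by_harvest` - `site_id`, `harvest_id`, `hi`, `hi_band`;
#'   * `scenario`, `unit_mode`.
#' @examples
#' fr <- data.frame(site_id = "S2", harvest_id = "C1",
#'                  metal = c("Hg", "Pb"), value = c(0.07, 0.090),
#'                  censored = FALSE)
#' risk_table(fr)
#' @export
risk_table <- function(fruits, scenario = exposure_scenario(),
                       refvals = default_reference_values(),
                       unit_mode = c("paper_compat", "strict_mg"),
                       censored_policy = c("nc", "half_lod")) {
  unit_mode <- match.arg(unit_mode)
  censored_policy <- match.arg(censored_policy)
  assert_columns(fruits, c("site_id", "harvest_id", "metal", "value",
                           "censored"), "'fruits'")
  if (!inherits(refvals, "reference_values"))
    stop("'refvals' must be a reference_values object", call. = FALSE)
  if (nrow(fruits) == 0)
    warning("empty fruit table: risk report is all-NC", call. = FALSE)

  fr <- fruits
  if (censored_policy == "half_lod" && any(fr$censored)) {
    assert_columns(fr, "lod", "'fruits' (half_lod policy)")
    fr$value[fr$censored] <- fr$lod[fr$censored] / 2
    fr$censored <- FALSE
  }

  n <- nrow(fr)
  edi_mg <- cdi_mg <- thq_v <- ilcr_v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (fr$censored[i]) next
    m <- fr$metal[i]
    edi_mg[i] <- edi(fr$value[i], scenario)
    cdi_mg[i] <- cdi(edi_mg[i], scenario)
    rfd <- refvals$rfd[m]
    thq_v[i] <- thq(cdi_mg[i], rfd, metal = m)
    csf <- refvals$csf[m]
    if (!is.na(csf))
      ilcr_v[i] <- ilcr(cdi_mg[i], unname(csf), unit_mode)
  }
  by_metal <- data.frame(
    site_id = fr$site_id, harvest_id = fr$harvest_id, metal = fr$metal,
    c_fruit = ifelse(fr$censored, NA_real_, fr$value),
    censored = fr$censored,
    edi_mg = edi_mg, edi_ug = 1000 * edi_mg, cdi_mg = cdi_mg,
    thq = thq_v, ilcr = ilcr_v, ilcr_band = classify_ilcr(ilcr_v),
    stringsAsFactors = FALSE)

  keys <- unique(by_metal[, c("site_id", "harvest_id")])
  by_harvest <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- by_metal$site_id == keys$site_id[i] &
      by_metal$harvest_id == keys$harvest_id[i]
    h <- hi(by_metal$thq[sel])
    data.frame(site_id = keys$site_id[i], harvest_id = keys$harvest_id[i],
               hi = h$hi, hi_band = h$band, stringsAsFactors = FALSE)
  }))
  structure(list(by_metal = by_metal, by_harvest = by_harvest,
                 scenario = scenario, unit_mode = unit_mode),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %d records, unit_mode = %s\n",
              nrow(x$by_metal), x$unit_mode))
  print(utils::head(x$by_metal, 8))
  invisible(x)
}
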