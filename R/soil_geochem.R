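# Soil-side data model: metal totals, sequential-extraction fraction
# profiles, Risk Assessment Code and regulatory screening.

#' Construct a soil sample record
#'
#' A soil sample carries total metal concentrations (mg kg^-1 dry soil) for
#' one site and timepoint, plus the physicochemistry that governs metal
#' mobility (pH, organic matter, texture). Uncertainties ("±" values) are
#' carried alongside the means but only means enter computations.
#'
#' @param site_id Site label (e.g. `"S1"`).
#' @param distance_km Distance from the contamination source, km (>= 0).
#' @param timepoint `"initial"` (pre-cultivation) or `"final"` (post-harvest).
#' @param metal_totals Named numeric vector of total concentrations,
#'   mg kg^-1 dry soil; names are metals (`"Hg"`, `"Pb"`, `"As"`).
#' @param metal_sd Optional named numeric vector of standard deviations.
#' @param ph Soil pH in (0, 14); `NA` if unmeasured.
#' @param om_pct Organic-matter content, percent.
#' @param texture Textural class label (e.g. `"loamy"`).
#' @return An object of class `"soil_sample"`.
#' @examples
#' soil_sample("S1", 0.6, "initial",
#'             c(Hg = 22.13, Pb = 1997.02, As = 37.52), ph = 4.62)
#' @export
soil_sample <- function(site_id, distance_km,
                        timepoint = c("initial", "final"),
                        metal_totals, metal_sd = NULL,
                        ph = NA_real_, om_pct = NA_real_,
                        texture = NA_character_) {
  timepoint <- match.arg(timepoint)
  assert_number(distance_km, "distance_km", lower = 0)
  if (!is.numeric(metal_totals) || is.null(names(metal_totals)) ||
      any(!nzchar(names(metal_totals))))
    stop("'metal_totals' must be a named numeric vector", call. = FALSE)
  if (any(metal_totals < 0, na.rm = TRUE))
    stop("metal concentrations must be >= 0", call. = FALSE)
  assert_number(ph, "ph", allow_na = TRUE)
  if (!is.na(ph) && (ph <= 0 || ph >= 14))
    stop("'ph' must lie in (0, 14)", call. = FALSE)
  if (!is.null(metal_sd)) {
    extra <- setdiff(names(metal_sd), names(metal_totals))
    if (length(extra))
      stop("metal_sd given for metals without totals: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(
    list(site_id = as.character(site_id), distance_km = distance_km,
         timepoint = timepoint, metal_totals = metal_totals,
         metal_sd = metal_sd, ph = ph, om_pct = om_pct, texture = texture),
    class = "soil_sample")
}

#' @export
print.soil_sample <- function(x, ...) {
  cat(sprintf("<soil_sample> %s (%.1f km, %s)\n", x$site_id, x$distance_km,
              x$timepoint))
  print(x$metal_totals)
  invisible(x)
}

#' Construct a sequential-extraction fraction profile
#'
#' Fraction percentages of one metal under a named extraction scheme. The
#' Bloom scheme (water-soluble F1, stomach-acid-soluble F2) applies to Hg;
#' the Tessier scheme (exchangeable F1, carbonate-bound F2) applies to Pb
#' and As. F1 and F2 are the bioavailable fractions that enter the Risk
#' Assessment Code.
#'
#' @param metal `"Hg"`, `"Pb"` or `"As"`.
#' @param schema `"bloom"` (Hg only) or `"tessier"` (Pb/As only).
#' @param f1_pct,f2_pct Fraction percentages in \[0, 100\].
#' @param residual_pct Optional residual-fraction percentage.
#' @return An object of class `"fraction_profile"`.
#' @examples
#' fraction_profile("Pb", "tessier", f1_pct = 10.99, f2_pct = 4.35)
#' @export
fraction_profile <- function(metal, schema = c("bloom", "tessier"),
                             f1_pct, f2_pct, residual_pct = NA_real_) {
  assert_metal(metal)
  schema <- match.arg(schema)
  if (schema == "bloom" && metal != "Hg")
    stop("the 'bloom' scheme is only valid for Hg", call. = FALSE)
  if (schema == "tessier" && metal == "Hg")
    stop("the 'tessier' scheme is only valid for Pb and As", call. = FALSE)
  assert_number(f1_pct, "f1_pct", lower = 0, upper = 100)
  assert_number(f2_pct, "f2_pct", lower = 0, upper = 100)
  assert_number(residual_pct, "residual_pct", lower = 0, upper = 100,
                allow_na = TRUE)
  if (f1_pct + f2_pct > 100 + 1e-9)
    stop("f1_pct + f2_pct exceeds 100%", call. = FALSE)
  structure(list(metal = metal, schema = schema, f1_pct = f1_pct,
                 f2_pct = f2_pct, residual_pct = residual_pct),
            class = "fraction_profile")
}

#' Risk Assessment Code band edges
#'
#' Default bands are contiguous and half-open: no risk \[0, 1), low \[1, 10),
#' medium \[10, 30), high \[30, 50), very high \[50, 100\]. Edges are
#' configurable so alternative published threshold sets can be restored.
#'
#' @param breaks Strictly increasing numeric vector of four interior band
#'   edges, each in (0, 100).
#' @return A list with `breaks` and `labels`, class `"rac_bands"`.
#' @export
rac_bands <- function(breaks = c(1, 10, 30, 50)) {
  if (!is.numeric(breaks) || length(breaks) != 4L ||
      any(diff(breaks) <= 0) || any(breaks <= 0) || any(breaks >= 100))
    stop("'breaks' must be 4 strictly increasing values in (0, 100)",
         call. = FALSE)
  structure(list(breaks = breaks,
                 labels = c("no_risk", "low", "medium", "high", "very_high")),
            class = "rac_bands")
}

#' Classify a Risk Assessment Code percentage into a risk band
#'
#' @param rac_pct Numeric vector of RAC percentages in \[0, 100\].
#' @param bands Band edges from [rac_bands()].
#' @return Character vector of band labels; lower band edges are inclusive
#'   (RAC = 1 is `"low"`).
#' @examples
#' classify_rac(c(0.5, 6.65, 15.34))
#' @export
classify_rac <- function(rac_pct, bands = rac_bands()) {
  if (!inherits(bands, "rac_bands")) stop("'bands' must come from rac_bands()")
  if (!is.numeric(rac_pct) || any(is.na(rac_pct)))
    stop("'rac_pct' must be numeric without NA", call. = FALSE)
  if (any(rac_pct < 0 | rac_pct > 100))
    stop("'rac_pct' must lie in [0, 100]", call. = FALSE)
  bands$labels[findInterval(rac_pct, bands$breaks) + 1L]
}

#' Compute the Risk Assessment Code of a fraction profile
#'
#' RAC = F1 + F2: the sum of the percentages of metal held in the two
#' bioavailable sequential-extraction fractions, classified into an
#' environmental-risk band.
#'
#' @param profile A [fraction_profile()].
#' @param bands Band edges from [rac_bands()].
#' @return An object of class `"rac_result"`: a list with `metal`,
#'   `rac_pct` (exactly `f1_pct + f2_pct`) and `risk_band`.
#' @examples
#' compute_rac(fraction_profile("Pb", "tessier", 10.99, 4.35))
#' @export
compute_rac <- function(profile, bands = rac_bands()) {
  if (!inherits(profile, "fraction_profile"))
    stop("'profile' must be a fraction_profile", call. = FALSE)
  rac <- profile$f1_pct + profile$f2_pct
  structure(list(metal = profile$metal, rac_pct = rac,
                 risk_band = classify_rac(rac, bands)),
            class = "rac_result")
}

#' @export
print.rac_result <- function(x, ...) {
  cat(sprintf("<rac_result> %s: RAC = %.2f%% (%s)\n",
              x$metal, x$rac_pct, x$risk_band))
  invisible(x)
}

#' Construct a regulatory soil-limit table
#'
#' @param metal Character vector of metals.
#' @param lower,upper Permissible bounds, mg kg^-1 (lower may be `NA` when an
#'   authority publishes a single screening value).
#' @param authority Provenance label per row.
#' @return A data frame of class `"soil_limit_table"`.
#' @export
soil_limit_table <- function(metal, lower, upper, authority) {
  if (any(!metal %in% .metals)) stop("unknown metal in limit table")
  if (any(upper <= 0, na.rm = TRUE) || any(lower <= 0, na.rm = TRUE))
    stop("limit bounds must be > 0", call. = FALSE)
  ok <- is.na(lower) | lower <= upper
  if (!all(ok)) stop("lower bound exceeds upper bound", call. = FALSE)
  structure(data.frame(metal = metal, lower = lower, upper = upper,
                       authority = authority, stringsAsFactors = FALSE),
            class = c("soil_limit_table", "data.frame"))
}

#' Default regulatory soil limits
#'
#' EEC ranges for Pb (50-300 mg kg^-1) and Hg (1-1.5 mg kg^-1) plus the
#' Eco-SSL screening value for As (18 mg kg^-1, applied as an upper bound).
#'
#' @return A [soil_limit_table()].
#' @export
default_soil_limits <- function() {
  soil_limit_table(metal = c("Pb", "Hg", "As"),
                   lower = c(50, 1, NA),
                   upper = c(300, 1.5, 18),
                   authority = c("EEC", "EEC", "Eco-SSL"))
}

#' Screen soil totals against regulatory limits
#'
#' A metal exceeds when its total is strictly greater than the upper
#' permissible bound; equality is compliant. Metals listed in the limit
#' table but absent from the sample are flagged `"missing"`, never skipped.
#'
#' @param sample A [soil_sample()].
#' @param limits A [soil_limit_table()].
#' @return Data frame with columns `metal`, `total`, `upper`, `authority`,
#'   `status` (`"exceeds"`, `"within"` or `"missing"`).
#' @export
screen_soil_limits <- function(sample, limits = default_soil_limits()) {
  if (!inherits(sample, "soil_sample")) stop("'sample' must be a soil_sample")
  if (!inherits(limits, "soil_limit_table"))
    stop("'limits' must be a soil_limit_table")
  total <- sample$metal_totals[limits$metal]
  status <- ifelse(is.na(total), "missing",
                   ifelse(total > limits$upper, "exceeds", "within"))
  data.frame(metal = limits$metal, total = unname(total),
             upper = limits$upper, authority = limits$authority,
             status = status, stringsAsFactors = FALSE)
}

#' Per-metal concentration change between two timepoints
#'
#' @param initial,final [soil_sample()] objects for the same site at
#'   timepoints `"initial"` and `"final"`.
#' @return Data frame with `metal`, `initial`, `final`, `change`
#'   (final - initial), `pct_change` (relative to initial; `NA` with
#'   `pct_defined = FALSE` when initial is 0).
#' @export
concentration_change <- function(initial, final) {
  if (!inherits(initial, "soil_sample") || !inherits(final, "soil_sample"))
    stop("inputs must be soil_sample objects", call. = FALSE)
  if (initial$site_id != final$site_id)
    stop("samples are from different sites", call. = FALSE)
  if (initial$timepoint != "initial" || final$timepoint != "final")
    stop("expected timepoints 'initial' and 'final'", call. = FALSE)
  metals <- intersect(names(initial$metal_totals), names(final$metal_totals))
  if (!length(metals)) stop("no metals in common", call. = FALSE)
  ci <- initial$metal_totals[metals]
  cf <- final$metal_totals[metals]
  delta <- cf - ci
  defined <- ci != 0
  pct <- ifelse(defined, 100 * delta / ci, NA_real_)
  data.frame(metal = metals, initial = unname(ci), final = unname(cf),
             change = unname(delta), pct_change = unname(pct),
             pct_defined = unname(defined), stringsAsFactors = FALSE)
}
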