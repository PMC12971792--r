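# Plant-side computations: bioconcentration and translocation factors,
# accumulator classification, punch-method leaf area and Lichtenthaler
# pigment quantification.

#' Construct a tissue concentration record
#'
#' One organ-level metal concentration (mg kg^-1 dry weight). Values below
#' the instrument detection limit are stored as censored records carrying
#' the LOD, never as substituted numbers; downstream ratio operations
#' propagate censoring as "not computable" (NC).
#'
#' @param plant_id,site_id Labels.
#' @param organ One of `"root"`, `"stem"`, `"leaf"`, `"fruit"`.
#' @param metal `"Hg"`, `"Pb"` or `"As"`.
#' @param value Concentration, mg kg^-1 dry weight; `NA` when censored.
#' @param censored Logical: value below detection limit?
#' @param lod Detection limit; required (positive) when `censored = TRUE`.
#' @return An object of class `"tissue_concentration"`.
#' @examples
#' tissue_concentration("P1", "S1", "root", "Hg", 2.29)
#' tissue_concentration("P9", "S3", "root", "Pb", NA, censored = TRUE, lod = 0.08)
#' @export
tissue_concentration <- function(plant_id, site_id, organ, metal,
                                 value, censored = FALSE, lod = NA_real_) {
  if (!organ %in% .organs)
    stop(sprintf("'organ' must be one of %s", paste(.organs, collapse = ", ")),
         call. = FALSE)
  assert_metal(metal)
  if (!is.logical(censored) || length(censored) != 1L || is.na(censored))
    stop("'censored' must be TRUE or FALSE", call. = FALSE)
  if (censored) {
    assert_number(lod, "lod")
    if (lod <= 0) stop("censored records must carry a positive lod",
                       call. = FALSE)
  } else {
    assert_number(value, "value", lower = 0)
  }
  structure(list(plant_id = as.character(plant_id),
                 site_id = as.character(site_id),
                 organ = organ, metal = metal,
                 value = if (censored) NA_real_ else value,
                 censored = censored, lod = lod),
            class = "tissue_concentration")
}

# Accept a tissue_concentration or a bare number; return list(value, censored)
#' @noRd
as_conc <- function(x, name) {
  if (inherits(x, "tissue_concentration"))
    return(list(value = x$value, censored = x$censored))
  assert_number(x, name, lower = 0)
  list(value = x, censored = FALSE)
}

#' Bioconcentration factor (root / soil)
#'
#' BCF = concentration in roots / total concentration in soil, both in
#' mg kg^-1 dry weight. Measures soil-to-root uptake. A censored root
#' concentration yields `NA` (not computable, reported "NC"); a
#' non-positive soil total is an error.
#'
#' @param root Root concentration: a [tissue_concentration()] or a
#'   non-negative number.
#' @param soil_total Total soil concentration, mg kg^-1 (> 0). By
#'   convention the pre-cultivation (initial) soil total.
#' @return The ratio at full precision (`NA` if not computable). Use
#'   [report_ratio()] for the 2-decimal report convention.
#' @examples
#' bcf(2.29, 22.13)   # 0.1035 -> reported 0.10
#' @export
bcf <- function(root, soil_total) {
  assert_number(soil_total, "soil_total")
  if (soil_total <= 0) stop("'soil_total' must be > 0", call. = FALSE)
  r <- as_conc(root, "root")
  if (r$censored) return(NA_real_)
  r$value / soil_total
}

#' Translocation factor (leaf / root)
#'
#' TF = concentration in leaves / concentration in roots; measures
#' root-to-shoot transfer efficiency. Strictly leaf over root; ratios for
#' other organs are available via [organ_ratio()] and are never silently
#' substituted. A censored or zero root, or a censored leaf, yields `NA`
#' (not computable).
#'
#' @param leaf,root Concentrations: [tissue_concentration()] objects or
#'   non-negative numbers.
#' @return The ratio at full precision (`NA` if not computable).
#' @examples
#' tf(0.11, 1.61)
#' @export
tf <- function(leaf, root) {
  l <- as_conc(leaf, "leaf")
  r <- as_conc(root, "root")
  if (r$censored || l$censored || r$value <= 0) return(NA_real_)
  l$value / r$value
}

#' Ratio of an arbitrary organ concentration to the root concentration
#'
#' Clearly-named extension of [tf()] for stem or fruit translocation.
#'
#' @param organ_conc,root As in [tf()].
#' @return Ratio or `NA` when not computable.
#' @export
organ_ratio <- function(organ_conc, root) tf(organ_conc, root)

#' Classify accumulator behaviour from uptake factors
#'
#' A species is a non-accumulator for a metal when every computed factor
#' (BCF, TF) is below 1; any computed factor at or above 1 marks a
#' potential accumulator. If neither factor is computable the record is
#' not classifiable.
#'
#' @param bcf,tf Numeric factors; `NA` means not computable.
#' @return `"non_accumulator"`, `"potential_accumulator"` or
#'   `"not_classifiable"`.
#' @examples
#' classify_accumulator(bcf = 0.10, tf = 0.04)
#' @export
classify_accumulator <- function(bcf, tf) {
  vals <- c(bcf, tf)
  computed <- vals[!is.na(vals)]
  if (!length(computed)) return("not_classifiable")
  if (any(computed < 0)) stop("uptake factors must be >= 0", call. = FALSE)
  if (all(computed < 1)) "non_accumulator" else "potential_accumulator"
}

#' Uptake factors for one site/metal
#'
#' Convenience wrapper computing BCF, TF and the accumulator class together.
#'
#' @inheritParams bcf
#' @inheritParams tf
#' @return A list of class `"uptake_factors"` with `bcf`, `tf`,
#'   `accumulator_class`.
#' @export
uptake_factors <- function(root, leaf, soil_total) {
  b <- bcf(root, soil_total)
  t_ <- tf(leaf, root)
  structure(list(bcf = b, tf = t_,
                 accumulator_class = classify_accumulator(b, t_)),
            class = "uptake_factors")
}

#' Report-convention rounding for BCF/TF ratios
#'
#' Uptake-factor tables print ratios at 2 decimals; `NA` renders as "NC".
#'
#' @param x Numeric vector of ratios.
#' @param digits Decimals (default 2).
#' @return Numeric vector rounded for report; internal values stay at full
#'   precision.
#' @export
report_ratio <- function(x, digits = 2) round(x, digits)

#' Lichtenthaler pigment quantification from extract absorbances
#'
#' Chlorophyll a, b, total (a+b) and carotenoid concentrations in an 80%
#' acetone leaf extract from absorbances at 663, 647 and 470 nm:
#' \deqn{Chl_a = 12.25 A_{663} - 2.79 A_{647}}
#' \deqn{Chl_b = 21.50 A_{647} - 5.10 A_{663}}
#' \deqn{Chl_{a+b} = 7.15 A_{663} + 18.71 A_{647}}
#' \deqn{Car = (1000 A_{470} - 1.82 Chl_a - 85.02 Chl_b) / 198}
#' The total-chlorophyll coefficients are algebraically the sum of the a and
#' b sets, so `chl_total == chl_a + chl_b` exactly. A negative pigment value
#' is physically impossible and marks the result invalid (bad extract or
#' transcription); values are returned unclamped for diagnosability.
#'
#' @param a663,a647,a470 Absorbances (>= 0).
#' @return An object of class `"pigment_result"`: `chl_a`, `chl_b`,
#'   `chl_total`, `carotenoids` (extract concentration units) and `valid`.
#' @examples
#' pigments(0.859, 0.367, 0.810)
#' @export
pigments <- function(a663, a647, a470) {
  assert_number(a663, "a663", lower = 0)
  assert_number(a647, "a647", lower = 0)
  assert_number(a470, "a470", lower = 0)
  chl_a <- 12.25 * a663 - 2.79 * a647
  chl_b <- 21.50 * a647 - 5.10 * a663
  chl_total <- 7.15 * a663 + 18.71 * a647
  car <- (1000 * a470 - 1.82 * chl_a - 85.02 * chl_b) / 198
  structure(list(chl_a = chl_a, chl_b = chl_b, chl_total = chl_total,
                 carotenoids = car,
                 valid = all(c(chl_a, chl_b, chl_total, car) >= 0)),
            class = "pigment_result")
}

#' @export
print.pigment_result <- function(x, ...) {
  cat(sprintf(
    "<pigment_result> chl_a %.3f, chl_b %.3f, total %.3f, car %.3f%s\n",
    x$chl_a, x$chl_b, x$chl_total, x$carotenoids,
    if (x$valid) "" else "  [INVALID: negative pigment]"))
  invisible(x)
}

#' Punch-method leaf area
#'
#' Scales total leaf dry weight by the area-to-weight ratio of punched
#' disks: `area = total_wt * (n_disks * disk_area) / disk_wt`. The default
#' disk area, 5.72 cm^2, is the rounded area of a 2.7 cm diameter punch.
#'
#' @param total_leaf_dry_wt Total leaf dry weight, g.
#' @param disk_dry_wt Combined dry weight of the punched disks, g (> 0).
#' @param n_disks Number of disks (>= 1).
#' @param disk_area_cm2 Area of one disk, cm^2.
#' @return Leaf area, cm^2.
#' @examples
#' leaf_area(6.3, 0.25, 10)
#' @export
leaf_area <- function(total_leaf_dry_wt, disk_dry_wt, n_disks,
                      disk_area_cm2 = 5.72) {
  assert_number(total_leaf_dry_wt, "total_leaf_dry_wt", lower = 0)
  assert_number(disk_dry_wt, "disk_dry_wt")
  if (disk_dry_wt <= 0) stop("'disk_dry_wt' must be > 0", call. = FALSE)
  if (!is.numeric(n_disks) || length(n_disks) != 1L || n_disks < 1 ||
      n_disks != as.integer(n_disks))
    stop("'n_disks' must be a whole number >= 1", call. = FALSE)
  assert_number(disk_area_cm2, "disk_area_cm2", lower = 0)
  total_leaf_dry_wt * (n_disks * disk_area_cm2) / disk_dry_wt
}

#' Uptake-factor table across sites and metals
#'
#' Builds the site-by-metal BCF/TF table from long-format tissue data and
#' soil totals (initial-soil denominators by default).
#'
#' @param tissues Data frame with columns `site_id`, `organ`, `metal`,
#'   `value`, `censored` (root and leaf rows are used). Replicate rows for
#'   the same site/organ/metal are averaged (censored replicates excluded;
#'   an all-censored group is NC).
#' @param soils Data frame with columns `site_id`, `timepoint`, `metal`,
#'   `concentration`.
#' @param soil_timepoint Which soil totals form the BCF denominator.
#' @return Long data frame: `site_id`, `metal`, `bcf`, `tf`,
#'   `accumulator_class`, plus report-rounded `bcf_report`, `tf_report`.
#' @export
bcf_tf_table <- function(tissues, soils, soil_timepoint = "initial") {
  assert_columns(tissues, c("site_id", "organ", "metal", "value", "censored"),
                 "'tissues'")
  assert_columns(soils, c("site_id", "timepoint", "metal", "concentration"),
                 "'soils'")
  soils <- soils[soils$timepoint == soil_timepoint, , drop = FALSE]

  mean_conc <- function(site, organ, metal) {
    rows <- tissues[tissues$site_id == site & tissues$organ == organ &
                      tissues$metal == metal, , drop = FALSE]
    if (!nrow(rows)) return(NULL)                  # organ not measured
    ok <- !rows$censored
    if (!any(ok)) return(list(value = NA_real_, censored = TRUE))
    list(value = mean(rows$value[ok]), censored = FALSE)
  }

  grid <- unique(tissues[, c("site_id", "metal")])
  grid <- grid[order(grid$site_id, match(grid$metal, .metals)), , drop = FALSE]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    site <- grid$site_id[i]; metal <- grid$metal[i]
    soil <- soils$concentration[soils$site_id == site & soils$metal == metal]
    root <- mean_conc(site, "root", metal)
    leaf <- mean_conc(site, "leaf", metal)
    b <- if (is.null(root) || !length(soil)) NA_real_
      else if (root$censored) NA_real_ else root$value / soil[1]
    t_ <- if (is.null(root) || is.null(leaf)) NA_real_
      else if (root$censored || leaf$censored || root$value <= 0) NA_real_
      else leaf$value / root$value
    data.frame(site_id = site, metal = metal, bcf = b, tf = t_,
               accumulator_class = classify_accumulator(b, t_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$bcf_report <- report_ratio(res$bcf)
  res$tf_report <- report_ratio(res$tf)
  rownames(res) <- NULL
  res
}
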