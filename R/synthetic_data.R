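# Synthetic-study generator: complete distance-gradient studies with known
# ground truth, in the CSV schemas consumed by the analysis modules, so the
# whole pipeline is testable with no external data and parameter recovery
# can be asserted.

#' Configuration for a synthetic distance-gradient study
#'
#' Defaults describe a screen-house study of a vegetable crop on
#' gold-mining-impacted soils: three sites at 0.6, 3 and 10 km from the
#' source, three replicate plants per site, four fruit harvests, metals Hg,
#' Pb and As. Default soil totals are a realistic mining gradient; true
#' uptake factors are of non-accumulator magnitude (all below 1). Noise is
#' multiplicative lognormal with unit mean at coefficient of variation
#' `noise_cv` (default 0.1, a representative analytical-plus-biological CV
#' for replicate trace-metal measurements).
#'
#' @param seed Integer RNG seed; a fixed seed makes the study byte-identical.
#' @param distances_km Site distances from the contamination source.
#' @param soil_totals Metals-by-sites matrix of total soil concentrations
#'   (mg kg^-1; rownames metals, one column per site), or `NULL` to use the
#'   exponential gradient `c0 * exp(-decay_per_km * distance)`.
#' @param c0,decay_per_km Named per-metal gradient parameters, used only
#'   when `soil_totals` is `NULL`.
#' @param n_replicates Plants per site.
#' @param n_harvests Fruit harvests.
#' @param true_bcf,true_tf Named per-metal true uptake factors.
#' @param stem_partition Stem concentration as a fraction of root.
#' @param fruit_partition Fruit concentration as a fraction of leaf.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param lod_plant,lod_soil Named per-metal detection limits, mg kg^-1.
#' @param fraction_alpha Named list: metal -> length-3 Dirichlet
#'   concentration parameters for (F1, F2, residual).
#' @param pigment_truth Named vector `chl_a`, `chl_b`, `carotenoids`:
#'   ground-truth extract pigment concentrations.
#' @param pigment_noise_cv Multiplicative noise on the inverted absorbances.
#' @param n_blanks Named vector: blanks per matrix (`soil`, `plant`).
#' @param exposure An [exposure_scenario()].
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed = 1L,
    distances_km = c(0.6, 3, 10),
    soil_totals = rbind(Hg = c(22.13, 5.38, 2.05),
                        Pb = c(1997.02, 186.03, 57.19),
                        As = c(37.52, 15.70, 7.90)),
    c0 = NULL, decay_per_km = NULL,
    n_replicates = 3L,
    n_harvests = 4L,
    true_bcf = c(Hg = 0.30, Pb = 0.15, As = 0.10),
    true_tf = c(Hg = 0.07, Pb = 0.04, As = 0.04),
    stem_partition = c(Hg = 0.5, Pb = 0.5, As = 0.5),
    fruit_partition = c(Hg = 0.6, Pb = 0.6, As = 0.6),
    noise_cv = 0.1,
    lod_plant = c(Hg = 1e-4, Pb = 0.08, As = 0.05),
    lod_soil = c(Hg = 0.001, Pb = 0.08, As = 0.05),
    fraction_alpha = list(Hg = c(0.3, 0.3, 99.4),
                          Pb = c(5.3, 1.9, 92.8),
                          As = c(0.3, 0.4, 99.3)),
    pigment_truth = c(chl_a = 9.5, chl_b = 3.5, carotenoids = 2.5),
    pigment_noise_cv = 0,
    n_blanks = c(soil = 7L, plant = 10L),
    exposure = exposure_scenario()) {

  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (any(distances_km < 0)) stop("'distances_km' must be >= 0")
  n_sites <- length(distances_km)
  if (is.null(soil_totals)) {
    if (is.null(c0) || is.null(decay_per_km))
      stop("give either 'soil_totals' or gradient parameters c0/decay_per_km",
           call. = FALSE)
    soil_totals <- t(vapply(
      .metals, function(m) c0[[m]] * exp(-decay_per_km[[m]] * distances_km),
      numeric(n_sites)))
    dimnames(soil_totals) <- list(.metals, NULL)
  }
  if (!is.matrix(soil_totals) || ncol(soil_totals) != n_sites ||
      is.null(rownames(soil_totals)))
    stop("'soil_totals' must be a metals-by-sites matrix with rownames",
         call. = FALSE)
  metals <- rownames(soil_totals)
  if (any(soil_totals < 0)) stop("soil totals must be >= 0")
  for (nm in c("true_bcf", "true_tf", "stem_partition", "fruit_partition",
               "lod_plant", "lod_soil")) {
    v <- get(nm)
    if (any(!metals %in% names(v)))
      stop(sprintf("'%s' must name every metal", nm), call. = FALSE)
    if (any(v[metals] < 0)) stop(sprintf("'%s' must be >= 0", nm))
  }
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(pigment_noise_cv, "pigment_noise_cv", lower = 0)
  if (any(!metals %in% names(fraction_alpha)) ||
      any(vapply(fraction_alpha[metals],
                 function(a) length(a) != 3L || any(a <= 0), logical(1))))
    stop("'fraction_alpha' needs 3 positive parameters per metal",
         call. = FALSE)
  if (any(pigment_truth < 0)) stop("'pigment_truth' must be >= 0")

  structure(list(
    seed = as.integer(seed), distances_km = distances_km,
    soil_totals = soil_totals, metals = metals,
    n_replicates = as.integer(n_replicates),
    n_harvests = as.integer(n_harvests),
    true_bcf = true_bcf[metals], true_tf = true_tf[metals],
    stem_partition = stem_partition[metals],
    fruit_partition = fruit_partition[metals],
    noise_cv = noise_cv, lod_plant = lod_plant[metals],
    lod_soil = lod_soil[metals], fraction_alpha = fraction_alpha[metals],
    pigment_truth = pigment_truth, pigment_noise_cv = pigment_noise_cv,
    n_blanks = n_blanks, exposure = exposure),
    class = "synthetic_config")
}

# Unit-mean multiplicative lognormal noise at coefficient of variation cv.
#' @noRd
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet draw via normalized gammas.
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Invert the Lichtenthaler equations to absorbances
#'
#' Solves the 2x2 linear system of the chlorophyll a/b equations for A663
#' and A647, then the carotenoid equation for A470. Errors when the pigment
#' triple has no non-negative absorbance solution (infeasible ground truth).
#'
#' @param chl_a,chl_b,carotenoids Target pigment concentrations (extract
#'   units).
#' @return Named vector `a663`, `a647`, `a470`.
#' @examples
#' invert_pigments(9.46, 16.40, 2.5)   # a663 = a647 = 1
#' @export
invert_pigments <- function(chl_a, chl_b, carotenoids) {
  A <- matrix(c(12.25, -2.79,
                -5.10, 21.50), nrow = 2, byrow = TRUE)
  ab <- solve(A, c(chl_a, chl_b))
  a470 <- (198 * carotenoids + 1.82 * chl_a + 85.02 * chl_b) / 1000
  out <- c(a663 = ab[1], a647 = ab[2], a470 = a470)
  if (any(out < -1e-12))
    stop("pigment truth has no non-negative absorbance solution",
         call. = FALSE)
  pmax(out, 0)
}

#' Generate a complete synthetic study
#'
#' Draws a full study under the configured ground truth: soil totals per
#' site (initial, and final reduced by plant uptake/losses), sequential
#' extraction fraction profiles (Dirichlet), tissue concentrations
#' (`root = BCF x soil x eps`, `leaf = TF x root x eps`, stem and fruit by
#' the stated partitions, eps multiplicative lognormal), four fruit
#' harvests, leaf-extract absorbances obtained by inverting the pigment
#' equations, method blanks consistent with the configured LODs, and CRM
#' checks. Values below the matrix LOD are emitted as censored records.
#' Output is byte-identical for a fixed config and seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `"synthetic_study"` with data frames `soils`,
#'   `fractions`, `tissues`, `fruits`, `absorbances`, `blanks`, `crm`, and
#'   a `truth` record sufficient to recompute every expectation.
#' @seealso [write_study()], [recover_parameters()]
#' @export
generate_study <- function(cfg) {
  if (!inherits(cfg, "synthetic_config"))
    stop("'cfg' must come from synthetic_config()", call. = FALSE)
  set.seed(cfg$seed)
  metals <- cfg$metals
  sites <- paste0("S", seq_along(cfg$distances_km))
  n_sites <- length(sites)

  # --- soils: initial totals from the gradient, final slightly depleted
  soils <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    do.call(rbind, lapply(metals, function(m) {
      c_init <- cfg$soil_totals[m, s]
      c_fin <- c_init * 0.9 * rlnorm_cv(1, cfg$noise_cv)
      data.frame(site_id = rep(sites[s], 2),
                 distance_km = rep(cfg$distances_km[s], 2),
                 timepoint = c("initial", "final"),
                 metal = rep(m, 2),
                 concentration = c(c_init, c_fin),
                 sd = c_init * cfg$noise_cv * c(1, 1),
                 stringsAsFactors = FALSE)
    }))
  }))

  # --- sequential-extraction fraction profiles
  fractions <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    do.call(rbind, lapply(metals, function(m) {
      p <- 100 * rdirichlet1(cfg$fraction_alpha[[m]])
      data.frame(site_id = rep(sites[s], 3),
                 metal = rep(m, 3),
                 schema = rep(if (m == "Hg") "bloom" else "tessier", 3),
                 fraction_id = c("F1", "F2", "residual"),
                 percent = p, stringsAsFactors = FALSE)
    }))
  }))

  # --- tissues: root/stem/leaf per plant, censored below the plant LOD
  censor_row <- function(plant, site, organ, m, v) {
    lod <- cfg$lod_plant[[m]]
    cens <- v < lod
    data.frame(plant_id = plant, site_id = site, organ = organ, metal = m,
               value = if (cens) NA_real_ else v, censored = cens,
               lod = lod, stringsAsFactors = FALSE)
  }
  tissues <- list(); leaf_true <- matrix(NA_real_, n_sites, length(metals),
                                         dimnames = list(sites, metals))
  for (s in seq_len(n_sites)) {
    for (m in metals) {
      leaf_true[s, m] <- cfg$true_tf[[m]] * cfg$true_bcf[[m]] *
        cfg$soil_totals[m, s]
    }
    for (r in seq_len(cfg$n_replicates)) {
      plant <- sprintf("%s-P%d", sites[s], r)
      for (m in metals) {
        root <- cfg$true_bcf[[m]] * cfg$soil_totals[m, s] *
          rlnorm_cv(1, cfg$noise_cv)
        leaf <- cfg$true_tf[[m]] * root * rlnorm_cv(1, cfg$noise_cv)
        stem <- cfg$stem_partition[[m]] * root * rlnorm_cv(1, cfg$noise_cv)
        tissues <- c(tissues, list(
          censor_row(plant, sites[s], "root", m, root),
          censor_row(plant, sites[s], "stem", m, stem),
          censor_row(plant, sites[s], "leaf", m, leaf)))
      }
    }
  }
  tissues <- do.call(rbind, tissues)

  # --- fruits: n_harvests per site, fruit = partition x expected leaf x eps
  fruits <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    do.call(rbind, lapply(seq_len(cfg$n_harvests), function(h) {
      do.call(rbind, lapply(metals, function(m) {
        v <- cfg$fruit_partition[[m]] * leaf_true[s, m] *
          rlnorm_cv(1, cfg$noise_cv)
        lod <- cfg$lod_plant[[m]]
        cens <- v < lod
        data.frame(site_id = sites[s], harvest_id = paste0("C", h),
                   metal = m, value = if (cens) NA_real_ else v,
                   censored = cens, lod = lod, stringsAsFactors = FALSE)
      }))
    }))
  }))

  # --- absorbances: invert the pigment equations, optional noise
  a_true <- invert_pigments(cfg$pigment_truth[["chl_a"]],
                            cfg$pigment_truth[["chl_b"]],
                            cfg$pigment_truth[["carotenoids"]])
  absorbances <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
      eps <- rlnorm_cv(3, cfg$pigment_noise_cv)
      data.frame(sample_id = sprintf("%s-P%d", sites[s], r),
                 a663 = a_true[["a663"]] * eps[1],
                 a647 = a_true[["a647"]] * eps[2],
                 a470 = a_true[["a470"]] * eps[3],
                 stringsAsFactors = FALSE)
    }))
  }))

  # --- method blanks consistent with the configured LODs (lod = 3 sd)
  blanks <- do.call(rbind, lapply(c("soil", "plant"), function(mat) {
    lods <- if (mat == "soil") cfg$lod_soil else cfg$lod_plant
    nb <- cfg$n_blanks[[mat]]
    do.call(rbind, lapply(metals, function(m) {
      s_blank <- lods[[m]] / 3
      data.frame(matrix_type = mat, analyte = m, replicate = seq_len(nb),
                 value = stats::rnorm(nb, mean = lods[[m]], sd = s_blank),
                 stringsAsFactors = FALSE)
    }))
  }))

  # --- CRM checks around unit recovery
  certified <- c(Hg = 0.20, Pb = 0.117, As = 0.63)[metals]
  crm <- data.frame(
    analyte = metals, certified = unname(certified),
    certified_u = unname(certified) * 0.1,
    measured = unname(certified) * rlnorm_cv(length(metals), 0.02),
    measured_sd = unname(certified) * 0.03, n_reps = 3L,
    stringsAsFactors = FALSE)

  truth <- list(config = cfg, leaf_true = leaf_true,
                absorbance_true = a_true)
  structure(list(soils = soils, fractions = fractions, tissues = tissues,
                 fruits = fruits, absorbances = absorbances, blanks = blanks,
                 crm = crm, truth = truth),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory of CSV files
#'
#' Emits the full CSV suite in the schemas consumed by the readers in
#' [read_study()], plus `truth.json` with the generating parameters, so the
#' file-based pipeline is exercised end-to-end.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study"))
    stop("'study' must be a synthetic_study", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("soils", "fractions", "tissues", "fruits", "absorbances",
               "blanks", "crm"))
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  truth$config$exposure <- unclass(truth$config$exposure)
  truth$config$soil_totals <- as.data.frame(truth$config$soil_totals)
  truth$leaf_true <- as.data.frame(truth$leaf_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Recover generating parameters from a synthetic study
#'
#' Runs the real analysis chain on the synthetic tables: per-metal BCF is
#' estimated from root and initial-soil concentrations via [bcf_tf_table()],
#' TF from leaf and root, and the estimates are compared with the
#' generator's ground truth.
#'
#' @param study A [generate_study()] result.
#' @return Data frame: `parameter` (`"bcf"`/`"tf"`), `metal`, `truth`,
#'   `estimate` (mean over sites and replicates), `se` (standard error of
#'   the mean), `n` (site-replicate ratios used), `error`.
#' @export
recover_parameters <- function(study) {
  if (!inherits(study, "synthetic_study"))
    stop("'study' must be a synthetic_study", call. = FALSE)
  cfg <- study$truth$config
  soils <- study$soils[study$soils$timepoint == "initial", ]
  tiss <- study$tissues

  per_plant <- function(organ_num, organ_den, den_soil = FALSE) {
    out <- list()
    for (i in seq_len(nrow(tiss))) {
      row <- tiss[i, ]
      if (row$organ != organ_num || row$censored) next
      if (den_soil) {
        den <- soils$concentration[soils$site_id == row$site_id &
                                     soils$metal == row$metal]
        if (!length(den) || den[1] <= 0) next
        out[[length(out) + 1L]] <-
          data.frame(metal = row$metal, ratio = row$value / den[1])
      } else {
        d <- tiss[tiss$plant_id == row$plant_id & tiss$metal == row$metal &
                    tiss$organ == organ_den, ]
        if (!nrow(d) || d$censored[1] || d$value[1] <= 0) next
        out[[length(out) + 1L]] <-
          data.frame(metal = row$metal, ratio = row$value / d$value[1])
      }
    }
    do.call(rbind, out)
  }
  bcf_r <- per_plant("root", den_soil = TRUE)
  tf_r <- per_plant("leaf", "root")

  summarize <- function(r, param, truth_vec) {
    do.call(rbind, lapply(cfg$metals, function(m) {
      x <- r$ratio[r$metal == m]
      est <- if (length(x)) mean(x) else NA_real_
      se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
      data.frame(parameter = param, metal = m, truth = truth_vec[[m]],
                 estimate = est, se = se, n = length(x),
                 error = est - truth_vec[[m]], stringsAsFactors = FALSE)
    }))
  }
  res <- rbind(summarize(bcf_r, "bcf", cfg$true_bcf),
               summarize(tf_r, "tf", cfg$true_tf))
  rownames(res) <- NULL
  res
}
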