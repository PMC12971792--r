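# Helper: a small single-metal configuration for focused checks.
one_metal_cfg <- function(metal = "Hg", soil = 5.38, bcf = 0.3, tf = 0.07,
                          fruit_part = 0.6, cv = 0, seed = 1, n_rep = 1,
                          n_harv = 4, lod = 1e-4) {
  m <- stats::setNames(1, metal)
  synthetic_config(
    seed = seed, distances_km = 1,
    soil_totals = matrix(soil, 1, 1, dimnames = list(metal, NULL)),
    n_replicates = n_rep, n_harvests = n_harv,
    true_bcf = m * bcf, true_tf = m * tf,
    stem_partition = m * 0.5, fruit_partition = m * fruit_part,
    noise_cv = cv,
    lod_plant = m * lod, lod_soil = m * lod,
    fraction_alpha = stats::setNames(list(c(1, 1, 98)), metal))
}

test_that("the noiseless generator is exact multiplication", {
  st <- generate_study(one_metal_cfg(soil = 5.38, bcf = 0.3, cv = 0))
  root <- st$tissues[st$tissues$organ == "root", ]
  expect_equal(root$value, 1.614)
  leaf <- st$tissues[st$tissues$organ == "leaf", ]
  expect_equal(leaf$value, 0.07 * 1.614)
  expect_equal(unique(st$fruits$value), 0.6 * 0.07 * 1.614)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 42, noise_cv = 0.2)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  s3 <- generate_study(synthetic_config(seed = 43, noise_cv = 0.2))
  expect_false(identical(s1$fruits$value, s3$fruits$value))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated tables pass the consuming schemas round-trip", {
  st <- generate_study(synthetic_config(seed = 7, noise_cv = 0.3))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  fruits <- read_fruits(file.path(dir, "fruits.csv"))
  expect_equal(fruits$value, st$fruits$value)
  expect_identical(fruits$censored, st$fruits$censored)
  expect_s3_class(read_soils(file.path(dir, "soils.csv")), "data.frame")
  expect_s3_class(read_fractions(file.path(dir, "fractions.csv")),
                  "data.frame")
  expect_s3_class(read_tissues(file.path(dir, "tissues.csv")), "data.frame")
  expect_s3_class(read_absorbances(file.path(dir, "absorbances.csv")),
                  "data.frame")
  # fraction rows per profile sum to 100
  fr <- st$fractions
  sums <- tapply(fr$percent, paste(fr$site_id, fr$metal), sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})

test_that("pigment inversion solves the absorbance system", {
  a <- invert_pigments(9.46, 16.40, 2.5)
  expect_equal(unname(a[c("a663", "a647")]), c(1, 1))
  # inversion then forward evaluation is the identity on pigments
  set.seed(17)
  for (i in 1:15) {
    truth <- c(stats::runif(1, 1, 15), stats::runif(1, 0.5, 6),
               stats::runif(1, 0.5, 5))
    ab <- invert_pigments(truth[1], truth[2], truth[3])
    p <- pigments(ab[["a663"]], ab[["a647"]], ab[["a470"]])
    expect_equal(c(p$chl_a, p$chl_b, p$carotenoids), truth)
  }
  # any non-negative pigment triple is feasible (inversion matrix has
  # non-negative adjugate entries); a negative target is not
  expect_error(invert_pigments(-5, 1, 1), "non-negative")
})

test_that("absorbances in a generated study reproduce the pigment truth", {
  st <- generate_study(synthetic_config(seed = 3))
  ab <- st$absorbances[1, ]
  p <- pigments(ab$a663, ab$a647, ab$a470)
  expect_equal(p$chl_a, 9.5)
  expect_equal(p$chl_b, 3.5)
  expect_equal(p$carotenoids, 2.5)
})

test_that("censoring frequency matches the lognormal exceedance probability", {
  # expected fruit value equals the LOD so censoring is near 50%
  cv <- 0.3
  cfg <- one_metal_cfg(metal = "Pb", soil = 0.08 / (0.15 * 0.04 * 0.6),
                       bcf = 0.15, tf = 0.04, fruit_part = 0.6,
                       cv = cv, seed = 8, n_harv = 800, lod = 0.08)
  st <- generate_study(cfg)
  sdlog <- sqrt(log(1 + cv^2))
  p_cens <- stats::pnorm((log(1) + sdlog^2 / 2) / sdlog)   # P(mu*eps < mu)
  obs <- mean(st$fruits$censored)
  expect_equal(obs, p_cens, tolerance = 4 * sqrt(p_cens * (1 - p_cens) / 800))
})

test_that("parameter recovery is exact without noise and unbiased with it", {
  noiseless <- recover_parameters(generate_study(synthetic_config(seed = 2,
                                                                  noise_cv = 0)))
  expect_equal(noiseless$error, rep(0, nrow(noiseless)), tolerance = 1e-12)

  # noise_cv 0.2, 50 replicates: mean estimates within 3 SE of truth
  st <- generate_study(synthetic_config(seed = 12, n_replicates = 50,
                                        noise_cv = 0.2))
  rec <- recover_parameters(st)
  expect_true(all(rec$n >= 50))
  expect_true(all(abs(rec$error) <= 3 * rec$se))
})

test_that("end-to-end synthetic THQ matches the closed-form value", {
  # fruit concentration pinned to 0.07 mg/kg by a noiseless generator
  cfg <- one_metal_cfg(metal = "Hg", soil = 1, bcf = 1, tf = 1,
                       fruit_part = 0.07, cv = 0)
  st <- generate_study(cfg)
  expect_equal(unique(st$fruits$value), 0.07)
  r <- risk_table(st$fruits)
  expect_equal(unique(signif(r$by_metal$thq, 3)), 0.119)
})

test_that("the gradient parameterization decays with distance", {
  cfg <- synthetic_config(
    seed = 1, soil_totals = NULL,
    c0 = c(Hg = 25, Pb = 2200, As = 40),
    decay_per_km = c(Hg = 0.25, Pb = 0.38, As = 0.17))
  expect_equal(unname(cfg$soil_totals["Hg", 1]), 25 * exp(-0.25 * 0.6))
  expect_true(all(apply(cfg$soil_totals, 1, diff) < 0))
})

test_that("infeasible configurations error early", {
  expect_error(synthetic_config(noise_cv = -1), "noise_cv")
  expect_error(synthetic_config(true_bcf = c(Hg = 0.3)), "true_bcf")
  expect_error(synthetic_config(
    pigment_truth = c(chl_a = -1, chl_b = 10, carotenoids = 1)),
    "pigment_truth")
})
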