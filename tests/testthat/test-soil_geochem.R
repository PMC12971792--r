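test_that("RAC is the exact sum of the bioavailable fractions, with bands", {
  # Pb under the Tessier scheme: S3-type fractions fall in the medium band
  r <- compute_rac(fraction_profile("Pb", "tessier", 10.99, 4.35))
  expect_identical(r$rac_pct, 10.99 + 4.35)
  expect_equal(r$rac_pct, 15.34)
  expect_identical(r$risk_band, "medium")

  r <- compute_rac(fraction_profile("Pb", "tessier", 5.34, 1.31))
  expect_equal(r$rac_pct, 6.65)
  expect_identical(r$risk_band, "low")

  r <- compute_rac(fraction_profile("Hg", "bloom", 0, 0))
  expect_identical(r$rac_pct, 0)
  expect_identical(r$risk_band, "no_risk")
})

test_that("RAC classification partitions [0, 100] monotonically", {
  expect_identical(classify_rac(0.5), "no_risk")
  expect_identical(classify_rac(15.34), "medium")
  expect_identical(classify_rac(1), "low")       # inclusive lower edge
  expect_identical(classify_rac(c(0, 10, 30, 50, 100)),
                   c("no_risk", "medium", "high", "very_high", "very_high"))
  # monotone non-decreasing over a fine grid; every value gets one band
  grid <- seq(0, 100, by = 0.25)
  bands <- classify_rac(grid)
  order_idx <- match(bands, rac_bands()$labels)
  expect_true(all(diff(order_idx) >= 0))
  expect_false(anyNA(bands))
  expect_error(classify_rac(-1), "0")
  expect_error(classify_rac(101), "100")
})

test_that("band edges are configurable", {
  strict <- rac_bands(breaks = c(1, 11, 31, 75))
  expect_identical(classify_rac(10.5, strict), "low")
  expect_identical(classify_rac(10.5), "medium")
})

test_that("fraction profiles validate ranges and scheme/metal coupling", {
  expect_error(fraction_profile("Pb", "tessier", -1, 4), "f1_pct")
  expect_error(fraction_profile("Pb", "tessier", 101, 4), "f1_pct")
  expect_error(fraction_profile("Pb", "tessier", 60, 50), "exceeds")
  expect_error(fraction_profile("Pb", "bloom", 5, 1), "bloom")
  expect_error(fraction_profile("Hg", "tessier", 5, 1), "tessier")
  # tolerance at the 100% boundary
  expect_s3_class(fraction_profile("Pb", "tessier", 60, 40), "fraction_profile")
})

test_that("soil screening uses a strict upper bound and flags missing data", {
  s1 <- soil_sample("S1", 0.6, "initial",
                    c(Hg = 22.13, Pb = 1997.02, As = 37.52))
  out <- screen_soil_limits(s1)
  expect_identical(out$status[out$metal == "Pb"], "exceeds")   # 1997 > 300
  expect_identical(out$status[out$metal == "Hg"], "exceeds")

  s2 <- soil_sample("S2", 3, "initial", c(As = 15.70))
  out2 <- screen_soil_limits(s2)
  expect_identical(out2$status[out2$metal == "As"], "within")  # 15.7 <= 18
  expect_identical(out2$status[out2$metal == "Pb"], "missing")

  # boundary: equality is compliant
  s_eq <- soil_sample("X", 1, "initial", c(As = 18))
  expect_identical(
    screen_soil_limits(s_eq)$status[out$metal == "As"], "within")
})

test_that("soil screening agrees with brute force on random limit tables", {
  set.seed(42)
  for (i in 1:25) {
    totals <- stats::setNames(round(stats::runif(3, 0, 50), 3),
                              c("Hg", "Pb", "As"))
    upper <- round(stats::runif(3, 0.1, 50), 3)
    lim <- soil_limit_table(c("Hg", "Pb", "As"), lower = NA, upper = upper,
                            authority = "sim")
    got <- screen_soil_limits(soil_sample("S", 1, "initial", totals), lim)
    want <- ifelse(totals[lim$metal] > upper, "exceeds", "within")
    expect_identical(got$status, unname(want))
  }
})

test_that("concentration change reports deltas and guards zero baselines", {
  init <- soil_sample("S1", 0.6, "initial", c(Pb = 1997.02, Hg = 22.13))
  fin <- soil_sample("S1", 0.6, "final", c(Pb = 1433, Hg = 22.13))
  ch <- concentration_change(init, fin)
  expect_equal(ch$change[ch$metal == "Pb"], 1433 - 1997.02)
  expect_equal(ch$change[ch$metal == "Pb"], -564.02)
  expect_equal(ch$change[ch$metal == "Hg"], 0)
  expect_equal(ch$pct_change[ch$metal == "Hg"], 0)

  z_init <- soil_sample("Z", 1, "initial", c(Hg = 0))
  z_fin <- soil_sample("Z", 1, "final", c(Hg = 0.5))
  chz <- concentration_change(z_init, z_fin)
  expect_true(is.na(chz$pct_change))
  expect_false(chz$pct_defined)

  expect_error(concentration_change(fin, init), "timepoints")
  expect_error(concentration_change(
    init, soil_sample("S9", 1, "final", c(Pb = 1))), "different sites")
})

test_that("soil sample validation catches impossible inputs", {
  expect_error(soil_sample("S", -1, "initial", c(Hg = 1)), "distance_km")
  expect_error(soil_sample("S", 1, "initial", c(Hg = -2)), ">= 0")
  expect_error(soil_sample("S", 1, "initial", c(Hg = 1), ph = 15), "ph")
})
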