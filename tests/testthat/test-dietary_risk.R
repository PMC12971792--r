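test_that("EDI follows FIR*C/BW on both unit scales", {
  expect_equal(edi_ug(0.090), 35.7e-3 * 0.090 / 70 * 1000)
  expect_equal(round(edi_ug(0.090), 3), 0.046)
  expect_equal(edi(0.07), 3.57e-5)
  expect_equal(edi(0), 0)
  expect_true(is.na(edi(0.05, censored = TRUE)))
  expect_error(edi(-1), ">= 0")
  expect_error(exposure_scenario(bw_kg = 0), "bw_kg")
})

test_that("CDI equals EDI under the default scenario and scales linearly", {
  e <- edi(c(0.07, 0.090, 0.100))
  expect_identical(cdi(e), e)          # 365 * 70 / 25550 == 1 exactly
  half <- exposure_scenario(ef_days_yr = 182.5)
  expect_equal(cdi(e, half), e / 2)
  expect_equal(cdi(4.59e-5), 4.59e-5)
})

test_that("THQ and HI reproduce the published harvest values", {
  expect_equal(signif(thq(cdi(edi(0.07)), 0.0003), 3), 0.119)
  expect_equal(signif(thq(cdi(edi(0.100)), 0.0003), 3), 0.17)
  expect_equal(thq(1, 1), 1)
  expect_error(thq(1, NA, metal = "Hg"), "Hg")

  h <- hi(c(Hg = 0.119, Pb = 0.0131))
  expect_equal(signif(h$hi, 3), 0.132)
  expect_identical(h$band, "negligible")
  expect_equal(hi(c(a = 0.3))$hi, 0.3)
  h2 <- hi(c(1.0, 0.5))
  expect_equal(h2$hi, 1.5)
  expect_identical(h2$band, "potential_adverse")
  expect_identical(hi(c(NA_real_, NA_real_))$band, "NC")
  # HI excludes NC metals rather than imputing zero
  expect_equal(hi(c(0.119, NA))$hi, 0.119)
})

test_that("HI is additive and monotone in each THQ", {
  set.seed(5)
  for (i in 1:20) {
    t1 <- stats::runif(3, 0, 2)
    expect_equal(hi(t1)$hi, sum(t1))
    bump <- t1 + c(stats::runif(1, 0, 1), 0, 0)
    expect_gte(hi(bump)$hi, hi(t1)$hi)
  }
})

test_that("ILCR unit modes differ by exactly 1000x and classify correctly", {
  c_pb <- cdi(edi(0.090))
  expect_equal(ilcr(c_pb, 0.0085), 3.9015e-4, tolerance = 1e-10)
  expect_identical(classify_ilcr(ilcr(c_pb, 0.0085)), "potential_concern")
  expect_equal(ilcr(c_pb, 0.0085, "strict_mg"), 3.9015e-7, tolerance = 1e-13)
  set.seed(3)
  for (i in 1:20) {
    cc <- stats::runif(1, 0, 1e-3)
    expect_equal(ilcr(cc, 1.5, "strict_mg"), ilcr(cc, 1.5) / 1000)
  }
  expect_identical(classify_ilcr(c(0, 5e-7, 5e-5, 5e-4, 5e-3, NA)),
                   c("negligible", "negligible", "acceptable",
                     "potential_concern", "moderate_risk", "NC"))
  expect_warning(no_csf <- ilcr(c_pb, NA_real_), "slope factor")
  expect_true(is.na(no_csf))
})

test_that("MOE reproduces the adult and child lead margins", {
  e <- edi_ug(0.090)
  m <- moe(c(adults_sbp = 1.50, children_iq = 0.5), e)
  expect_identical(m$moe_rounded, c(33, 11))
  expect_identical(m$concern, c(FALSE, FALSE))
  expect_identical(m$near_threshold, c(FALSE, TRUE))

  m1 <- moe(c(x = 2), 2)
  expect_equal(m1$moe, 1)
  expect_true(m1$concern)

  m0 <- moe(c(x = 2), 0)
  expect_identical(m0$moe, Inf)
  expect_false(m0$concern)
})

test_that("MOE * EDI recovers the BMDL before rounding", {
  set.seed(9)
  for (i in 1:20) {
    b <- stats::runif(2, 0.1, 5)
    e <- stats::runif(1, 1e-4, 2)
    expect_equal(moe(b, e)$moe * e, unname(b))
  }
})

test_that("weekly intake scales EDI by 7 and compares with the PTWI", {
  w <- weekly_intake(0.037, ptwi = 4)
  expect_equal(w$weekly, 0.259)
  expect_equal(round(w$weekly, 2), 0.26)
  expect_equal(w$ptwi_fraction, 0.259 / 4)
  expect_equal(weekly_intake(0.00006)$weekly, 0.00042)
  expect_equal(weekly_intake(0)$weekly, 0)
  expect_true(is.na(weekly_intake(1)$ptwi_fraction))
})

test_that("MAC screening uses strict exceedance and handles censoring", {
  refs <- default_reference_values()
  hg <- screen_mac(0.05, refs$mac$Hg)
  expect_identical(hg$status, "exceeds")
  pb <- screen_mac(0.090, refs$mac$Pb)
  expect_identical(pb$status[pb$authority == "GB 2762-2022"], "compliant")
  expect_identical(pb$status[pb$authority == "Codex CXS 193-1995"], "exceeds")
  expect_identical(screen_mac(0.1, c(GB = 0.1))$status, "compliant")  # equal
  expect_identical(screen_mac(NA, c(GB = 0.1), censored = TRUE)$status,
                   "censored_compliant")
  expect_identical(screen_mac(0.1, numeric())$status, "NC")
})

test_that("EDI, THQ and ILCR are linear in the fruit concentration", {
  set.seed(13)
  for (i in 1:10) {
    c0 <- stats::runif(1, 0.001, 1)
    k <- stats::runif(1, 0.1, 5)
    expect_equal(edi(k * c0), k * edi(c0))
    expect_equal(thq(cdi(edi(k * c0)), 3e-4), k * thq(cdi(edi(c0)), 3e-4))
    expect_equal(ilcr(cdi(edi(k * c0)), 0.0085),
                 k * ilcr(cdi(edi(c0)), 0.0085))
  }
})

test_that("risk_table propagates censoring and supports LOD/2 sensitivity", {
  fr <- data.frame(site_id = "S2", harvest_id = c("C1", "C1", "C2"),
                   metal = c("Hg", "Pb", "Pb"),
                   value = c(0.07, 0.090, NA),
                   censored = c(FALSE, FALSE, TRUE), lod = c(1e-4, 0.08, 0.08))
  r <- risk_table(fr)
  bm <- r$by_metal
  expect_true(is.na(bm$thq[bm$harvest_id == "C2"]))
  expect_identical(bm$ilcr_band[bm$harvest_id == "C2"], "NC")
  expect_equal(r$by_harvest$hi[r$by_harvest$harvest_id == "C1"],
               thq(cdi(edi(0.07)), 3e-4) + thq(cdi(edi(0.090)), 3.5e-3))

  r2 <- risk_table(fr, censored_policy = "half_lod")
  expect_equal(r2$by_metal$thq[3], thq(cdi(edi(0.04)), 3.5e-3))

  expect_warning(risk_table(fr[0, ]), "empty")
})
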