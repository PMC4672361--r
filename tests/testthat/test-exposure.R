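test_that("chronic daily intakes match an independent single-expression oracle", {
  p <- exposure_parameters(cw_ng_l = 10)
  # independently coded evaluations of the dose equations (Cw in mg/L)
  oracle_i <- (10 * 1e-6) * 2.39 * 350 * 70 / (62.1 * 25550)
  oracle_d <- (10 * 1e-6) * 16000 * 1.2 * 0.15 * 350 * 70 * 0.001 /
    (62.1 * 25550)
  expect_equal(cdi_ingestion(p), oracle_i, tolerance = 1e-14)
  expect_equal(cdi_dermal(p), oracle_d, tolerance = 1e-14)
  # frozen magnitudes from hand arithmetic on the point values
  expect_equal(cdi_ingestion(p), 3.6905e-7, tolerance = 1e-4)
  expect_equal(cdi_dermal(p), 4.4471e-7, tolerance = 1e-4)
})

test_that("doses are linear in their numerators and inverse in BW/AT", {
  p <- exposure_parameters(cw_ng_l = 7)
  p2 <- exposure_parameters(cw_ng_l = 7, ir = 2 * 2.39)
  expect_equal(cdi_ingestion(p2), 2 * cdi_ingestion(p))
  p3 <- exposure_parameters(cw_ng_l = 7, sa = 8000)
  expect_equal(cdi_dermal(p3), cdi_dermal(p) / 2)
  p4 <- exposure_parameters(cw_ng_l = 0)
  expect_equal(cdi_ingestion(p4), 0)
  expect_equal(cdi_dermal(p4), 0)
  p5 <- exposure_parameters(cw_ng_l = 7, bw = 2 * 62.1)
  expect_equal(cdi_ingestion(p5), cdi_ingestion(p) / 2)
})

test_that("dermal slope factor is the AAF-adjusted oral factor", {
  expect_equal(dermal_sf(7.3, 0.92), 7.3 / 0.92, tolerance = 1e-15)
  expect_equal(dermal_sf(7.3, 0.92, presented = TRUE), 7.9)
  expect_equal(dermal_sf(5, 1), 5)          # AAF = 1 leaves SF unchanged
  expect_equal(dermal_sf(1, 0.5), 2)
  expect_error(dermal_sf(7.3, 0), "aaf")
  expect_error(dermal_sf(7.3, 1.2), "aaf")
})

test_that("cancer risk is the dose-slope product with guarded inputs", {
  expect_equal(carcinogenic_risk(3.6905e-7, 7.3), 2.694065e-6,
               tolerance = 1e-6)
  expect_equal(carcinogenic_risk(4.4471e-7, 7.3 / 0.92), 3.529128e-6,
               tolerance = 1e-5)
  expect_equal(carcinogenic_risk(0, 7.3), 0)
  expect_error(carcinogenic_risk(-1e-9, 7.3), "cdi")
  expect_error(carcinogenic_risk(1e-9, 0), "sf")
})

test_that("total risk composes the routes and sums exactly", {
  rr <- total_risk(exposure_parameters(cw_ng_l = 10))
  expect_equal(rr$cr_total, 6.22e-6, tolerance = 1e-3)
  expect_identical(rr$cr_total, rr$cr_ingestion + rr$cr_dermal)
  expect_equal(as.character(rr$category), "acceptable")
  rr0 <- total_risk(exposure_parameters(cw_ng_l = 0))
  expect_equal(rr0$cr_total, 0)
  expect_equal(as.character(rr0$category), "below_de_minimis")
})

test_that("total risk is scale-equivariant in Cw", {
  base <- total_risk(exposure_parameters(cw_ng_l = 3.7))
  for (k in c(0.5, 2, 10)) {
    scaled <- total_risk(exposure_parameters(cw_ng_l = 3.7 * k))
    expect_equal(scaled$cr_total, k * base$cr_total, tolerance = 1e-12)
    expect_equal(scaled$cr_ingestion, k * base$cr_ingestion,
                 tolerance = 1e-12)
    expect_equal(scaled$cr_dermal, k * base$cr_dermal, tolerance = 1e-12)
  }
})

test_that("every operation matches an inline oracle on random parameter sets", {
  set.seed(401)
  for (i in 1:1000) {
    cw <- runif(1, 0, 200); ir <- runif(1, 0.5, 5); ef <- runif(1, 100, 365)
    ed <- runif(1, 1, 70); bw <- runif(1, 40, 100)
    at <- runif(1, 10000, 30000); sa <- runif(1, 5000, 20000)
    kp <- runif(1, 0.1, 3); et <- runif(1, 0.05, 1)
    sf <- runif(1, 1, 10); aaf <- runif(1, 0.5, 1)
    p <- exposure_parameters(cw, ir, ef, ed, bw, at, sa, kp, et, sf, aaf)
    cwm <- cw * 1e-6
    expect_equal(cdi_ingestion(p), cwm * ir * ef * ed / (bw * at),
                 tolerance = 1e-12)
    expect_equal(cdi_dermal(p),
                 cwm * sa * kp * et * ef * ed * 0.001 / (bw * at),
                 tolerance = 1e-12)
    rr <- total_risk(p)
    expect_equal(rr$cr_total,
                 cwm * ir * ef * ed / (bw * at) * sf +
                   cwm * sa * kp * et * ef * ed * 0.001 / (bw * at) *
                   (sf / aaf),
                 tolerance = 1e-12)
  }
})

test_that("risk classification uses strict thresholds", {
  expect_equal(as.character(classify_risk(5e-7)), "below_de_minimis")
  expect_equal(as.character(classify_risk(5e-5)), "acceptable")
  expect_equal(as.character(classify_risk(2e-4)), "above_limit")
  # equality falls in the lower category
  expect_equal(as.character(classify_risk(1e-6)), "below_de_minimis")
  expect_equal(as.character(classify_risk(1e-4)), "acceptable")
})

test_that("invalid exposure parameters are rejected by name", {
  expect_error(exposure_parameters(cw_ng_l = -1), "cw_ng_l")
  expect_error(exposure_parameters(bw = 0), "bw")
  expect_error(exposure_parameters(ef = 400), "ef")
  expect_error(exposure_parameters(aaf = 1.5), "aaf")
  expect_error(exposure_parameters(cf = 0.01), "cf")
})
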