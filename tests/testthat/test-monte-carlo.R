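test_that("distribution specs validate their parameters", {
  expect_error(dist_spec("xx", "point", value = 1), "unknown")
  expect_error(dist_spec("ed", "uniform", min = 5, max = 5), "min < max")
  expect_error(dist_spec("bw", "lognormal", mean = -1, cv = 0.2), "lognormal")
  sp <- dist_spec("bw", "lognormal", mean = 62.1, cv = 0.2)
  # moment-matched conversion: back-transformed mean equals the input mean
  expect_equal(exp(sp$params$meanlog + sp$params$sdlog^2 / 2), 62.1)
})

test_that("parameter sampling is reproducible and family-correct", {
  specs <- list(dist_spec("ed", "uniform", min = 0, max = 70),
                dist_spec("bw", "point", value = 62.1),
                dist_spec("cw_ng_l", "lognormal", meanlog = log(10),
                          sdlog = 0.5))
  d1 <- sample_parameters(specs, n = 10000, seed = 31)
  d2 <- sample_parameters(specs, n = 10000, seed = 31)
  expect_identical(d1, d2)
  expect_true(all(d1$bw == 62.1))
  expect_true(all(d1$ed >= 0 & d1$ed <= 70))
  expect_true(all(d1$cw_ng_l > 0))
  # uniform mean within 3 SE of 35
  se <- 70 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(d1$ed) - 35), 3 * se)
})

test_that("point-collapsed simulation reproduces the deterministic result", {
  specs <- list(dist_spec("cw_ng_l", "point", value = 10),
                dist_spec("bw", "point", value = 62.1),
                dist_spec("ed", "point", value = 70))
  mc <- simulate_risk(specs, n = 500, seed = 1)
  det <- total_risk(exposure_parameters(cw_ng_l = 10))$cr_total
  expect_lt(abs(mc$mean - det) / det, 1e-12)
  expect_identical(mc$se, 0)
  expect_equal(mc$p5, det); expect_equal(mc$p50, det); expect_equal(mc$p95, det)
  expect_true(all(is.na(mc$sensitivity)))
})

test_that("with only Cw varied the mean matches the closed-form expectation", {
  # linearity: E[risk] = risk(E[Cw]); lognormal mean = exp(mu + s^2/2)
  mu <- log(10); s <- 0.6
  specs <- list(dist_spec("cw_ng_l", "lognormal", meanlog = mu, sdlog = s))
  mc <- simulate_risk(specs, n = 20000, seed = 77)
  det_at_mean <- total_risk(
    exposure_parameters(cw_ng_l = exp(mu + s^2 / 2)))$cr_total
  expect_lt(abs(mc$mean - det_at_mean) / det_at_mean, 3 * mc$se / mc$mean)
})

test_that("single-draw simulation degenerates to that draw", {
  specs <- list(dist_spec("cw_ng_l", "lognormal", meanlog = log(10),
                          sdlog = 0.5))
  mc <- simulate_risk(specs, n = 1, seed = 3)
  expect_equal(mc$mean, mc$risks$cr_total[1])
  expect_equal(mc$p50, mc$risks$cr_total[1])
  expect_identical(mc$se, 0)
})

test_that("monotone single inputs give rank correlations of +/-1", {
  mc_cw <- simulate_risk(list(dist_spec("cw_ng_l", "lognormal",
                                        meanlog = log(10), sdlog = 0.5)),
                         n = 200, seed = 5)
  expect_equal(unname(mc_cw$sensitivity[["cw_ng_l"]]), 1)
  mc_bw <- simulate_risk(list(dist_spec("bw", "lognormal", mean = 62.1,
                                        cv = 0.2)),
                         n = 200, seed = 5)
  expect_equal(unname(mc_bw$sensitivity[["bw"]]), -1)
})

test_that("a parameter absent from the risk formula has near-zero correlation", {
  # draws of an extra column uncorrelated with risk by construction
  set.seed(11)
  draws <- tibble::tibble(cw_ng_l = rlnorm(5000, log(10), 0.7),
                          sa = rlnorm(5000, log(16000), 0.2))
  # risk ignores the sa column entirely here
  risks <- total_risk(exposure_parameters(cw_ng_l = draws$cw_ng_l))$cr_total
  rho <- sensitivity(draws, risks)
  expect_lt(abs(rho[["sa"]]), 3 / sqrt(5000))
  expect_error(sensitivity(tibble::tibble(bw = rep(1, 10)), rep(1e-6, 10)),
               "constant")
})

test_that("SE of the Monte Carlo mean shrinks as 1/sqrt(n)", {
  specs <- list(dist_spec("cw_ng_l", "lognormal", meanlog = log(10),
                          sdlog = log(2)),
                dist_spec("ed", "uniform", min = 0, max = 70))
  ses <- vapply(c(100, 1000, 10000), function(n) {
    simulate_risk(specs, n = n, seed = 19)$se
  }, numeric(1))
  expect_lt(ses[2] / ses[1], 1 / sqrt(10) * 1.5)
  expect_gt(ses[2] / ses[1], 1 / sqrt(10) / 1.5)
  expect_lt(ses[3] / ses[2], 1 / sqrt(10) * 1.5)
  expect_gt(ses[3] / ses[2], 1 / sqrt(10) / 1.5)
})

test_that("probabilistic mean exceeds the median-parameter deterministic risk", {
  # Jensen-type direction: E[Cw] > median(Cw) for lognormal Cw, risk linear
  specs <- list(dist_spec("cw_ng_l", "lognormal", meanlog = log(10),
                          sdlog = log(2)),
                dist_spec("ed", "uniform", min = 0, max = 70))
  det_median <- total_risk(exposure_parameters(cw_ng_l = 10, ed = 35))$cr_total
  mc <- simulate_risk(specs, n = 10000, seed = 23)
  expect_gt(mc$mean, det_median)
})

test_that("distribution fitting selects and recovers a lognormal truth", {
  set.seed(41)
  x <- rlnorm(10000, log(10), log(2))
  fit <- fit_cw_distribution(x)
  expect_equal(fit$family, "lognormal")
  expect_lt(abs(attr(fit, "gm") - 10) / 10, 0.05)
  # single-candidate fit returns that family regardless of AIC comparison
  fit1 <- fit_cw_distribution(x, candidates = "lognormal")
  expect_equal(fit1$family, "lognormal")
  expect_error(fit_cw_distribution(rep(5, 50)), "constant")
  expect_error(fit_cw_distribution(c(1, 2, 3)), "at least 10")
})

test_that("summary percentiles follow the linear-interpolation convention", {
  risks <- tibble::tibble(cr_total = (1:100) * 1e-6)
  mc <- structure(list(n = 100, draws = tibble::tibble(), risks = risks,
                       sensitivity = c(cw_ng_l = NA_real_)),
                  class = "mc_result")
  mc <- summarize_mc(mc)
  expect_equal(mc$p50, 50.5e-6)
  expect_equal(mc$p5, unname(quantile((1:100) * 1e-6, 0.05)))
  expect_equal(mc$se, sd(risks$cr_total) / 10)
  # pooled mean is preserved when concatenating draw sets
  a <- (1:10) * 1e-6; b <- (5:24) * 1e-6
  mc2 <- summarize_mc(structure(
    list(n = 30, draws = tibble::tibble(),
         risks = tibble::tibble(cr_total = c(a, b)),
         sensitivity = c(cw_ng_l = NA_real_)), class = "mc_result"))
  expect_equal(mc2$mean, (sum(a) + sum(b)) / 30)
})
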