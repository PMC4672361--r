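test_that("geometric mean and CI behave on exact and simulated cases", {
  expect_equal(geometric_mean_ci(c(10, 1000))$gm, 100)
  g <- geometric_mean_ci(rep(7, 5))
  expect_equal(g$gm, 7); expect_equal(g$ci_low, 7); expect_equal(g$ci_high, 7)
  expect_error(geometric_mean_ci(c(1, -2)), "positive")
  set.seed(101)
  x <- rlnorm(10000, log(10), 0.8)
  g2 <- geometric_mean_ci(x)
  expect_lt(abs(g2$gm - 10) / 10, 0.02)
  expect_true(g2$ci_low <= 10 && 10 <= g2$ci_high)
  # AM-GM on a synthetic campaign's BaPeq values
  camp <- make_campaign(seed = 2)
  v <- bapeq_concentration(camp$samples, nd_policy = "half_dl")
  expect_lte(geometric_mean_ci(v)$gm, mean(v))
})

test_that("Box-Cox grid search finds the canonical optima", {
  set.seed(55)
  lognorm <- rlnorm(5000, 2, 0.6)
  expect_lt(abs(boxcox_lambda(lognorm)$lambda), 0.15)
  set.seed(56)
  normal <- rnorm(5000, 100, 5)  # mean >> sd, already normal
  expect_lt(abs(boxcox_lambda(normal)$lambda - 1), 0.25)
  # lambda = 0 branch is the natural log exactly
  bc <- boxcox_lambda(lognorm, grid = 0)
  expect_identical(bc$transformed, log(lognorm))
  expect_error(boxcox_lambda(c(-1, rep(1, 20))), "positive")
})

test_that("Box-Cox grid profile agrees with the MASS oracle", {
  set.seed(57)
  x <- rgamma(500, shape = 3, rate = 0.5)
  ours <- boxcox_lambda(x)$lambda
  mb <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  oracle <- mb$x[which.max(mb$y)]
  expect_lt(abs(ours - oracle), 0.05)
})

test_that("normality tests hold their level and reject exponential data", {
  ok <- vapply(1:20, function(s) {
    set.seed(500 + s)
    p <- normality_tests(rnorm(1000))
    p$anderson_darling_p > 0.05 && p$kolmogorov_smirnov_p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  rej <- vapply(1:20, function(s) {
    set.seed(600 + s)
    p <- normality_tests(rexp(1000))
    p$anderson_darling_p < 0.05 && p$kolmogorov_smirnov_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  expect_warning(p0 <- normality_tests(rep(1, 20)), "constant")
  expect_true(is.na(p0$anderson_darling_p))
})

test_that("group comparisons pick the right test and detect real shifts", {
  same <- compare_groups(c(1:10, 1:10), rep(c("a", "b"), each = 10))
  expect_equal(same$method, "wilcoxon")
  expect_gt(same$p_value, 0.9)
  set.seed(70)
  shifted <- compare_groups(c(rnorm(20), rnorm(20, 10)),
                            rep(c("a", "b"), each = 20))
  expect_lt(shifted$p_value, 0.01)
  expect_equal(shifted$signif, "**")
  expect_error(compare_groups(rnorm(30), rep(c("a", "b", "c"), 10),
                              method = "wilcoxon"), "2 groups")
  kw <- compare_groups(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_equal(kw$method, "kruskal_wallis")
})

test_that("rank tests hold their type-I error over permuted copies", {
  set.seed(71)
  base <- rlnorm(30)
  hits <- vapply(1:50, function(i) {
    vals <- c(sample(base), sample(base), sample(base))
    compare_groups(vals, rep(c("a", "b", "c"), each = 30))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.06 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("p-values are invariant under group relabeling", {
  set.seed(72)
  vals <- rnorm(40); grp <- rep(c("a", "b"), each = 20)
  relab <- ifelse(grp == "a", "b", "a")
  expect_equal(compare_groups(vals, grp)$p_value,
               compare_groups(vals, relab)$p_value)
})

test_that("exceedance fractions reproduce the fixed reporting vectors", {
  expect_equal(exceedance_percent(60, 232), 25.9)
  expect_equal(exceedance_percent(98, 232), 42.2)
  expect_equal(exceedance_percent(63, 232), 27.2)
  expect_equal(exceedance_percent(0, 100), 0)
  # cross-module consistency: rate equals the mean of the flag column
  camp <- make_campaign(seed = 13)
  er <- exceedance_rates(camp$samples)
  fl <- screen_samples(camp$samples)
  expect_equal(er$n_exceed[er$limit == "bap"], sum(fl$exceeds_bap))
  expect_equal(er$percent[er$limit == "bap"],
               round(100 * mean(fl$exceeds_bap), 1))
})

test_that("incidence-mortality correlation handles exact and null cases", {
  v <- tibble::tibble(incidence = c(100, 200, 300, 400),
                      mortality = 0.8 * c(100, 200, 300, 400))
  expect_equal(incidence_mortality_correlation(v)$r, 1)
  set.seed(90)
  indep <- tibble::tibble(incidence = rlnorm(1000, 5, 0.3),
                          mortality = rlnorm(1000, 5, 0.3))
  expect_lt(abs(incidence_mortality_correlation(indep)$r), 0.1)
  expect_error(incidence_mortality_correlation(
    tibble::tibble(incidence = rep(1, 5), mortality = 1:5)), "variance")
})

test_that("summary tables have the campaign-report layout", {
  camp <- make_campaign(seed = 1)
  tab <- summary_table(camp$samples, "season", "water_type")
  # 15 detected analytes + total, carcinogenic and BaPeq aggregate rows
  expect_equal(nrow(tab), 18)
  expect_equal(tail(tab$analyte, 3), c("sum_pahs", "sum_pahs_c", "bapeq"))
  expect_false("DahA" %in% tab$analyte)  # never detected, omitted
  expect_true(all(c("winter_SW", "winter_SG", "winter_DG",
                    "summer_SW", "summer_SG", "summer_DG",
                    "p_winter", "p_summer",
                    "p_SW", "p_SG", "p_DG", "p_all") %in% names(tab)))
  expect_true(all(tab$p_all >= 0 & tab$p_all <= 1))
  gtab <- summary_table(camp$samples, "group", "water_type")
  expect_equal(nrow(gtab), 18)
  expect_true(all(c("risk_SW", "control_SW", "p_risk", "p_control",
                    "p_all") %in% names(gtab)))
})

test_that("summer concentrations dominate winter in the generated campaign", {
  camp <- make_campaign(seed = 21)
  vals <- total_pahs(camp$samples, nd_policy = "half_dl")
  cmp <- compare_groups(vals, camp$samples$season)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(geometric_mean_ci(vals[camp$samples$season == "summer"])$gm,
            geometric_mean_ci(vals[camp$samples$season == "winter"])$gm)
})
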