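#' Geometric mean with a 95% confidence interval
#'
#' `GM = exp(mean(log x))`; the CI is the exponentiated t-interval on the log
#' scale, the standard summary for lognormal environmental concentrations.
#'
#' @param values Positive numeric vector.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `gm`, `ci_low`, `ci_high` (ng/L scale of the input)
#'   and `n`.
#' @export
#' @examples
#' geometric_mean_ci(c(10, 1000))  # GM 100
geometric_mean_ci <- function(values, level = 0.95) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0)) {
    stop("geometric mean requires positive, finite values ",
         "(resolve non-detects first)", call. = FALSE)
  }
  lg <- log(values)
  n <- length(lg)
  gm <- exp(mean(lg))
  if (n >= 2 && stats::sd(lg) > 0) {
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
      stats::sd(lg) / sqrt(n)
  } else {
    half <- 0
  }
  tibble::tibble(gm = gm, ci_low = exp(mean(lg) - half),
                 ci_high = exp(mean(lg) + half), n = n)
}

#' Box-Cox transformation with grid-search lambda
#'
#' Profiles the Box-Cox log-likelihood over a fixed lambda grid
#' (-3 to 3 in steps of 0.01) and returns the maximizing lambda together
#' with the transformed values `(x^lambda - 1)/lambda` (natural log at
#' lambda = 0).
#'
#' @param values Positive numeric vector, n >= 10.
#' @param grid Lambda grid (default `seq(-3, 3, by = 0.01)`).
#' @return List with `lambda`, `transformed`, and the profiled `loglik`
#'   tibble (`lambda`, `loglik`).
#' @export
#' @examples
#' boxcox_lambda(rlnorm(200))$lambda  # near 0 for lognormal data
boxcox_lambda <- function(values, grid = seq(-3, 3, by = 0.01)) {
  values <- as.numeric(values)
  if (length(values) < 10) stop("need n >= 10 for Box-Cox", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  }
  n <- length(values)
  lg <- log(values)
  slg <- sum(lg)
  ll <- vapply(grid, function(lam) {
    y <- if (abs(lam) < 1e-12) lg else (values^lam - 1) / lam
    v <- stats::var(y) * (n - 1) / n
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slg
  }, numeric(1))
  lam <- grid[which.max(ll)]
  transformed <- if (abs(lam) < 1e-12) lg else (values^lam - 1) / lam
  list(lambda = lam, transformed = transformed,
       loglik = tibble::tibble(lambda = grid, loglik = ll))
}

#' Normality tests against the fitted normal family
#'
#' Anderson-Darling and Lilliefors-corrected Kolmogorov-Smirnov tests with
#' estimated mean and SD (via \pkg{nortest}).
#'
#' @param values Numeric vector, n >= 8.
#' @return Tibble with `anderson_darling_p` and `kolmogorov_smirnov_p`
#'   (`NA` with a warning for degenerate input).
#' @export
normality_tests <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8) stop("need n >= 8 for normality tests",
                               call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("constant input: normality tests undefined, returning NA")
    return(tibble::tibble(anderson_darling_p = NA_real_,
                          kolmogorov_smirnov_p = NA_real_))
  }
  tibble::tibble(
    anderson_darling_p = nortest::ad.test(values)$p.value,
    kolmogorov_smirnov_p = nortest::lillie.test(values)$p.value
  )
}

#' Compare concentration groups
#'
#' Two-group comparisons use the Wilcoxon rank-sum test, three-or-more-group
#' comparisons the Kruskal-Wallis test (`method = "auto"` picks by arity);
#' `method = "anova"` runs a one-way ANOVA instead (conventionally on
#' Box-Cox-transformed concentrations). Significance markers `*` (P < 0.05)
#' and `**` (P < 0.01) are attached for table rendering.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor), same length.
#' @param method `"auto"`, `"wilcoxon"`, `"kruskal_wallis"` or `"anova"`.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `signif`,
#'   `n_groups`, `group_ns` (comma-separated counts).
#' @export
#' @examples
#' compare_groups(c(1:10, 11:20), rep(c("a", "b"), each = 10))
compare_groups <- function(values, groups,
                           method = c("auto", "wilcoxon", "kruskal_wallis",
                                      "anova")) {
  method <- match.arg(method)
  groups <- factor(groups)
  groups <- droplevels(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  ns <- table(groups)
  if (k < 2 || any(ns < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (method == "auto") method <- if (k == 2) "wilcoxon" else "kruskal_wallis"
  if (method == "wilcoxon" && k != 2) {
    stop("wilcoxon requires exactly 2 groups (got ", k, ")", call. = FALSE)
  }
  if (method == "kruskal_wallis" && k < 3) {
    stop("kruskal_wallis requires >= 3 groups; use wilcoxon for 2",
         call. = FALSE)
  }
  res <- switch(
    method,
    wilcoxon = {
      t <- stats::wilcox.test(values ~ groups, exact = FALSE)
      c(stat = unname(t$statistic), p = t$p.value)
    },
    kruskal_wallis = {
      t <- stats::kruskal.test(values, groups)
      c(stat = unname(t$statistic), p = t$p.value)
    },
    anova = {
      t <- summary(stats::aov(values ~ groups))[[1]]
      c(stat = t$`F value`[1], p = t$`Pr(>F)`[1])
    }
  )
  p <- unname(res["p"])
  tibble::tibble(
    method = method, statistic = unname(res["stat"]), p_value = p,
    signif = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
    n_groups = k, group_ns = paste(as.integer(ns), collapse = ",")
  )
}

#' Exceedance counts and rates against a standard
#'
#' Screens the samples with [screen_samples()] and reports, per defined
#' limit, the exceedance count, total and percentage (rounded to one
#' decimal, the convention for reporting monitoring compliance).
#'
#' @inheritParams screen_samples
#' @return Tibble: `limit`, `n_exceed`, `n_total`, `percent`.
#' @export
exceedance_rates <- function(samples, standard = default_standards()$china,
                             pefs = default_pef_table(),
                             nd_policy = c("zero", "half_dl", "dl"),
                             detection_limits = default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  if (nrow(samples) == 0) stop("need at least one sample", call. = FALSE)
  flagged <- screen_samples(samples, standard, pefs, nd_policy,
                            detection_limits)
  flag_cols <- grep("^exceeds_", names(flagged), value = TRUE)
  tibble::tibble(
    limit = sub("^exceeds_", "", flag_cols),
    n_exceed = vapply(flag_cols, function(cl) sum(flagged[[cl]]),
                      integer(1), USE.NAMES = FALSE),
    n_total = nrow(flagged),
    percent = vapply(flag_cols, function(cl) {
      exceedance_percent(sum(flagged[[cl]]), nrow(flagged))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Exceedance percentage, rounded to one decimal
#'
#' @param n_exceed,n_total Counts.
#' @return `round(100 * n_exceed / n_total, 1)`.
#' @export
#' @examples
#' exceedance_percent(60, 232)  # 25.9
exceedance_percent <- function(n_exceed, n_total) {
  stopifnot(n_total >= 1, n_exceed >= 0, n_exceed <= n_total)
  round(100 * n_exceed / n_total, 1)
}

#' Correlation between cancer incidence and mortality across villages
#'
#' Pearson correlation of the per-100,000 rates with a two-sided test.
#'
#' @param villages Tibble from [generate_villages()] (needs `incidence` and
#'   `mortality` columns), n >= 3.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
incidence_mortality_correlation <- function(villages) {
  stopifnot(all(c("incidence", "mortality") %in% names(villages)))
  if (nrow(villages) < 3) stop("need >= 3 villages", call. = FALSE)
  if (stats::sd(villages$incidence) == 0 ||
      stats::sd(villages$mortality) == 0) {
    stop("zero variance in incidence or mortality", call. = FALSE)
  }
  ct <- stats::cor.test(villages$incidence, villages$mortality,
                        method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(villages))
}

# Internal: resolved concentration vector for one analyte or aggregate.
# Aggregates: "sum_pahs", "sum_pahs_c", "bapeq".
row_values <- function(samples, row, pefs, nd_policy, detection_limits) {
  switch(row,
         sum_pahs = total_pahs(samples, nd_policy, detection_limits),
         sum_pahs_c = carcinogenic_sum(samples, pefs, nd_policy,
                                       detection_limits),
         bapeq = bapeq_concentration(samples, pefs, nd_policy,
                                     detection_limits),
         resolve_conc(samples[[paste0(row, "_ng_l")]],
                      samples[[paste0(row, "_nd")]],
                      nd_policy, detection_limits[[row]]))
}

fmt_gm_ci <- function(s) {
  sprintf("%.1f (%.1f, %.1f)", s$gm, s$ci_low, s$ci_high)
}

#' Concentration summary-and-comparison table
#'
#' Renders the standard campaign summary: one row per detected analyte plus
#' the three aggregates (total PAHs, carcinogenic PAHs, BaPeq); per stratum
#' (the interaction of `col_var` within each level of `panel_var`) the
#' geometric mean and 95% CI; a rank-test P value across `col_var` strata
#' within each panel; and a P value across panels within each `col_var`
#' stratum plus overall. With `panel_var = "season"` and
#' `col_var = "water_type"` this reproduces the season-comparison layout;
#' with `panel_var = "group"` the risk-vs-control layout.
#'
#' Analytes never detected in the campaign are omitted (their geometric mean
#' is undefined without full substitution), so a 16-analyte campaign with
#' one all-censored analyte yields 15 + 3 = 18 rows. Non-detects entering
#' the geometric means are substituted at half the detection limit by
#' default.
#'
#' @param samples Censored wide sample tibble.
#' @param panel_var `"season"` or `"group"` — the paired panels.
#' @param col_var Stratifying variable within panels (default
#'   `"water_type"`).
#' @param pefs,nd_policy,detection_limits Passed to the aggregation helpers;
#'   `nd_policy` defaults to `"half_dl"` here (a zero substitution would
#'   break the log transform).
#' @return Tibble with one row per analyte/aggregate: `gm (ci)` text columns
#'   per panel x stratum, `p_<panel>` comparison columns across strata, and
#'   `p_<stratum>` / `p_all` columns across panels.
#' @export
summary_table <- function(samples, panel_var = c("season", "group"),
                          col_var = "water_type",
                          pefs = default_pef_table(),
                          nd_policy = c("half_dl", "dl", "zero"),
                          detection_limits = default_detection_limits()) {
  panel_var <- match.arg(panel_var)
  nd_policy <- match.arg(nd_policy)
  stopifnot(col_var %in% names(samples), panel_var %in% names(samples))
  have <- sample_analytes(samples)
  detected <- have[vapply(have, function(a) {
    any(!samples[[paste0(a, "_nd")]])
  }, logical(1))]
  rows <- c(detected, "sum_pahs", "sum_pahs_c", "bapeq")
  panels <- sort(unique(as.character(samples[[panel_var]])))
  strata <- unique(as.character(samples[[col_var]]))

  out <- lapply(rows, function(rw) {
    vals <- row_values(samples, rw, pefs, nd_policy, detection_limits)
    rec <- list(analyte = rw)
    for (pn in panels) {
      in_panel <- samples[[panel_var]] == pn
      for (st in strata) {
        idx <- in_panel & samples[[col_var]] == st
        rec[[paste0(pn, "_", st)]] <-
          if (any(idx)) fmt_gm_ci(geometric_mean_ci(vals[idx])) else NA
      }
      rec[[paste0("p_", pn)]] <-
        compare_groups(vals[in_panel],
                       samples[[col_var]][in_panel])$p_value
    }
    if (length(panels) == 2) {
      for (st in strata) {
        idx <- samples[[col_var]] == st
        rec[[paste0("p_", st)]] <-
          compare_groups(vals[idx], samples[[panel_var]][idx])$p_value
      }
      rec$p_all <- compare_groups(vals, samples[[panel_var]])$p_value
    }
    tibble::as_tibble(rec)
  })
  dplyr::bind_rows(out)
}

#' Deterministic risk summary by stratum
#'
#' Per-sample deterministic lifetime risks (BaPeq as the water
#' concentration, all other exposure parameters at their point values)
#' summarized overall and within strata: mean, standard error of the mean,
#' and the 5th/50th/95th percentiles.
#'
#' @param samples Censored wide sample tibble.
#' @param params Point [exposure_parameters()].
#' @param by Character vector of stratifying columns (e.g.
#'   `c("group", "water_type")`).
#' @inheritParams bapeq_concentration
#' @return List with `risks` (per-sample tibble incl. `cr_total`) and
#'   `summary` (tibble of `label`, `n`, `mean`, `se`, `p5`, `p50`, `p95`).
#' @export
deterministic_risk_summary <- function(samples,
                                       params = exposure_parameters(),
                                       by = c("group", "water_type"),
                                       pefs = default_pef_table(),
                                       nd_policy = c("zero", "half_dl", "dl"),
                                       detection_limits =
                                         default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  cw <- bapeq_concentration(samples, pefs, nd_policy, detection_limits)
  p <- unclass(params)
  p$cw_ng_l <- cw
  p <- structure(p, class = "exposure_parameters")
  rr <- total_risk(p)
  risks <- dplyr::bind_cols(
    samples[intersect(c("village_id", by), names(samples))], rr)
  srow <- function(x, label) {
    q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    tibble::tibble(label = label, n = length(x), mean = mean(x),
                   se = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                        else 0,
                   p5 = q[1], p50 = q[2], p95 = q[3])
  }
  summ <- srow(rr$cr_total, "total")
  for (v in intersect(by, names(samples))) {
    for (lv in unique(as.character(samples[[v]]))) {
      idx <- samples[[v]] == lv
      summ <- dplyr::bind_rows(summ, srow(rr$cr_total[idx],
                                          paste(v, lv, sep = ":")))
    }
  }
  list(risks = risks, summary = summ)
}
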