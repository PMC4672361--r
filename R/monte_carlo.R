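#' Distribution specification for a Monte Carlo input
#'
#' Describes one uncertain risk-model parameter. Supported families:
#' * `point`: `value`;
#' * `lognormal`: either `meanlog`/`sdlog`, or natural-scale `mean` and `cv`
#'   (converted internally);
#' * `uniform`: `min`, `max`;
#' * `gamma`: `shape`, `rate`;
#' * `weibull`: `shape`, `scale`;
#' * `normal`: `mean`, `sd` (draws are truncated at 0, since all model
#'   inputs are non-negative quantities).
#'
#' @param name Parameter name: one of `cw_ng_l`, `bw`, `ed`, `et`, `ir`, `sa`.
#' @param family Distribution family.
#' @param ... Family parameters, as above.
#' @return A list of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("bw", "lognormal", mean = 62.1, cv = 0.2)
#' dist_spec("ed", "uniform", min = 0, max = 70)
dist_spec <- function(name,
                      family = c("point", "lognormal", "uniform", "gamma",
                                 "weibull", "normal"),
                      ...) {
  family <- match.arg(family)
  valid <- c("cw_ng_l", "bw", "ed", "et", "ir", "sa")
  if (!name %in% valid) {
    stop("unknown Monte Carlo parameter '", name, "'; must be one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  p <- list(...)
  p <- switch(
    family,
    point = {
      stopifnot(!is.null(p$value))
      list(value = p$value)
    },
    lognormal = {
      if (!is.null(p[["mean"]])) {
        if (p[["mean"]] <= 0 || is.null(p$cv) || p$cv <= 0) {
          stop("lognormal needs mean > 0 and cv > 0", call. = FALSE)
        }
        sdlog <- sqrt(log(1 + p$cv^2))
        list(meanlog = log(p[["mean"]]) - sdlog^2 / 2, sdlog = sdlog)
      } else {
        stopifnot(!is.null(p$meanlog), !is.null(p$sdlog), p$sdlog > 0)
        list(meanlog = p$meanlog, sdlog = p$sdlog)
      }
    },
    uniform = {
      stopifnot(!is.null(p$min), !is.null(p$max))
      if (p$min >= p$max) stop("uniform needs min < max", call. = FALSE)
      list(min = p$min, max = p$max)
    },
    gamma = {
      stopifnot(!is.null(p$shape), !is.null(p$rate), p$shape > 0, p$rate > 0)
      list(shape = p$shape, rate = p$rate)
    },
    weibull = {
      stopifnot(!is.null(p$shape), !is.null(p$scale), p$shape > 0,
                p$scale > 0)
      list(shape = p$shape, scale = p$scale)
    },
    normal = {
      stopifnot(!is.null(p$mean), !is.null(p$sd), p$sd > 0)
      list(mean = p$mean, sd = p$sd)
    }
  )
  structure(list(name = name, family = family, params = p),
            class = "dist_spec")
}

# One vector of draws from a dist_spec
draw_spec <- function(spec, n) {
  p <- spec$params
  switch(
    spec$family,
    point = rep(p$value, n),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    uniform = stats::runif(n, p$min, p$max),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    weibull = stats::rweibull(n, shape = p$shape, scale = p$scale),
    normal = {
      # inverse-CDF truncation at 0: model inputs cannot be negative
      lo <- stats::pnorm(0, p$mean, p$sd)
      stats::qnorm(stats::runif(n, lo, 1), p$mean, p$sd)
    }
  )
}

#' Default Monte Carlo input distributions
#'
#' The probabilistic counterparts of the deterministic point values:
#' lognormal body weight, contact time, ingestion rate and skin surface
#' (means at the point values; spreads as a configurable coefficient of
#' variation, default 0.2 each) and exposure duration uniform on 0-70 years.
#' The water concentration `cw_ng_l` is supplied separately, usually from
#' [fit_cw_distribution()].
#'
#' @param params An [exposure_parameters()] set providing the means.
#' @param cv Named list/vector of CVs for `bw`, `et`, `ir`, `sa`.
#' @param ed_range Exposure-duration bounds, years.
#' @return Named list of [dist_spec()] objects.
#' @export
default_mc_specs <- function(params = exposure_parameters(),
                             cv = c(bw = 0.2, et = 0.2, ir = 0.2, sa = 0.2),
                             ed_range = c(0, 70)) {
  list(
    bw = dist_spec("bw", "lognormal", mean = params$bw, cv = cv[["bw"]]),
    et = dist_spec("et", "lognormal", mean = params$et, cv = cv[["et"]]),
    ir = dist_spec("ir", "lognormal", mean = params$ir, cv = cv[["ir"]]),
    sa = dist_spec("sa", "lognormal", mean = params$sa, cv = cv[["sa"]]),
    ed = dist_spec("ed", "uniform", min = ed_range[1], max = ed_range[2])
  )
}

#' Fit a concentration distribution to detected BaPeq values
#'
#' Fits each candidate family by maximum likelihood (via
#' \pkg{fitdistrplus}), selects by lowest AIC (ties broken by the smaller
#' Kolmogorov-Smirnov statistic) and returns the winner as a [dist_spec()]
#' for the water-concentration input `cw_ng_l`.
#'
#' @param values Positive concentrations, ng/L; at least 10, non-degenerate.
#' @param candidates Subset of `c("lognormal", "gamma", "weibull", "normal")`.
#' @return A `dist_spec` with attributes `fits` (per-family AIC/KS table) and,
#'   for a lognormal winner, `gm` (back-transformed geometric mean, ng/L).
#' @export
#' @examples
#' set.seed(1)
#' fit_cw_distribution(rlnorm(500, log(10), log(2)))
fit_cw_distribution <- function(values,
                                candidates = c("lognormal", "gamma",
                                               "weibull", "normal")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  values <- as.numeric(values)
  if (length(values) < 10) {
    stop("need at least 10 positive concentrations to fit", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all concentrations must be positive and finite", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("concentrations are constant; no distribution can be fitted ",
         "(use a point spec instead)", call. = FALSE)
  }
  distname <- c(lognormal = "lnorm", gamma = "gamma", weibull = "weibull",
                normal = "norm")
  fits <- list(); diag <- character(0)
  for (fam in candidates) {
    f <- tryCatch(fitdistrplus::fitdist(values, distname[[fam]]),
                  error = function(e) e)
    if (inherits(f, "error")) {
      diag[fam] <- conditionMessage(f)
    } else {
      gof <- fitdistrplus::gofstat(f)
      fits[[fam]] <- list(fit = f, aic = f$aic, ks = unname(gof$ks))
    }
  }
  if (length(fits) == 0) {
    stop("all candidate fits failed:\n",
         paste(names(diag), diag, sep = ": ", collapse = "\n"),
         call. = FALSE)
  }
  tab <- tibble::tibble(
    family = names(fits),
    aic = vapply(fits, function(x) x$aic, numeric(1)),
    ks = vapply(fits, function(x) x$ks, numeric(1))
  )
  tab <- tab[order(tab$aic, tab$ks), ]
  best <- fits[[tab$family[1]]]$fit
  est <- as.list(best$estimate)
  spec <- switch(
    tab$family[1],
    lognormal = dist_spec("cw_ng_l", "lognormal", meanlog = est$meanlog,
                          sdlog = est$sdlog),
    gamma = dist_spec("cw_ng_l", "gamma", shape = est$shape, rate = est$rate),
    weibull = dist_spec("cw_ng_l", "weibull", shape = est$shape,
                        scale = est$scale),
    normal = dist_spec("cw_ng_l", "normal", mean = est$mean, sd = est$sd)
  )
  attr(spec, "fits") <- tab
  if (spec$family == "lognormal") attr(spec, "gm") <- exp(est$meanlog)
  spec
}

#' Draw a Monte Carlo parameter table
#'
#' Independent draws for every supplied spec; parameters without a spec are
#' not drawn (the risk engine holds them at their point defaults).
#'
#' @param specs List of [dist_spec()] objects (possibly named).
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Tibble with `n` rows and one column per spec.
#' @export
sample_parameters <- function(specs, n = 10000, seed = 1L) {
  stopifnot(n >= 1)
  specs <- as_spec_list(specs)
  set.seed(seed)
  out <- lapply(specs, draw_spec, n = n)
  tibble::as_tibble(stats::setNames(out, vapply(specs, `[[`, "", "name")))
}

as_spec_list <- function(specs) {
  if (inherits(specs, "dist_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "dist_spec")))
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate parameter specs", call. = FALSE)
  specs
}

#' Monte Carlo simulation of lifetime cancer risk
#'
#' Propagates the input distributions through the deterministic risk model:
#' each draw row is evaluated with [total_risk()], parameters without a spec
#' held at the point values in `params`. Returns the draws, summary
#' statistics (mean, SE of the mean, 5th/50th/95th percentiles) and
#' Spearman rank-correlation sensitivity coefficients.
#'
#' @param specs List of [dist_spec()]s (e.g. [default_mc_specs()] plus a
#'   fitted `cw_ng_l` spec).
#' @param params Point defaults, an [exposure_parameters()] set.
#' @param n Number of draws (default 10,000).
#' @param seed Integer seed.
#' @return A list of class `mc_result`: `n`, `draws`, `risks` (tibble from
#'   [total_risk()]), `mean`, `se`, `p5`, `p50`, `p95`, `sensitivity`.
#' @export
#' @examples
#' specs <- c(default_mc_specs(),
#'            list(cw = dist_spec("cw_ng_l", "lognormal",
#'                                meanlog = log(10), sdlog = log(2))))
#' r <- simulate_risk(specs, n = 2000, seed = 42)
#' r$mean; r$sensitivity
simulate_risk <- function(specs, params = exposure_parameters(), n = 10000,
                          seed = 1L) {
  stopifnot(inherits(params, "exposure_parameters"), n >= 1)
  specs <- as_spec_list(specs)
  draws <- sample_parameters(specs, n = n, seed = seed)
  p <- unclass(params)
  for (nm in names(draws)) p[[nm]] <- draws[[nm]]
  p <- structure(p, class = "exposure_parameters")
  validate_exposure_parameters(p)
  risks <- total_risk(p)
  varied <- vapply(draws, function(x) stats::sd(x) > 0, logical(1))
  rho <- if (any(varied) && n >= 3) {
    sensitivity(draws, risks$cr_total)
  } else {
    # fully degenerate run: the point-collapse oracle case; no input varies
    stats::setNames(rep(NA_real_, ncol(draws)), names(draws))
  }
  summarize_mc(structure(list(n = n, draws = draws, risks = risks,
                              sensitivity = rho),
                         class = "mc_result"))
}

#' Rank-correlation sensitivity analysis
#'
#' Spearman rank correlation between each input parameter's draws and the
#' output risks — the convention of spreadsheet risk packages for ranking
#' input influence. Parameters with zero variance are reported as `NA`.
#'
#' @param draws Tibble of parameter draws.
#' @param risks Numeric vector of output risks, same length.
#' @return Named numeric vector of rank correlations in \[-1, 1\] (or `NA`),
#'   ordered by decreasing absolute value.
#' @export
sensitivity <- function(draws, risks) {
  stopifnot(nrow(draws) == length(risks))
  if (nrow(draws) < 3) stop("need at least 3 draws", call. = FALSE)
  varied <- vapply(draws, function(x) stats::sd(x) > 0, logical(1))
  if (!any(varied)) {
    stop("all parameters are constant; sensitivity is undefined",
         call. = FALSE)
  }
  rho <- vapply(names(draws), function(nm) {
    if (!varied[[nm]]) return(NA_real_)
    stats::cor(draws[[nm]], risks, method = "spearman")
  }, numeric(1))
  rho[order(-abs(rho), na.last = TRUE)]
}

#' Summary statistics of a Monte Carlo result
#'
#' Attaches (or recomputes) the mean, standard error of the mean and the
#' empirical 5th/50th/95th percentiles (type-7 linear interpolation) of the
#' total-risk draws.
#'
#' @param mc An `mc_result`.
#' @return The `mc_result` with `mean`, `se`, `p5`, `p50`, `p95` fields set.
#' @export
summarize_mc <- function(mc) {
  stopifnot(inherits(mc, "mc_result"))
  x <- mc$risks$cr_total
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  mc$mean <- mean(x)
  mc$se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  mc$p5 <- q[1]; mc$p50 <- q[2]; mc$p95 <- q[3]
  mc
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo risk simulation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean %.3e  SE %.3e\n", x$mean, x$se))
  cat(sprintf("  P5 %.3e  P50 %.3e  P95 %.3e\n", x$p5, x$p50, x$p95))
  cat("  sensitivity (Spearman rho):\n")
  s <- x$sensitivity
  for (nm in names(s)) {
    cat(sprintf("    %-8s %s\n", nm,
                ifelse(is.na(s[[nm]]), "n/a", sprintf("%+.3f", s[[nm]]))))
  }
  invisible(x)
}

#' One summary row of a Monte Carlo result
#'
#' @param mc An `mc_result`.
#' @param label Optional stratum label.
#' @return One-row tibble: `label`, `n`, `mean`, `se`, `p5`, `p50`, `p95`.
#' @export
mc_summary_row <- function(mc, label = "total") {
  stopifnot(inherits(mc, "mc_result"))
  tibble::tibble(label = label, n = mc$n, mean = mc$mean, se = mc$se,
                 p5 = mc$p5, p50 = mc$p50, p95 = mc$p95)
}
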