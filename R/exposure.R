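#' Exposure parameter set for the ingestion/dermal risk model
#'
#' Bundles every symbol of the chronic-daily-intake and cancer-risk equations.
#' Defaults are the adult lifetime point values used in the deterministic
#' assessment: ingestion rate 2.39 L/day and body weight 62.1 kg (Chinese
#' exposure-factors handbook), exposure frequency 350 days/year, exposure
#' duration 70 years, averaging time 25,550 days (70 y x 365 d), exposed skin
#' surface 16,000 cm2, BaP dermal permeability 1.2 cm/h, 0.15 h/day contact
#' time, oral slope factor 7.3 (mg/kg/day)^-1 and gastrointestinal absorption
#' fraction 0.92. Concentrations enter in ng/L and are converted to mg/L
#' (factor 1e-6) inside the dose equations.
#'
#' All fields may be vectors (recycled against each other), which is how the
#' Monte Carlo engine evaluates the model on a draw table.
#'
#' @param cw_ng_l BaPeq concentration in water, ng/L (>= 0).
#' @param ir Water ingestion rate, L/day.
#' @param ef Exposure frequency, days/year (<= 366).
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at Averaging time, days (fixed lifetime denominator).
#' @param sa Exposed dermal surface area, cm2.
#' @param kp Dermal permeability coefficient, cm/h.
#' @param et Water-contact exposure time, h/day.
#' @param sf_oral Oral cancer slope factor, (mg/kg/day)^-1.
#' @param aaf Gastrointestinal absorption fraction in (0, 1], used to convert
#'   the oral (administered-dose) slope factor to an absorbed-dose basis for
#'   the dermal route.
#' @param cf Volume conversion factor, exactly 0.001 L/cm3.
#' @param rounded_dermal_sf If `TRUE`, the dermal route uses the slope factor
#'   rounded to one decimal (7.9) instead of the exact quotient; off by
#'   default so downstream risk carries full precision.
#' @return A list of class `exposure_parameters`.
#' @export
#' @examples
#' p <- exposure_parameters(cw_ng_l = 10)
#' total_risk(p)
exposure_parameters <- function(cw_ng_l = 10, ir = 2.39, ef = 350, ed = 70,
                                bw = 62.1, at = 25550, sa = 16000, kp = 1.2,
                                et = 0.15, sf_oral = 7.3, aaf = 0.92,
                                cf = 0.001, rounded_dermal_sf = FALSE) {
  p <- list(cw_ng_l = cw_ng_l, ir = ir, ef = ef, ed = ed, bw = bw, at = at,
            sa = sa, kp = kp, et = et, sf_oral = sf_oral, aaf = aaf, cf = cf,
            rounded_dermal_sf = isTRUE(rounded_dermal_sf))
  validate_exposure_parameters(p)
  structure(p, class = "exposure_parameters")
}

validate_exposure_parameters <- function(p) {
  num <- c("cw_ng_l", "ir", "ef", "ed", "bw", "at", "sa", "kp", "et",
           "sf_oral", "aaf", "cf")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) < 1 || anyNA(p[[nm]])) {
      stop("exposure parameter '", nm, "' must be numeric and non-missing",
           call. = FALSE)
    }
  }
  if (any(p$cw_ng_l < 0)) stop("cw_ng_l must be >= 0", call. = FALSE)
  for (nm in setdiff(num, "cw_ng_l")) {
    if (any(p[[nm]] <= 0)) {
      if (nm == "ed") next  # ED = 0 is a legal draw (uniform 0-70 includes 0)
      stop("exposure parameter '", nm, "' must be strictly positive",
           call. = FALSE)
    }
  }
  if (any(p$ed < 0)) stop("exposure parameter 'ed' must be >= 0", call. = FALSE)
  if (any(p$ef > 366)) stop("ef cannot exceed 366 days/year", call. = FALSE)
  if (any(p$aaf > 1)) stop("aaf must lie in (0, 1]", call. = FALSE)
  if (any(p$cf != 0.001)) stop("cf is fixed at 0.001 L/cm3", call. = FALSE)
  invisible(p)
}

# ng/L -> mg/L, applied exactly once at the dose-equation boundary
NG_PER_L_TO_MG_PER_L <- 1e-6

#' Chronic daily intake via ingestion
#'
#' `CDIi = Cw x IR x EF x ED / (BW x AT)` with Cw in mg/L, giving a dose in
#' mg BaPeq per kg body weight per day, averaged over a lifetime.
#'
#' @param p An [exposure_parameters()] set (fields may be vectors).
#' @return Numeric vector of doses, mg/kg/day.
#' @export
cdi_ingestion <- function(p) {
  stopifnot(inherits(p, "exposure_parameters"))
  cw <- p$cw_ng_l * NG_PER_L_TO_MG_PER_L
  cw * p$ir * p$ef * p$ed / (p$bw * p$at)
}

#' Chronic daily intake via dermal absorption
#'
#' `CDId = Cw x SA x Kp x ET x EF x ED x CF / (BW x AT)` with Cw in mg/L and
#' CF = 0.001 L/cm3 converting the permeated volume.
#'
#' @inheritParams cdi_ingestion
#' @return Numeric vector of doses, mg/kg/day.
#' @export
cdi_dermal <- function(p) {
  stopifnot(inherits(p, "exposure_parameters"))
  cw <- p$cw_ng_l * NG_PER_L_TO_MG_PER_L
  cw * p$sa * p$kp * p$et * p$ef * p$ed * p$cf / (p$bw * p$at)
}

#' Dermal slope factor from the oral slope factor
#'
#' The oral slope factor is expressed per administered dose; the dermal route
#' delivers an absorbed dose, so the factor is divided by the
#' gastrointestinal absorption fraction: `SF_dermal = SF_oral / AAF`.
#' With the BaP defaults, 7.3 / 0.92 = 7.93 (mg/kg/day)^-1, conventionally
#' presented as 7.9.
#'
#' @param sf_oral Oral slope factor, (mg/kg/day)^-1.
#' @param aaf Gastrointestinal absorption fraction in (0, 1].
#' @param presented If `TRUE`, round to one decimal for reporting; the
#'   default returns the unrounded value used in computation.
#' @return Dermal slope factor, (mg/kg/day)^-1.
#' @export
#' @examples
#' dermal_sf(7.3, 0.92)                   # 7.934783...
#' dermal_sf(7.3, 0.92, presented = TRUE) # 7.9
dermal_sf <- function(sf_oral, aaf, presented = FALSE) {
  if (!is.numeric(aaf) || any(aaf <= 0) || any(aaf > 1)) {
    stop("aaf must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(sf_oral) || any(sf_oral <= 0)) {
    stop("sf_oral must be positive", call. = FALSE)
  }
  out <- sf_oral / aaf
  if (isTRUE(presented)) round(out, 1) else out
}

#' Lifetime cancer risk from a chronic daily intake
#'
#' `CR = CDI x SF`: the linear low-dose extrapolation converting an averaged
#' daily dose into an incremental lifetime cancer probability. No capping is
#' applied; environmental risks here are far below 1.
#'
#' @param cdi Chronic daily intake, mg/kg/day (>= 0).
#' @param sf Slope factor, (mg/kg/day)^-1 (> 0).
#' @return Numeric vector of lifetime probabilities.
#' @export
carcinogenic_risk <- function(cdi, sf) {
  if (any(cdi < 0)) stop("cdi must be >= 0", call. = FALSE)
  if (any(sf <= 0)) stop("sf must be > 0", call. = FALSE)
  cdi * sf
}

#' Total carcinogenic risk via ingestion and dermal exposure
#'
#' Composes the two dose equations and the slope factors: the ingestion route
#' uses the oral slope factor; the dermal route uses [dermal_sf()]. Total risk
#' is the sum of the two route risks, classified against the US EPA
#' 1e-6 / 1e-4 risk-management range.
#'
#' @inheritParams cdi_ingestion
#' @return A tibble of class `risk_result` with one row per parameter-vector
#'   element: `cdi_ingestion`, `cdi_dermal`, `cr_ingestion`, `cr_dermal`,
#'   `cr_total`, `category`.
#' @export
#' @examples
#' total_risk(exposure_parameters(cw_ng_l = 10))
total_risk <- function(p) {
  stopifnot(inherits(p, "exposure_parameters"))
  cdi_i <- cdi_ingestion(p)
  cdi_d <- cdi_dermal(p)
  sf_d <- dermal_sf(p$sf_oral, p$aaf)
  if (isTRUE(p$rounded_dermal_sf)) sf_d <- round(sf_d, 1)
  cr_i <- carcinogenic_risk(cdi_i, p$sf_oral)
  cr_d <- carcinogenic_risk(cdi_d, sf_d)
  out <- tibble::tibble(
    cdi_ingestion = cdi_i,
    cdi_dermal = cdi_d,
    cr_ingestion = cr_i,
    cr_dermal = cr_d,
    cr_total = cr_i + cr_d,
    category = classify_risk(cr_i + cr_d)
  )
  class(out) <- c("risk_result", class(out))
  out
}

#' Classify a lifetime cancer risk against the EPA management range
#'
#' Risks of at most 1e-6 are below the de minimis level; risks strictly above
#' 1e-4 exceed the upper management limit; everything between is within the
#' acceptable range. Both comparisons are strict (`>`), so a risk exactly at
#' a threshold falls in the lower category.
#'
#' @param cr_total Numeric vector of lifetime risks (>= 0).
#' @return Factor with levels `below_de_minimis`, `acceptable`, `above_limit`.
#' @export
#' @examples
#' classify_risk(c(5e-7, 5e-5, 2e-4))
classify_risk <- function(cr_total) {
  if (any(cr_total < 0)) stop("cr_total must be >= 0", call. = FALSE)
  lv <- c("below_de_minimis", "acceptable", "above_limit")
  out <- ifelse(cr_total > 1e-4, lv[3], ifelse(cr_total > 1e-6, lv[2], lv[1]))
  factor(out, levels = lv)
}
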