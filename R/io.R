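#' Read a water-sample table from CSV
#'
#' Expected schema: `village_id`, `group`, `water_type`, `season`, then one
#' `<analyte>_ng_l` and one `<analyte>_nd` column per analyte (ng/L;
#' non-detect rows carry an empty concentration). Validation failures report
#' the offending data row.
#'
#' @param path CSV file path.
#' @return Wide sample tibble.
#' @export
read_samples <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  key <- c("village_id", "group", "water_type", "season")
  missing_key <- setdiff(key, names(raw))
  if (length(missing_key) > 0) {
    stop("sample file lacks column(s): ", paste(missing_key, collapse = ", "),
         call. = FALSE)
  }
  other <- setdiff(names(raw), key)
  an <- unique(sub("_(ng_l|nd)$", "", other))
  unknown <- setdiff(an, pah_analytes())
  if (length(unknown) > 0) {
    stop("unknown analyte column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  raw$group <- factor(raw$group, levels = c("risk", "control"))
  if (nrow(raw) == 0) {
    warning("sample file ", path, " contains a header only; returning an ",
            "empty table")
    return(tibble::as_tibble(raw))
  }
  for (a in an) {
    raw[[paste0(a, "_ng_l")]] <- as.numeric(raw[[paste0(a, "_ng_l")]])
    cc <- paste0(a, "_ng_l"); nc <- paste0(a, "_nd")
    if (!all(c(cc, nc) %in% names(raw))) {
      stop("analyte ", a, " needs both ", cc, " and ", nc, " columns",
           call. = FALSE)
    }
    raw[[nc]] <- as.logical(raw[[nc]])
    bad <- which(!raw[[nc]] & (is.na(raw[[cc]]) | raw[[cc]] <= 0))
    if (length(bad) > 0) {
      stop("row ", bad[1], ": detected ", a,
           " concentration missing or non-positive", call. = FALSE)
    }
    bad <- which(raw[[nc]] & !is.na(raw[[cc]]))
    if (length(bad) > 0) {
      stop("row ", bad[1], ": ", a,
           " flagged non-detect but carries a concentration", call. = FALSE)
    }
  }
  raw
}

#' Write a water-sample table to CSV
#' @param samples Wide sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a village registry table from CSV
#'
#' Columns: `village_id`, `group`, `population`, `incidence`, `mortality`.
#'
#' @param path CSV file path.
#' @return Village tibble.
#' @export
read_villages <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("village_id", "group", "population", "incidence", "mortality")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("village file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(raw$population < 1 | raw$incidence < 0 | raw$mortality < 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": population must be >= 1 and rates >= 0",
         call. = FALSE)
  }
  raw
}

#' Write a village registry table to CSV
#' @param villages Village tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_villages <- function(villages, path) {
  readr::write_csv(villages, path, progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The full configuration tree consumed by [run_pipeline()]: `synthetic`
#' (campaign design and registry parameters), `exposure` (point values),
#' `standards` (screening limits, ng/L), `mc` (draw count and input CVs),
#' `stats` (non-detect policies) and `seed`. [read_config()] merges a YAML
#' file over these defaults.
#'
#' @param seed Integer campaign seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      enabled = TRUE,
      n_villages_per_group = 20,
      water_types = c("SW", "SG", "DG"),
      seasons = c("winter", "summer"),
      missingness_rate = 8 / 240,
      village_sd = 0.4,
      sd_log = 0.7,
      incidence = list(
        risk = c(mean = 397.47, sd = 92.35),
        control = c(mean = 134.89, sd = 50.33),
        mortality_risk = c(mean = 313.44, sd = 73.83),
        mortality_control = c(mean = 140.06, sd = 71.73),
        r = 0.78
      )
    ),
    exposure = list(
      ir_l_per_day = 2.39, ef_days_per_year = 350, ed_years = 70,
      bw_kg = 62.1, at_days = 25550, sa_cm2 = 16000, kp_cm_per_h = 1.2,
      et_h_per_day = 0.15, sf_oral = 7.3, aaf = 0.92,
      rounded_dermal_sf = FALSE
    ),
    standards = list(
      china = list(bap_ng_l = 10, total_ng_l = 2000, bapeq_ng_l = 10),
      us = list(bap_ng_l = 200),
      egypt = list(bap_ng_l = 700)
    ),
    mc = list(
      n = 10000,
      cv = c(bw = 0.2, et = 0.2, ir = 0.2, sa = 0.2),
      ed_range = c(0, 70)
    ),
    stats = list(nd_policy_sums = "zero", nd_policy_gm = "half_dl"),
    io = list(samples = NULL, villages = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override [default_config()]; everything else keeps its
#' default. Basic schema validation runs before any stage.
#'
#' @param path YAML file path (optional; `NULL` returns the defaults).
#' @param seed Seed overriding both the file and the default.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    # keep bare y/n keys (e.g. mc.n) as strings; YAML 1.1 would read them
    # as booleans
    handlers <- list(
      "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
      "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE
    )
    user <- yaml::read_yaml(path, handlers = handlers)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  exp <- cfg$exposure
  if (any(unlist(exp[setdiff(names(exp), "rounded_dermal_sf")]) <= 0)) {
    stop("config: every exposure value must be positive", call. = FALSE)
  }
  if (!is.numeric(cfg$mc$n) || cfg$mc$n < 1) {
    stop("config: mc.n must be a positive integer", call. = FALSE)
  }
  if (cfg$synthetic$missingness_rate < 0 ||
      cfg$synthetic$missingness_rate >= 1) {
    stop("config: synthetic.missingness_rate must lie in [0, 1)",
         call. = FALSE)
  }
  for (nm in names(cfg$standards)) {
    if (any(unlist(cfg$standards[[nm]]) <= 0)) {
      stop("config: standard '", nm, "' has a non-positive limit",
           call. = FALSE)
    }
  }
  cfg
}

# Exposure-parameter set (point values) from a config
config_exposure <- function(cfg, cw_ng_l = 10) {
  e <- cfg$exposure
  exposure_parameters(
    cw_ng_l = cw_ng_l, ir = e$ir_l_per_day, ef = e$ef_days_per_year,
    ed = e$ed_years, bw = e$bw_kg, at = e$at_days, sa = e$sa_cm2,
    kp = e$kp_cm_per_h, et = e$et_h_per_day, sf_oral = e$sf_oral,
    aaf = e$aaf, rounded_dermal_sf = isTRUE(e$rounded_dermal_sf)
  )
}

config_standard <- function(block, name) {
  structure(c(list(name = name), block), class = "water_standard")
}
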