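#' Run the full risk-assessment pipeline
#'
#' Orchestrates every stage on one campaign: (1) synthetic generation of the
#' village registry and water samples (or reading user CSVs from
#' `config$io`), (2) detection-limit censoring, (3) BaPeq conversion,
#' (4) standard screening and exceedance rates, (5) deterministic per-sample
#' risk with stratified summaries, (6) Monte Carlo risk with a fitted
#' concentration distribution and sensitivity analysis, and (7) descriptive
#' group statistics (summary tables, incidence-mortality correlation,
#' registry summary). All randomness flows from `config$seed`; a manifest
#' records the seed, package version and a hash of the configuration so two
#' runs with the same config are identical.
#'
#' @param config Configuration from [default_config()] / [read_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV/JSON files there.
#' @return (Invisibly when writing) a list: `villages`, `samples`,
#'   `exceedance`, `deterministic` (per-sample risks + summary),
#'   `mc` (an `mc_result`), `mc_summary`, `season_table`, `group_table`,
#'   `incidence_correlation`, `registry_summary`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_config(seed = 1))
#' res$exceedance
#' res$mc$mean
#' }
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[pahrisk] %-14s %6.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  syn <- config$synthetic
  design <- campaign_design(
    n_villages_per_group = syn$n_villages_per_group,
    water_types = syn$water_types, seasons = syn$seasons,
    missingness_rate = syn$missingness_rate, seed = config$seed
  )

  inputs <- stage("inputs", {
    if (!is.null(config$io$samples)) {
      list(villages = read_villages(config$io$villages),
           samples = read_samples(config$io$samples))
    } else {
      inc <- syn$incidence
      villages <- generate_villages(
        design,
        incidence_params(risk = unlist(inc$risk),
                         control = unlist(inc$control),
                         mortality_risk = unlist(inc$mortality_risk),
                         mortality_control = unlist(inc$mortality_control),
                         r = inc$r))
      model <- concentration_model(sd_log = syn$sd_log,
                                   village_sd = syn$village_sd)
      samples <- apply_detection_limits(
        generate_samples(villages, design, model),
        design$detection_limits)
      list(villages = villages, samples = samples)
    }
  })
  villages <- inputs$villages
  samples <- inputs$samples

  nd_sums <- config$stats$nd_policy_sums
  dl <- design$detection_limits
  pefs <- default_pef_table()

  samples <- stage("bapeq", {
    samples$bapeq_ng_l <- bapeq_concentration(samples, pefs, nd_sums, dl)
    samples$total_pahs_ng_l <- total_pahs(samples, nd_sums, dl)
    samples
  })

  exceed <- stage("screening", {
    dplyr::bind_rows(lapply(names(config$standards), function(nm) {
      dplyr::mutate(
        exceedance_rates(samples, config_standard(config$standards[[nm]], nm),
                         pefs, nd_sums, dl),
        standard = nm, .before = 1)
    }))
  })

  det <- stage("deterministic", {
    deterministic_risk_summary(samples, config_exposure(config),
                               by = c("group", "water_type"),
                               pefs = pefs, nd_policy = nd_sums,
                               detection_limits = dl)
  })

  mc <- stage("monte_carlo", {
    detected <- samples$bapeq_ng_l[samples$bapeq_ng_l > 0]
    cw_spec <- fit_cw_distribution(detected)
    specs <- c(default_mc_specs(config_exposure(config),
                                cv = unlist(config$mc$cv),
                                ed_range = unlist(config$mc$ed_range)),
               list(cw = cw_spec))
    simulate_risk(specs, config_exposure(config), n = config$mc$n,
                  seed = config$seed + 20011L)
  })

  stats_out <- stage("group_stats", {
    nd_gm <- config$stats$nd_policy_gm
    list(
      season_table = summary_table(samples, "season", "water_type", pefs,
                                   nd_gm, dl),
      group_table = summary_table(samples, "group", "water_type", pefs,
                                  nd_gm, dl),
      incidence_correlation = incidence_mortality_correlation(villages),
      registry_summary = dplyr::summarise(
        dplyr::group_by(villages, .data$group),
        n = dplyr::n(),
        incidence_mean = mean(.data$incidence),
        incidence_sd = stats::sd(.data$incidence),
        mortality_mean = mean(.data$mortality),
        mortality_sd = stats::sd(.data$mortality),
        .groups = "drop")
    )
  })

  cfg_hash <- rlang::hash(config)
  manifest <- list(
    package = "pahrisk",
    version = as.character(utils::packageVersion("pahrisk")),
    seed = config$seed,
    config_hash = cfg_hash,
    n_villages = nrow(villages),
    n_samples = nrow(samples),
    mc_n = mc$n
  )

  res <- list(
    villages = villages, samples = samples, exceedance = exceed,
    deterministic = det, mc = mc,
    mc_summary = mc_summary_row(mc),
    season_table = stats_out$season_table,
    group_table = stats_out$group_table,
    incidence_correlation = stats_out$incidence_correlation,
    registry_summary = stats_out$registry_summary,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_villages(villages, file.path(out_dir, "villages.csv"))
      write_samples(samples, file.path(out_dir, "samples.csv"))
      readr::write_csv(exceed, file.path(out_dir, "exceedance.csv"))
      readr::write_csv(det$risks, file.path(out_dir, "risk_per_sample.csv"))
      readr::write_csv(det$summary,
                       file.path(out_dir, "risk_summary_deterministic.csv"))
      readr::write_csv(res$mc_summary,
                       file.path(out_dir, "risk_summary_probabilistic.csv"))
      readr::write_csv(res$season_table,
                       file.path(out_dir, "summary_by_season.csv"))
      readr::write_csv(res$group_table,
                       file.path(out_dir, "summary_by_group.csv"))
      jsonlite::write_json(
        c(manifest,
          list(sensitivity = as.list(mc$sensitivity),
               incidence_correlation = as.list(res$incidence_correlation))),
        file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      NULL
    })
    return(invisible(res))
  }
  res
}
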