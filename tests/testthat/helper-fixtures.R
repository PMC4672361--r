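# A minimal wide sample row: named concentrations, everything else non-detect.
# Analytes not mentioned get nd = TRUE with no value.
make_sample <- function(..., analytes = pah_analytes(), n = 1,
                        group = "risk", water_type = "SW",
                        season = "winter") {
  conc <- list(...)
  out <- tibble::tibble(
    village_id = sprintf("V%02d", seq_len(n)),
    group = group, water_type = water_type, season = season
  )
  for (a in analytes) {
    if (a %in% names(conc)) {
      out[[paste0(a, "_ng_l")]] <- conc[[a]]
      out[[paste0(a, "_nd")]] <- FALSE
    } else {
      out[[paste0(a, "_ng_l")]] <- NA_real_
      out[[paste0(a, "_nd")]] <- TRUE
    }
  }
  out
}

# Default small campaign used across tests (deterministic given seed)
make_campaign <- function(seed = 1, n_villages = 20) {
  design <- campaign_design(n_villages_per_group = n_villages, seed = seed)
  villages <- generate_villages(design)
  samples <- apply_detection_limits(generate_samples(villages, design),
                                    design$detection_limits)
  list(design = design, villages = villages, samples = samples)
}
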