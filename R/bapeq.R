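#' @importFrom rlang .data
NULL

# Internal: column names of the wide sample table
conc_cols <- function(analytes = pah_analytes()) paste0(analytes, "_ng_l")
nd_cols <- function(analytes = pah_analytes()) paste0(analytes, "_nd")

# Internal: check a samples tibble and return the analytes it carries
sample_analytes <- function(samples, required = NULL) {
  stopifnot(is.data.frame(samples))
  have <- pah_analytes()[conc_cols() %in% names(samples)]
  missing_nd <- setdiff(nd_cols(have), names(samples))
  if (length(missing_nd) > 0) {
    stop("samples table lacks non-detect flag column(s): ",
         paste(missing_nd, collapse = ", "), call. = FALSE)
  }
  if (!is.null(required)) {
    absent <- setdiff(required, have)
    if (length(absent) > 0) {
      stop("analyte(s) absent from sample table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  have
}

# Internal: resolve one analyte's concentrations under a non-detect policy.
# Detected values pass through; non-detects become 0, DL/2 or DL.
resolve_conc <- function(conc, nd, policy, dl) {
  policy <- match.arg(policy, c("zero", "half_dl", "dl"))
  sub <- switch(policy, zero = 0, half_dl = dl / 2, dl = dl)
  if (anyNA(conc[!nd])) {
    stop("detected concentrations must not be missing", call. = FALSE)
  }
  ifelse(nd, sub, conc)
}

#' BaPeq concentration of water samples
#'
#' The benzo\[a\]pyrene-equivalent concentration: the PEF-weighted sum of the
#' carcinogenic PAH concentrations, `sum(PEF_i x C_i)` over the carcinogenic
#' set. Non-detected analytes contribute according to `nd_policy`: zero
#' (default), half the detection limit, or the detection limit.
#'
#' @param samples Tibble of water samples in wide form (one `<analyte>_ng_l`
#'   and one `<analyte>_nd` column per analyte), as produced by
#'   [generate_samples()] or [read_samples()].
#' @param pefs A [default_pef_table()]-style PEF table.
#' @param nd_policy Non-detect substitution: `"zero"`, `"half_dl"` or `"dl"`.
#' @param detection_limits Named numeric vector of detection limits, ng/L
#'   (used by the `half_dl` and `dl` policies).
#' @return Numeric vector, one BaPeq value (ng/L) per sample row.
#' @export
#' @examples
#' s <- tibble::tibble(BaA_ng_l = 100, BaA_nd = FALSE,
#'                     BaP_ng_l = 5, BaP_nd = FALSE)
#' bapeq_concentration(s, pefs = default_pef_table(c(BaA = 0.1, BaP = 1)))
bapeq_concentration <- function(samples, pefs = default_pef_table(),
                                nd_policy = c("zero", "half_dl", "dl"),
                                detection_limits = default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  carc <- carcinogenic_set(pefs)
  sample_analytes(samples, required = carc)
  out <- numeric(nrow(samples))
  for (a in carc) {
    conc <- resolve_conc(samples[[paste0(a, "_ng_l")]],
                         samples[[paste0(a, "_nd")]],
                         nd_policy, detection_limits[[a]])
    out <- out + pefs[[a]] * conc
  }
  out
}

#' Total PAH concentration of water samples
#'
#' Unweighted sum over all analytes present in the table (the 16 priority
#' PAHs in a full campaign), with non-detects resolved by `nd_policy`.
#'
#' @inheritParams bapeq_concentration
#' @return Numeric vector, one total (ng/L) per sample row.
#' @export
total_pahs <- function(samples, nd_policy = c("zero", "half_dl", "dl"),
                       detection_limits = default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  have <- sample_analytes(samples)
  if (length(have) == 0) stop("no analyte columns in sample table", call. = FALSE)
  out <- numeric(nrow(samples))
  for (a in have) {
    out <- out + resolve_conc(samples[[paste0(a, "_ng_l")]],
                              samples[[paste0(a, "_nd")]],
                              nd_policy, detection_limits[[a]])
  }
  out
}

#' Summed carcinogenic PAH concentration
#'
#' As [total_pahs()] restricted to the carcinogenic set of the PEF table,
#' unweighted.
#'
#' @inheritParams bapeq_concentration
#' @return Numeric vector, ng/L per sample row.
#' @export
carcinogenic_sum <- function(samples, pefs = default_pef_table(),
                             nd_policy = c("zero", "half_dl", "dl"),
                             detection_limits = default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  carc <- carcinogenic_set(pefs)
  sample_analytes(samples, required = carc)
  out <- numeric(nrow(samples))
  for (a in carc) {
    out <- out + resolve_conc(samples[[paste0(a, "_ng_l")]],
                              samples[[paste0(a, "_nd")]],
                              nd_policy, detection_limits[[a]])
  }
  out
}

#' Screen samples against a drinking-water standard
#'
#' Computes the quantities the standard regulates (per-analyte
#' concentrations, total PAHs, BaPeq) and flags strict exceedances
#' (`value > limit`; equality is compliant). Non-detects count as zero for
#' screening under the default policy.
#'
#' @inheritParams bapeq_concentration
#' @param standard One element of [default_standards()] (or a compatible
#'   `water_standard` list with `bap_ng_l` / `total_ng_l` / `bapeq_ng_l`).
#' @return The `samples` tibble with one logical `exceeds_<limit>` column per
#'   limit the standard defines (e.g. `exceeds_bap`, `exceeds_total`,
#'   `exceeds_bapeq`).
#' @export
#' @examples
#' s <- generate_samples(generate_villages(campaign_design(seed = 1)),
#'                       campaign_design(seed = 1))
#' s <- apply_detection_limits(s)
#' colSums(screen_samples(s, default_standards()$china)[
#'   c("exceeds_bap", "exceeds_total", "exceeds_bapeq")])
screen_samples <- function(samples, standard = default_standards()$china,
                           pefs = default_pef_table(),
                           nd_policy = c("zero", "half_dl", "dl"),
                           detection_limits = default_detection_limits()) {
  nd_policy <- match.arg(nd_policy)
  stopifnot(inherits(standard, "water_standard") || is.list(standard))
  defined <- intersect(c("bap_ng_l", "total_ng_l", "bapeq_ng_l"),
                       names(standard))
  if (length(defined) == 0) stop("standard defines no limit", call. = FALSE)
  out <- samples
  if ("bap_ng_l" %in% defined) {
    sample_analytes(samples, required = "BaP")
    bap <- resolve_conc(samples$BaP_ng_l, samples$BaP_nd, nd_policy,
                        detection_limits[["BaP"]])
    out$exceeds_bap <- bap > standard$bap_ng_l
  }
  if ("total_ng_l" %in% defined) {
    out$exceeds_total <- total_pahs(samples, nd_policy, detection_limits) >
      standard$total_ng_l
  }
  if ("bapeq_ng_l" %in% defined) {
    out$exceeds_bapeq <- bapeq_concentration(samples, pefs, nd_policy,
                                             detection_limits) >
      standard$bapeq_ng_l
  }
  out
}
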