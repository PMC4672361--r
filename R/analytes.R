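#' The 16 US-EPA priority PAH analytes
#'
#' Standard abbreviations, in conventional elution order: naphthalene (Nap)
#' through benzo\[g,h,i\]perylene (BghiP). All concentration tables in this
#' package are keyed by these names, in ng/L.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' pah_analytes()
pah_analytes <- function() {
  c("Nap", "Acy", "Ace", "Fl", "Phe", "Ant", "Flu", "Pyr",
    "BaA", "Chy", "BaP", "BbF", "BkF", "DahA", "IcdP", "BghiP")
}

#' Potency equivalency factors (PEFs) relative to benzo\[a\]pyrene
#'
#' The default table carries the US EPA (1993) relative potencies for the
#' seven carcinogenic PAHs (BaA 0.1, Chy 0.001, BaP 1, BbF 0.1, BkF 0.01,
#' DahA 1, IcdP 0.1). Analytes outside the carcinogenic set have no PEF and
#' do not contribute to BaPeq.
#'
#' @param pef Named numeric vector of potency factors; names must be PAH
#'   abbreviations, values in (0, 1], and `pef["BaP"]` must be exactly 1.
#' @return An object of class `pef_table`: a named numeric vector whose names
#'   define the carcinogenic set.
#' @export
#' @examples
#' default_pef_table()
default_pef_table <- function(pef = c(BaA = 0.1, Chy = 0.001, BaP = 1,
                                      BbF = 0.1, BkF = 0.01, DahA = 1,
                                      IcdP = 0.1)) {
  if (is.null(names(pef)) || any(names(pef) == "")) {
    stop("PEF table must be a named vector of analyte => factor", call. = FALSE)
  }
  unknown <- setdiff(names(pef), pah_analytes())
  if (length(unknown) > 0) {
    stop("Unknown analyte(s) in PEF table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"BaP" %in% names(pef) || pef[["BaP"]] != 1) {
    stop("PEF table must contain BaP with PEF exactly 1", call. = FALSE)
  }
  if (any(pef <= 0) || any(pef > 1)) {
    stop("All PEFs must lie in (0, 1]", call. = FALSE)
  }
  structure(pef, class = "pef_table")
}

#' Carcinogenic analyte set of a PEF table
#' @param pefs A `pef_table`.
#' @return Character vector of analyte names carrying a PEF.
#' @export
carcinogenic_set <- function(pefs = default_pef_table()) names(pefs)

#' Default analytical detection limits
#'
#' Per-analyte method detection limits in ng/L, all within the 1-5 ng/L
#' range typical of SPE + GC/MS determination of PAHs in water. Naphthalene,
#' whose ambient levels are orders of magnitude above the limit, and the
#' late-eluting dibenz\[a,h\]anthracene carry the 5 ng/L end of the range.
#'
#' @return Named numeric vector (ng/L) over all 16 analytes.
#' @export
default_detection_limits <- function() {
  dl <- stats::setNames(rep(1, 16), pah_analytes())
  dl[c("Nap", "DahA")] <- 5
  dl
}

#' Drinking-water standards for PAH screening
#'
#' A named list of screening standards. Each standard may define a BaP limit
#' (`bap_ng_l`), a total-PAH limit (`total_ng_l`) and/or a BaPeq limit
#' (`bapeq_ng_l`), all in ng/L. Defaults:
#' * `china` — BaP 10 ng/L (also applied to BaPeq) and total PAHs 2000 ng/L;
#' * `us` — BaP 200 ng/L;
#' * `egypt` — BaP 700 ng/L.
#'
#' Exceedance is strict (`>`): a value equal to the limit is compliant.
#'
#' @return Named list of standards, each a list with class `water_standard`.
#' @export
#' @examples
#' default_standards()$china
default_standards <- function() {
  std <- function(name, bap_ng_l = NULL, total_ng_l = NULL, bapeq_ng_l = NULL) {
    lims <- list(bap_ng_l = bap_ng_l, total_ng_l = total_ng_l,
                 bapeq_ng_l = bapeq_ng_l)
    lims <- lims[!vapply(lims, is.null, logical(1))]
    if (length(lims) == 0) stop("standard '", name, "' defines no limit",
                                call. = FALSE)
    if (any(unlist(lims) <= 0)) stop("limits must be positive", call. = FALSE)
    structure(c(list(name = name), lims), class = "water_standard")
  }
  list(
    china = std("china", bap_ng_l = 10, total_ng_l = 2000, bapeq_ng_l = 10),
    us    = std("us", bap_ng_l = 200),
    egypt = std("egypt", bap_ng_l = 700)
  )
}
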