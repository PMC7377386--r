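#' Published stratified sepsis counts and decision-tree inputs
#'
#' Stratified estimates from a large UK primary-care cohort (CPRD GOLD,
#' 2002-2017; 706 practices, 66.2 million person-years, 35,244 first sepsis
#' events): per gender and age band, the number of first sepsis events, how
#' many were preceded by an infection consultation in the previous 30 days,
#' how many of those consultations carried a same-date antibiotic
#' prescription, and the five decision-tree input probabilities together with
#' the derived sepsis probabilities and NNT (with 95% uncertainty interval).
#'
#' These values serve two purposes: they are the default calibration targets
#' of the synthetic cohort generator ([sim_config()]), and they provide a
#' worked example for the deterministic decision-tree chain.
#'
#' @return A tibble with one row per gender x age band:
#' \describe{
#'   \item{gender}{"male" or "female".}
#'   \item{age_band}{Age band label (see [age_breaks_sepsis()]).}
#'   \item{sepsis_events}{First sepsis events recorded in the stratum.}
#'   \item{prior_infection_30d}{Events preceded by an infection consultation
#'     within the 30-day look-back window.}
#'   \item{same_date_ab}{Of those, consultations with a same-date antibiotic
#'     prescription.}
#'   \item{p_infection}{P(Infection): probability of an infection consultation
#'     in a 30-day period.}
#'   \item{p_sepsis}{P(Sepsis): probability of a first sepsis event in a
#'     30-day period.}
#'   \item{p_inf_given_sepsis}{P(Infection | Sepsis), as printed (2 dp).}
#'   \item{p_ab_given_infection}{P(AB | Infection).}
#'   \item{p_sepsis_no_ab, p_sepsis_ab}{Derived probability of sepsis after an
#'     infection consultation without/with antibiotics.}
#'   \item{nnt, nnt_lower, nnt_upper}{Number needed to treat with 95%
#'     uncertainty interval.}
#' }
#' @examples
#' uk_sepsis_strata()
#' @export
uk_sepsis_strata <- function() {
  path <- system.file("extdata", "uk_sepsis_strata.tsv", package = "sepsisnnt",
                      mustWork = TRUE)
  read_tsv(path, col_types = readr::cols(
    gender = "c", age_band = "c",
    .default = readr::col_double()
  ))
}
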