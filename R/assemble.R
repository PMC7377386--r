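# Bridges the cohort and sampling outputs into decision-tree inputs, and a
# one-call pipeline for simulated or user-supplied event tables.

#' Assemble probability sets from stratum counts and rate estimates
#'
#' Joins the population-side sufficient statistics
#' ([tabulate_strata()]: sepsis counts, look-back linkage counts,
#' person-years) with the sample-side estimates ([estimate_rates()]:
#' consultation rate, prescribing proportion) into one
#' [probability_set()] row per stratum, carrying the underlying counts so
#' that beta draws are possible:
#' * `P(Sepsis)`: `n_sepsis` of `person_years x 365.25 / 30` 30-day units;
#' * `P(Infection|Sepsis)`: `n_prior_infection` of `n_sepsis`;
#' * `P([AB|Inf]|Sepsis)`: `n_same_date_ab` of `n_prior_infection`;
#' * `P(Infection)`: sampled consultations of sampled 30-day units;
#' * `P(AB|Infection)`: same-day-antibiotic consultations of consultations.
#'
#' @param stratum_counts A [tabulate_strata()] result.
#' @param rates A [estimate_rates()] result; its `"all"` rows are used unless
#'   `infection` is a stratum column on both sides.
#' @return A `probability_sets` tibble with the stratum identifier columns.
#' @export
assemble_probability_sets <- function(stratum_counts, rates) {
  required_cols(stratum_counts, c("n_sepsis", "n_prior_infection",
                                  "n_same_date_ab", "person_years"),
                "stratum_counts")
  by_infection <- "infection" %in% names(stratum_counts)
  r <- if (by_infection) {
    rates |> filter(.data$infection != "all")
  } else {
    rates |> filter(.data$infection == "all") |> select(-"infection")
  }
  join_cols <- intersect(
    c("gender", "age_band", "period", "infection"),
    intersect(names(stratum_counts), names(r))
  )
  joined <- stratum_counts |>
    mutate(age_band = as.character(.data$age_band)) |>
    inner_join(r |> mutate(age_band = as.character(.data$age_band)),
               by = join_cols) |>
    filter(!.data$undefined, .data$events > 0, .data$n_sepsis > 0,
           .data$n_prior_infection > 0)

  ids <- joined |> select(all_of(setdiff(
    c("gender", "age_band", "period", "infection"), character()
  ) |> intersect(names(joined))))

  ps <- probability_set(counts = list(
    infection = cbind(joined$events, joined$person_time_30d),
    sepsis = cbind(joined$n_sepsis, joined$person_years * 365.25 / 30),
    inf_given_sepsis = cbind(joined$n_prior_infection, joined$n_sepsis),
    ab_given_infection = cbind(joined$ab_numerator, joined$ab_denominator),
    ab_given_inf_sepsis = cbind(joined$n_same_date_ab,
                                joined$n_prior_infection)
  ))
  out <- dplyr::bind_cols(ids, ps)
  n_dropped <- nrow(stratum_counts) - nrow(out)
  if (n_dropped > 0) {
    warn(sprintf(
      "%d stratum/strata dropped: no sampled person-time, consultations, sepsis events, or linked cases.",
      n_dropped
    ))
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("probability_sets", class(out))
  out
}

#' Full pipeline: event tables to stratified risk estimates
#'
#' Convenience wrapper running follow-up computation, incident ascertainment,
#' look-back linkage, stratum tabulation, the sampling design, rate
#' estimation, and the Monte Carlo decision tree.
#'
#' @param cohort An `ehr_cohort` from [simulate_cohort()], or a list with
#'   `patients`, `clinical_events`, `prescriptions`.
#' @param study_start,study_end Study window; default 2002-2017.
#' @param window_days Look-back window (30 or 60).
#' @param age_breaks Analysis age bands.
#' @param by Stratification passed to [tabulate_strata()].
#' @param per_stratum_n Patients per sampling stratum ([draw_sample()]).
#' @param n_draws,prior Monte Carlo settings ([draw_uncertainty()]).
#' @param seed Seed governing the sample draw and the beta draws.
#' @return A `sepsis_risk_tbl` (see [estimate_all_strata()]).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_patients = 2000, rng_seed = 7)
#' cohort <- simulate_cohort(cfg)
#' est <- estimate_sepsis_risk(cohort, n_draws = 500, seed = 7)
#' }
#' @export
estimate_sepsis_risk <- function(cohort,
                                 study_start = as.Date("2002-01-01"),
                                 study_end = as.Date("2017-12-31"),
                                 window_days = 30,
                                 age_breaks = age_breaks_sepsis(),
                                 by = c("gender", "age_band"),
                                 per_stratum_n = 10,
                                 n_draws = 10000,
                                 prior = "jeffreys",
                                 seed = NULL) {
  with_seed_maybe(seed, {
    fu <- compute_follow_up(cohort$patients, study_start, study_end)
    cases <- ascertain_incident_sepsis(cohort$clinical_events, fu) |>
      link_lookback(cohort$clinical_events, cohort$prescriptions,
                    window_days = window_days)
    counts <- tabulate_strata(cases, fu, cohort$patients,
                              age_breaks = age_breaks, by = by)
    smp <- draw_sample(cohort$patients,
                       years = seq(year(study_start), year(study_end)),
                       per_stratum_n = per_stratum_n)
    rates <- estimate_rates(smp, cohort$clinical_events, cohort$prescriptions,
                            fu, cohort$patients, age_breaks = age_breaks,
                            by_infection = "infection" %in% by)
    prob <- assemble_probability_sets(counts, rates)
    estimate_all_strata(prob, n_draws = n_draws, seed = NULL, prior = prior)
  })
}
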