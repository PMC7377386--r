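# Fixtures are built in code: no data files.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# Uniform generator parameters across every analysis stratum: used where the
# test needs a single known hazard structure rather than the published
# calibration.
uniform_params <- function(rate_30d, ab_prob, hazard_30d, mult_no_ab,
                           mult_ab) {
  tidyr::crossing(
    gender = c("male", "female"),
    age_band = c("0-4", "5-14", "15-24", "25-34", "35-44", "45-54",
                 "55-64", "65-74", "75-84", "85+")
  ) |>
    mutate(rate_30d = rate_30d, ab_prob = ab_prob, hazard_30d = hazard_30d,
           mult_no_ab = mult_no_ab, mult_ab = mult_ab)
}

# Patients registered long before the study so follow-up covers the window.
simple_patients <- function(n, gender = "male", birth = as.Date("1950-06-15"),
                            reg = as.Date("1990-01-01"),
                            reg_end = as.Date("2017-12-31"),
                            id_offset = 0L) {
  tibble(
    patient_id = id_offset + seq_len(n),
    practice_id = 1L,
    gender = gender,
    birth_date = as.Date(birth),
    registration_start = as.Date(reg),
    up_to_standard_date = as.Date(reg),
    registration_end = as.Date(reg_end),
    death_date = as.Date(NA)
  )
}

# Encode stratum-level counts (sepsis events, look-back-linked cases,
# same-date antibiotic cases) as explicit patient/event/prescription tables.
# Every case gets sepsis on the same index date; linked cases get one
# consultation 10 days earlier; same-date-AB cases additionally get a
# prescription on the consultation date.
count_fixture <- function(strata,
                          index_date = as.Date("2010-06-15")) {
  pid0 <- 0L
  parts <- purrr::pmap(strata, function(gender, birth_date, n_sepsis,
                                        n_linked, n_ab, ...) {
    pats <- simple_patients(n_sepsis, gender = gender,
                            birth = as.Date(birth_date),
                            reg = max(as.Date(birth_date),
                                      as.Date("1990-01-01")),
                            id_offset = pid0)
    ids <- pats$patient_id
    events <- bind_rows(
      tibble(patient_id = ids, event_date = index_date,
             category = "sepsis", code = "SEPS001"),
      tibble(patient_id = ids[seq_len(n_linked)],
             event_date = index_date - 10,
             category = "rti", code = "RTI001")
    ) |> mutate(source = "primary_care")
    rx <- tibble(patient_id = ids[seq_len(n_ab)],
                 prescription_date = index_date - 10,
                 product_class = "antibiotic")
    pid0 <<- pid0 + n_sepsis
    list(patients = pats, events = events, rx = rx)
  })
  list(
    patients = purrr::list_rbind(purrr::map(parts, "patients")),
    events = purrr::list_rbind(purrr::map(parts, "events")),
    prescriptions = purrr::list_rbind(purrr::map(parts, "rx"))
  )
}

# Probability sets for the published strata, with beta-draw counts. The
# population-side counts are published; the sample-side denominators are not,
# so synthetic sample sizes reflecting the design's order of magnitude are
# used (documented in the methods vignette).
published_prob_sets <- function(sampled_units = 2e5) {
  d <- uk_sepsis_strata()
  ids <- d |> select(gender, age_band)
  ps <- probability_set(
    p_infection = d$p_infection,
    p_ab_given_infection = d$p_ab_given_infection,
    counts = list(
      infection = cbind(round(d$p_infection * sampled_units), sampled_units),
      sepsis = cbind(d$sepsis_events, d$sepsis_events / d$p_sepsis),
      inf_given_sepsis = cbind(d$prior_infection_30d, d$sepsis_events),
      ab_given_infection = cbind(
        round(d$p_ab_given_infection * d$p_infection * sampled_units),
        round(d$p_infection * sampled_units)
      ),
      ab_given_inf_sepsis = cbind(d$same_date_ab, d$prior_infection_30d)
    )
  )
  out <- bind_cols(ids, ps)
  class(out) <- c("probability_sets", class(out))
  out
}

# Pool a cohort's extraction into one global probability set with counts,
# running every pipeline stage (follow-up, ascertainment, linkage, sampling,
# rate estimation) and summing the sufficient statistics across strata.
pooled_pipeline_counts <- function(cohort, study_start, study_end,
                                   per_stratum_n = 10, window_days = 30,
                                   sample_seed = 1) {
  fu <- compute_follow_up(cohort$patients, study_start, study_end)
  cases <- ascertain_incident_sepsis(cohort$clinical_events, fu) |>
    link_lookback(cohort$clinical_events, cohort$prescriptions,
                  window_days = window_days)
  smp <- draw_sample(cohort$patients,
                     years = seq(lubridate::year(study_start),
                                 lubridate::year(study_end)),
                     per_stratum_n = per_stratum_n, seed = sample_seed)
  rates <- suppressWarnings(
    estimate_rates(smp, cohort$clinical_events, cohort$prescriptions, fu,
                   cohort$patients)
  ) |> filter(infection == "all")
  probability_set(counts = list(
    infection = c(sum(rates$events), sum(rates$person_time_30d)),
    sepsis = c(nrow(cases), sum(fu$person_years) * 365.25 / 30),
    inf_given_sepsis = c(sum(cases$linked), nrow(cases)),
    ab_given_infection = c(sum(rates$ab_numerator),
                           sum(rates$ab_denominator)),
    ab_given_inf_sepsis = c(sum(cases$linked & cases$ab_same_date,
                                na.rm = TRUE),
                            sum(cases$linked))
  ))
}

# One moderate cohort shared by several test files (memoised).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_patients = 4000,
        params = uniform_params(0.06, 0.55, 0.002, 6, 2),
        rng_seed = 101
      )
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
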