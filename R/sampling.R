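# Stratified random-sample design for consultation-rate and prescribing
# estimation: in each study year, a fixed number of patients per family
# practice, gender and five-year age band is drawn without replacement from
# all patients registered in that year. Each sampled patient-year contributes
# its follow-up days within that calendar year.

#' Draw the stratified patient sample
#'
#' @param patients Patient table with `patient_id`, `practice_id`, `gender`,
#'   `birth_date`, `registration_start`, `registration_end`.
#' @param years Study years to sample in.
#' @param per_stratum_n Patients drawn per year x practice x gender x
#'   five-year band stratum (draws `min(per_stratum_n, stratum size)`).
#' @param sample_age_breaks Age bands of the sampling frame; ages above the
#'   top finite band are clamped into it.
#' @param seed Optional seed for reproducible draws.
#' @return Tibble `year`, `practice_id`, `gender`, `sample_band`,
#'   `patient_id`.
#' @export
draw_sample <- function(patients, years, per_stratum_n = 10,
                        sample_age_breaks = age_breaks_five_year(),
                        seed = NULL) {
  required_cols(patients, c("patient_id", "practice_id", "gender",
                            "birth_date", "registration_start",
                            "registration_end"), "patients")
  if (per_stratum_n < 1) {
    abort("`per_stratum_n` must be at least 1.",
          class = "sepsisnnt_config_error")
  }
  max_age <- max(sample_age_breaks[is.finite(sample_age_breaks)])

  frame <- crossing(year = as.integer(years),
                    patients |> select("patient_id", "practice_id", "gender",
                                       "birth_date", "registration_start",
                                       "registration_end")) |>
    filter(.data$registration_start <= year_end(.data$year),
           .data$registration_end >= year_start(.data$year)) |>
    mutate(
      age = pmin(age_at_year_start(.data$birth_date, .data$year), max_age),
      sample_band = assign_age_band(.data$age, sample_age_breaks)
    )

  # Uniform without-replacement draw per stratum, vectorised: order each
  # stratum by an independent uniform key and keep the first n rows.
  with_seed_maybe(seed, {
    frame$.u <- runif(nrow(frame))
    frame <- frame |>
      arrange(.data$year, .data$practice_id, .data$gender,
              .data$sample_band, .data$.u)
    gid <- paste(frame$year, frame$practice_id, frame$gender,
                 frame$sample_band)
    pos <- sequence(rle(gid)$lengths)
    frame[pos <= per_stratum_n,
          c("year", "practice_id", "gender", "sample_band", "patient_id")]
  })
}

#' Estimate consultation rates and prescribing proportions from the sample
#'
#' For each sampled patient-year, person-time is the overlap of the patient's
#' follow-up with that calendar year; consultations are the patient's
#' infection-coded events in that overlap, and a consultation counts as
#' antibiotic-treated when a prescription shares its date. Counts and
#' person-time are pooled within gender x analysis age band (x infection
#' type), and the probability of an infection consultation per 30 days is the
#' pooled rate times 30 days (a close approximation at these rates).
#'
#' @param sample_draw Output of [draw_sample()].
#' @param events Clinical events.
#' @param prescriptions Prescription table.
#' @param follow_up Output of [compute_follow_up()].
#' @param patients Patient table (for gender and birth dates).
#' @param age_breaks Analysis age bands for the estimates.
#' @param by_infection Also return per-infection-type rows (in addition to
#'   the `"all"` rows)?
#' @return Tibble of class `rate_estimates`: `gender`, `age_band`,
#'   `infection` (`"all"` plus types), `events`, `person_time_30d` (number of
#'   30-day units), `rate_per_30d`, `ab_numerator`, `ab_denominator`,
#'   `ab_proportion`, `undefined` (TRUE when the stratum has no person-time;
#'   such rates are NA, never silently zero).
#' @export
estimate_rates <- function(sample_draw, events, prescriptions, follow_up,
                           patients, age_breaks = age_breaks_sepsis(),
                           by_infection = TRUE) {
  required_cols(sample_draw, c("year", "patient_id"), "sample_draw")

  fu_years <- expand_follow_up_years(follow_up)
  sampled_py <- sample_draw |>
    select("year", "patient_id") |>
    left_join(fu_years, by = c("year", "patient_id")) |>
    left_join(select(patients, "patient_id", "gender", "birth_date"),
              by = "patient_id") |>
    mutate(
      days = dplyr::coalesce(.data$days, 0L),
      age_band = assign_age_band(
        age_at_year_start(.data$birth_date, .data$year), age_breaks
      )
    )

  pt <- sampled_py |>
    group_by(.data$gender, .data$age_band) |>
    summarise(person_time_30d = sum(.data$days) / 30, .groups = "drop")

  rx <- distinct(prescriptions, .data$patient_id, .data$prescription_date)
  consults <- sampled_py |>
    filter(.data$days > 0) |>
    inner_join(
      events |>
        filter(.data$category %in% infection_categories()) |>
        mutate(year = year(.data$event_date)),
      by = c("patient_id", "year"), relationship = "many-to-many"
    ) |>
    filter(.data$event_date >= .data$seg_start,
           .data$event_date <= .data$seg_end) |>
    left_join(rx |> mutate(ab = TRUE),
              by = c("patient_id", event_date = "prescription_date")) |>
    mutate(ab = dplyr::coalesce(.data$ab, FALSE))

  count_by <- function(d, label) {
    d |>
      group_by(.data$gender, .data$age_band) |>
      summarise(events = n(), ab_numerator = sum(.data$ab),
                .groups = "drop") |>
      mutate(infection = label)
  }
  counts <- count_by(consults, "all")
  if (by_infection) {
    per_type <- consults |>
      group_by(.data$gender, .data$age_band, .data$category) |>
      summarise(events = n(), ab_numerator = sum(.data$ab),
                .groups = "drop") |>
      rename(infection = "category")
    counts <- bind_rows(counts, per_type)
  }

  grid <- crossing(
    pt,
    infection = if (by_infection) c("all", infection_categories()) else "all"
  )
  out <- grid |>
    left_join(counts, by = c("gender", "age_band", "infection")) |>
    mutate(
      events = dplyr::coalesce(.data$events, 0L),
      ab_numerator = dplyr::coalesce(.data$ab_numerator, 0L),
      undefined = .data$person_time_30d <= 0,
      rate_per_30d = dplyr::if_else(.data$undefined, NA_real_,
                                    .data$events / .data$person_time_30d),
      ab_denominator = .data$events,
      ab_proportion = dplyr::if_else(.data$events > 0,
                                     .data$ab_numerator / .data$events,
                                     NA_real_)
    ) |>
    select("gender", "age_band", "infection", "events", "person_time_30d",
           "rate_per_30d", "ab_numerator", "ab_denominator", "ab_proportion",
           "undefined") |>
    arrange(.data$gender, .data$age_band, .data$infection)
  if (any(out$undefined)) {
    warn("Some strata have zero sampled person-time; their rates are NA.")
  }
  class(out) <- c("rate_estimates", class(out))
  out
}

#' Age-standardised aggregate rates
#'
#' Combines band-specific rates into a single standardised rate per gender
#' (and infection type) using equal band weights by default, or external
#' weights.
#'
#' @param rates A [estimate_rates()] result.
#' @param weights Optional tibble `age_band`, `weight`; equal weights when
#'   NULL.
#' @return Tibble `gender`, `infection`, `std_rate_per_30d`,
#'   `std_ab_proportion`.
#' @export
standardize_rates <- function(rates, weights = NULL) {
  r <- rates |> filter(!.data$undefined)
  if (is.null(weights)) {
    weights <- r |> distinct(.data$age_band) |> mutate(weight = 1)
  }
  r |>
    inner_join(weights, by = "age_band") |>
    group_by(.data$gender, .data$infection) |>
    summarise(
      std_rate_per_30d = sum(.data$rate_per_30d * .data$weight) /
        sum(.data$weight),
      std_ab_proportion = sum(.data$ab_proportion * .data$weight,
                              na.rm = TRUE) / sum(.data$weight),
      .groups = "drop"
    )
}
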