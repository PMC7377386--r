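# Incident sepsis ascertainment, person-time, and look-back exposure
# classification.
#
# Follow-up convention: a patient is at risk from the latest of (registration
# start + 1 year, the practice's up-to-standard date, study start) to the
# earliest of (registration end, death, study end); person-years use the
# inclusive-day convention (end - start + 1)/365.25.
#
# Look-back convention: a consultation "precedes" a sepsis event when it falls
# strictly inside the open interval (sepsis - window, sepsis): a consultation
# on the sepsis date itself, or exactly `window_days` before, does not
# qualify. When several consultations qualify, the most recent one defines
# the exposure (infection type and same-date antibiotic status).

#' Compute follow-up intervals
#'
#' @param patients Tibble with `patient_id`, `registration_start`,
#'   `up_to_standard_date`, `registration_end`, `death_date` (NA allowed).
#' @param study_start,study_end Study window (Dates).
#' @return Tibble `patient_id`, `start_date`, `end_date`, `person_years`.
#'   Patients whose interval is empty are returned with zero person-years,
#'   not dropped.
#' @examples
#' pats <- tibble::tibble(
#'   patient_id = 1L,
#'   registration_start = as.Date("2000-01-01"),
#'   up_to_standard_date = as.Date("1999-01-01"),
#'   registration_end = as.Date("2020-01-01"),
#'   death_date = as.Date(NA)
#' )
#' compute_follow_up(pats, as.Date("2002-01-01"), as.Date("2017-12-31"))
#' @export
compute_follow_up <- function(patients, study_start, study_end) {
  required_cols(patients, c("patient_id", "registration_start",
                            "up_to_standard_date", "registration_end"),
                "patients")
  assert_scalar_date(study_start, "study_start")
  assert_scalar_date(study_end, "study_end")
  if (!"death_date" %in% names(patients)) {
    patients$death_date <- as.Date(NA)
  }
  if (any(patients$registration_end < patients$registration_start,
          na.rm = TRUE)) {
    abort("Found registration_end earlier than registration_start.",
          class = "sepsisnnt_data_error")
  }
  patients |>
    mutate(
      start_date = pmax(.data$registration_start %m+% years(1),
                        .data$up_to_standard_date, study_start),
      end_date = pmin(.data$registration_end,
                      dplyr::coalesce(.data$death_date, study_end),
                      study_end),
      person_years = pmax(
        0, as.numeric(.data$end_date - .data$start_date) + 1
      ) / 365.25
    ) |>
    select("patient_id", "start_date", "end_date", "person_years")
}

# Expand follow-up into per-calendar-year segments (only rows with positive
# time). Used for stratified person-years and for the sampling estimator.
expand_follow_up_years <- function(follow_up) {
  fu <- follow_up |> filter(.data$person_years > 0)
  if (nrow(fu) == 0L) {
    return(tibble(patient_id = integer(), year = integer(),
                  seg_start = as.Date(character()),
                  seg_end = as.Date(character()), days = integer()))
  }
  y0 <- year(fu$start_date)
  y1 <- year(fu$end_date)
  reps <- y1 - y0 + 1L
  idx <- rep.int(seq_len(nrow(fu)), reps)
  out <- fu[idx, c("patient_id", "start_date", "end_date")]
  out$year <- y0[idx] + sequence(reps) - 1L
  out |>
    mutate(
      seg_start = pmax(.data$start_date, year_start(.data$year)),
      seg_end = pmin(.data$end_date, year_end(.data$year)),
      days = as.integer(.data$seg_end - .data$seg_start) + 1L
    ) |>
    select("patient_id", "year", "seg_start", "seg_end", "days")
}

#' Person-years split by stratum
#'
#' Splits each patient's follow-up at calendar-year boundaries (ages fixed at
#' each year start) and sums person-years by gender and age band, optionally
#' by calendar period. The split conserves total person-years exactly.
#'
#' @param follow_up Output of [compute_follow_up()].
#' @param patients Patient table with `patient_id`, `gender`, `birth_date`.
#' @param age_breaks Analysis age bands.
#' @param period_breaks Optional increasing integer years defining calendar
#'   periods (e.g. `c(2002, 2006, 2010, 2014, 2018)`).
#' @return Tibble `gender`, `age_band` (, `period`), `person_years`.
#' @export
split_person_years <- function(follow_up, patients,
                               age_breaks = age_breaks_sepsis(),
                               period_breaks = NULL) {
  required_cols(patients, c("patient_id", "gender", "birth_date"), "patients")
  seg <- expand_follow_up_years(follow_up) |>
    left_join(select(patients, "patient_id", "gender", "birth_date"),
              by = "patient_id") |>
    mutate(
      age_band = assign_age_band(
        age_at_year_start(.data$birth_date, .data$year), age_breaks
      )
    )
  grp <- c("gender", "age_band")
  if (!is.null(period_breaks)) {
    seg <- seg |> mutate(period = assign_period(.data$year, period_breaks))
    grp <- c(grp, "period")
  }
  seg |>
    group_by(across(all_of(grp))) |>
    summarise(person_years = sum(.data$days) / 365.25, .groups = "drop")
}

assign_period <- function(yr, period_breaks) {
  if (any(diff(period_breaks) <= 0)) {
    abort("`period_breaks` must be strictly increasing.",
          class = "sepsisnnt_config_error")
  }
  lab <- paste0(period_breaks[-length(period_breaks)], "-",
                period_breaks[-1] - 1)
  cut(yr, breaks = period_breaks, labels = lab, right = FALSE)
}

#' Ascertain incident first sepsis events
#'
#' Keeps, per patient, the chronologically first sepsis-coded event that falls
#' inside the patient's follow-up interval. Events outside follow-up are
#' ignored entirely: by default an earlier out-of-interval event does not
#' suppress a later in-interval one (set `suppress_prevalent = TRUE` to treat
#' patients with any sepsis code before follow-up start as prevalent and
#' exclude them).
#'
#' @param events Clinical-event tibble with `patient_id`, `event_date`,
#'   `category`.
#' @param follow_up Output of [compute_follow_up()].
#' @param suppress_prevalent Exclude patients with a sepsis code before
#'   follow-up start?
#' @return Tibble `patient_id`, `sepsis_date`.
#' @export
ascertain_incident_sepsis <- function(events, follow_up,
                                      suppress_prevalent = FALSE) {
  required_cols(events, c("patient_id", "event_date", "category"), "events")
  sep <- events |>
    filter(.data$category == "sepsis") |>
    inner_join(select(follow_up, "patient_id", "start_date", "end_date",
                      "person_years"),
               by = "patient_id")
  if (suppress_prevalent) {
    prevalent <- sep |>
      filter(.data$event_date < .data$start_date) |>
      distinct(.data$patient_id)
    sep <- anti_join(sep, prevalent, by = "patient_id")
  }
  sep |>
    filter(.data$person_years > 0,
           .data$event_date >= .data$start_date,
           .data$event_date <= .data$end_date) |>
    group_by(.data$patient_id) |>
    slice_min(.data$event_date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", sepsis_date = "event_date")
}

#' Merge sepsis event sources
#'
#' Per-patient union of sepsis-coded events across primary-care, hospital and
#' mortality streams; same-day multi-source records are deduplicated, keeping
#' the source with highest precedence (primary care, then hospital, then
#' mortality). The first event across sources then defines the incident date
#' downstream.
#'
#' @param primary,hospital,mortality Event tibbles sharing the clinical-event
#'   schema; `hospital` and `mortality` may be NULL. Missing `source` columns
#'   are filled with the stream name.
#' @return A unified event tibble.
#' @export
merge_event_sources <- function(primary, hospital = NULL, mortality = NULL) {
  label <- function(x, src) {
    if (is.null(x)) return(NULL)
    required_cols(x, c("patient_id", "event_date", "category"), src)
    if (!"source" %in% names(x)) x$source <- src
    x
  }
  bind_rows(label(primary, "primary_care"),
            label(hospital, "hospital"),
            label(mortality, "mortality")) |>
    mutate(.src_rank = match(.data$source,
                             c("primary_care", "hospital", "mortality"))) |>
    arrange(.data$patient_id, .data$event_date, .data$category,
            .data$.src_rank) |>
    distinct(.data$patient_id, .data$event_date, .data$category,
             .keep_all = TRUE) |>
    select(-".src_rank")
}

#' Link sepsis cases to preceding infection consultations
#'
#' For each case, finds the most recent infection consultation strictly inside
#' the open look-back window (see the conventions above) and records whether
#' an antibiotic prescription shares that consultation's date
#' (`ab_same_date`), as well as the number of distinct prescription dates
#' anywhere in the window (`n_ab_window`; recorded but not used for the
#' same-date exposure definition).
#'
#' @param cases Tibble with `patient_id`, `sepsis_date` (other columns kept).
#' @param events Clinical events; rows with `category` in rti/skin/uti are the
#'   consultations searched.
#' @param prescriptions Tibble `patient_id`, `prescription_date`.
#' @param window_days Look-back window width in days (30 by default; 60 for
#'   the sensitivity analysis).
#' @return `cases` with `linked`, `consultation_date`, `infection_type`,
#'   `ab_same_date` (NA when unlinked) and `n_ab_window` appended.
#' @export
link_lookback <- function(cases, events, prescriptions, window_days = 30) {
  required_cols(cases, c("patient_id", "sepsis_date"), "cases")
  required_cols(prescriptions, c("patient_id", "prescription_date"),
                "prescriptions")
  if (!is.numeric(window_days) || length(window_days) != 1 || window_days < 2) {
    abort("`window_days` must be a single number >= 2.",
          class = "sepsisnnt_config_error")
  }
  consults <- events |>
    filter(.data$category %in% infection_categories()) |>
    select("patient_id", consultation_date = "event_date",
           infection_type = "category")
  rx <- distinct(prescriptions, .data$patient_id, .data$prescription_date)

  in_window <- cases |>
    select("patient_id", "sepsis_date") |>
    inner_join(consults, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$consultation_date > .data$sepsis_date - window_days,
           .data$consultation_date < .data$sepsis_date)

  # Most recent consultation wins; on a same-day tie the higher-risk type
  # (uti > skin > rti) is taken for determinism.
  linked <- in_window |>
    mutate(.type_rank = match(.data$infection_type,
                              c("uti", "skin", "rti"))) |>
    group_by(.data$patient_id, .data$sepsis_date) |>
    arrange(dplyr::desc(.data$consultation_date), .data$.type_rank,
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(-".type_rank") |>
    left_join(rx |> mutate(ab_same_date = TRUE),
              by = c("patient_id", consultation_date = "prescription_date")) |>
    mutate(ab_same_date = dplyr::coalesce(.data$ab_same_date, FALSE))

  ab_counts <- cases |>
    select("patient_id", "sepsis_date") |>
    inner_join(rx, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$prescription_date > .data$sepsis_date - window_days,
           .data$prescription_date < .data$sepsis_date) |>
    count(.data$patient_id, .data$sepsis_date, name = "n_ab_window")

  cases |>
    left_join(linked, by = c("patient_id", "sepsis_date")) |>
    left_join(ab_counts, by = c("patient_id", "sepsis_date")) |>
    mutate(
      linked = !is.na(.data$consultation_date),
      n_ab_window = dplyr::coalesce(.data$n_ab_window, 0L)
    )
}

#' Tabulate stratum counts
#'
#' Produces, per stratum, the sufficient statistics of the decision tree's
#' population side: number of first sepsis events, number preceded by an
#' infection consultation, number of those with a same-date antibiotic, and
#' the person-years at risk.
#'
#' Strata are the cross of `gender` and `age_band`, optionally extended with
#' `period` (via `period_breaks`) and `infection` (type of the linked
#' consultation; `n_sepsis` and `person_years` then repeat the enclosing
#' gender/age(/period) totals, since the denominators are not type-specific).
#'
#' @param cases Linked cases from [link_lookback()].
#' @param follow_up Output of [compute_follow_up()].
#' @param patients Patient table (`patient_id`, `gender`, `birth_date`).
#' @param age_breaks Analysis age bands.
#' @param by Stratification variables; subset of
#'   `c("gender", "age_band", "period", "infection")`.
#' @param period_breaks Required when `"period"` is in `by`.
#' @return Tibble of class `stratum_counts`.
#' @export
tabulate_strata <- function(cases, follow_up, patients,
                            age_breaks = age_breaks_sepsis(),
                            by = c("gender", "age_band"),
                            period_breaks = NULL) {
  required_cols(cases, c("patient_id", "sepsis_date", "linked",
                         "ab_same_date"), "cases")
  required_cols(patients, c("patient_id", "gender", "birth_date"), "patients")
  allowed <- c("gender", "age_band", "period", "infection")
  if (!all(by %in% allowed)) {
    abort(sprintf("`by` may only contain: %s", paste(allowed, collapse = ", ")),
          class = "sepsisnnt_config_error")
  }
  if ("period" %in% by && is.null(period_breaks)) {
    abort("`period_breaks` is required when stratifying by period.",
          class = "sepsisnnt_config_error")
  }

  cc <- cases |>
    left_join(select(patients, "patient_id", "gender", "birth_date"),
              by = "patient_id") |>
    mutate(
      age_at_event = age_at_year_start(.data$birth_date,
                                       year(.data$sepsis_date)),
      age_band = assign_age_band(.data$age_at_event, age_breaks)
    )
  if (anyNA(cc$age_band)) {
    abort("Some cases fall outside the configured age bands.",
          class = "sepsisnnt_config_error")
  }
  if ("period" %in% by) {
    cc <- cc |> mutate(period = assign_period(year(.data$sepsis_date),
                                              period_breaks))
  }

  base_by <- intersect(c("gender", "age_band", "period"), by)
  counts <- cc |>
    group_by(across(all_of(base_by))) |>
    summarise(
      n_sepsis = n(),
      n_prior_infection = sum(.data$linked),
      n_same_date_ab = sum(.data$linked & .data$ab_same_date, na.rm = TRUE),
      .groups = "drop"
    )

  py <- split_person_years(follow_up, patients, age_breaks,
                           period_breaks = if ("period" %in% by) period_breaks)
  py_by <- intersect(names(py), base_by)
  py <- py |>
    group_by(across(all_of(py_by))) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop")
  out <- if (length(py_by) > 0) {
    full_join(counts, py, by = py_by)
  } else {
    counts |> mutate(person_years = sum(py$person_years))
  }
  out <- out |>
    mutate(across(c("n_sepsis", "n_prior_infection", "n_same_date_ab"),
                  \(x) dplyr::coalesce(x, 0L)))

  if ("infection" %in% by) {
    type_counts <- cc |>
      filter(.data$linked) |>
      group_by(across(all_of(c(base_by, "infection_type")))) |>
      summarise(
        n_prior_infection = sum(.data$linked),
        n_same_date_ab = sum(.data$ab_same_date, na.rm = TRUE),
        .groups = "drop"
      ) |>
      rename(infection = "infection_type")
    out <- type_counts |>
      left_join(select(out, all_of(c(base_by, "n_sepsis", "person_years"))),
                by = base_by)
  }

  class(out) <- c("stratum_counts", class(out))
  out
}
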