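# Synthetic EHR cohort generator.
#
# The generative model is deliberately the simplest one under which the
# decision-tree estimands are well defined and exactly recoverable:
# piecewise-constant hazards on a daily grid, with ages fixed at the start of
# each calendar year. Infection consultations arise as a Poisson process at a
# per-stratum rate per 30 days; each consultation receives a same-day
# antibiotic prescription with a per-stratum probability; sepsis events arise
# at a baseline per-30-day hazard which, on days that fall strictly inside the
# risk window after the most recent consultation (0 < day - consultation <
# `risk_window`), is multiplied by a no-antibiotic or antibiotic hazard ratio
# according to that consultation's same-day prescription status. Frailty
# deficits accrue as an age-dependent Poisson process over 36 deficit slots.

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' Hazards can be given directly (`params`) or calibrated from target
#' decision-tree probabilities (`targets`, the default, taken from
#' [uk_sepsis_strata()]); see [calibrate_hazards()].
#'
#' @param n_patients Number of patients to simulate.
#' @param calendar_start,calendar_end Simulation calendar window (Dates).
#' @param targets Per-stratum tibble of decision-tree input probabilities used
#'   to calibrate hazards: columns `gender`, `age_band`, `p_infection`,
#'   `p_ab_given_infection`, `p_sepsis`, `p_inf_given_sepsis`,
#'   `frac_same_date_ab`. Ignored when `params` is supplied. By default,
#'   derived from [uk_sepsis_strata()] (count-based ratios where counts
#'   exist).
#' @param params Per-stratum tibble of generator parameters: columns `gender`,
#'   `age_band`, `rate_30d` (consultation rate per 30 days, all infection
#'   types combined), `ab_prob` (same-day prescribing probability),
#'   `hazard_30d` (baseline sepsis hazard per 30 days), `mult_no_ab`,
#'   `mult_ab` (hazard ratios in the post-consultation window).
#' @param age_weights Sampling weights over the five-year age bands of
#'   [age_breaks_five_year()] for age at `calendar_start`; default
#'   approximates the UK population pyramid. Normalised internally.
#' @param gender_split Named probabilities for `male`/`female`.
#' @param infection_shares Split of the consultation rate across `rti`,
#'   `skin`, `uti`; must sum to 1.
#' @param type_multipliers Optional extra hazard ratio by infection type of
#'   the most recent consultation (default all 1).
#' @param risk_window Width W of the post-consultation risk-modification
#'   window, in days; hazard is modified on days d with
#'   0 < d - consultation < W, matching the analysis look-back convention.
#' @param n_practices Number of synthetic family practices.
#' @param prereg_frac Fraction of patients already registered before
#'   `calendar_start`.
#' @param mean_registration_years Mean registration duration (exponential).
#' @param death_frac Fraction of patients assigned a death date inside the
#'   calendar window.
#' @param deficit_rate_base,deficit_rate_age Frailty-deficit intensity: events
#'   per person-year is `deficit_rate_base * exp(deficit_rate_age * age)`.
#' @param sepsis_period_multipliers Optional tibble (`year`, `multiplier`)
#'   scaling the sepsis hazard by calendar year (secular trend).
#' @param simulate_frailty Generate frailty-deficit events? Turning this off
#'   speeds up large simulations that do not use frailty.
#' @param age_breaks Analysis age bands used to look up stratum parameters.
#' @param rng_seed Default seed used by [simulate_cohort()].
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 100, rng_seed = 1)
#' cohort <- simulate_cohort(cfg)
#' names(cohort)
#' @export
sim_config <- function(n_patients = 10000,
                       calendar_start = as.Date("2002-01-01"),
                       calendar_end = as.Date("2017-12-31"),
                       targets = NULL,
                       params = NULL,
                       age_weights = NULL,
                       gender_split = c(male = 0.49, female = 0.51),
                       infection_shares = c(rti = 0.60, skin = 0.25, uti = 0.15),
                       type_multipliers = c(rti = 1, skin = 1, uti = 1),
                       risk_window = 30,
                       n_practices = 20,
                       prereg_frac = 0.7,
                       mean_registration_years = 25,
                       death_frac = 0.08,
                       deficit_rate_base = 0.02,
                       deficit_rate_age = 0.045,
                       sepsis_period_multipliers = NULL,
                       simulate_frailty = TRUE,
                       age_breaks = age_breaks_sepsis(),
                       rng_seed = NULL) {
  assert_nonneg(n_patients, "n_patients")
  assert_scalar_date(calendar_start, "calendar_start")
  assert_scalar_date(calendar_end, "calendar_end")
  if (calendar_start >= calendar_end) {
    abort("`calendar_start` must precede `calendar_end`.",
          class = "sepsisnnt_config_error")
  }
  validate_age_breaks(age_breaks)

  if (is.null(params)) {
    if (is.null(targets)) targets <- default_sim_targets()
    params <- calibrate_hazards(targets, risk_window = risk_window)
  }
  required_cols(params, c("gender", "age_band", "rate_30d", "ab_prob",
                          "hazard_30d", "mult_no_ab", "mult_ab"), "params")
  assert_nonneg(params$rate_30d, "rate_30d")
  assert_prob(params$ab_prob, "ab_prob")
  assert_nonneg(params$hazard_30d, "hazard_30d")
  if (any(params$mult_no_ab <= 0) || any(params$mult_ab <= 0)) {
    abort("Risk multipliers `mult_no_ab`/`mult_ab` must be positive.",
          class = "sepsisnnt_config_error")
  }
  expected_bands <- band_labels(age_breaks)
  if (!all(expected_bands %in% params$age_band)) {
    abort("`params` must cover every analysis age band for each gender.",
          class = "sepsisnnt_config_error")
  }

  if (is.null(age_weights)) age_weights <- default_age_weights()
  assert_nonneg(age_weights, "age_weights")
  if (sum(age_weights) <= 0) {
    abort("`age_weights` must have positive sum.",
          class = "sepsisnnt_config_error")
  }
  if (length(age_weights) != length(age_breaks_five_year()) - 1L) {
    abort("`age_weights` must give one weight per five-year band (0-104).",
          class = "sepsisnnt_config_error")
  }
  assert_prob(gender_split, "gender_split")
  if (abs(sum(infection_shares) - 1) > 1e-8 || any(infection_shares < 0)) {
    abort("`infection_shares` must be non-negative and sum to 1.",
          class = "sepsisnnt_config_error")
  }
  if (!setequal(names(infection_shares), infection_categories())) {
    abort("`infection_shares` must be named rti, skin, uti.",
          class = "sepsisnnt_config_error")
  }
  if (any(type_multipliers <= 0)) {
    abort("`type_multipliers` must be positive.",
          class = "sepsisnnt_config_error")
  }
  if (risk_window < 2) {
    abort("`risk_window` must be at least 2 days.",
          class = "sepsisnnt_config_error")
  }
  assert_prob(prereg_frac, "prereg_frac")
  assert_prob(death_frac, "death_frac")
  assert_nonneg(mean_registration_years, "mean_registration_years")
  if (!is.null(sepsis_period_multipliers)) {
    required_cols(sepsis_period_multipliers, c("year", "multiplier"),
                  "sepsis_period_multipliers")
    assert_nonneg(sepsis_period_multipliers$multiplier, "multiplier")
  }

  structure(list(
    n_patients = as.integer(n_patients),
    calendar_start = calendar_start, calendar_end = calendar_end,
    params = as_tibble(params),
    age_weights = age_weights / sum(age_weights),
    gender_split = gender_split / sum(gender_split),
    infection_shares = infection_shares,
    type_multipliers = type_multipliers,
    risk_window = as.integer(risk_window),
    n_practices = as.integer(n_practices),
    prereg_frac = prereg_frac,
    mean_registration_years = mean_registration_years,
    death_frac = death_frac,
    deficit_rate_base = deficit_rate_base,
    deficit_rate_age = deficit_rate_age,
    sepsis_period_multipliers = sepsis_period_multipliers,
    simulate_frailty = isTRUE(simulate_frailty),
    age_breaks = age_breaks,
    rng_seed = rng_seed
  ), class = "sim_config")
}

# Calibration targets implied by the published strata: count-based ratios
# where the counts are published, printed probabilities otherwise.
default_sim_targets <- function() {
  uk_sepsis_strata() |>
    mutate(
      p_inf_given_sepsis = .data$prior_infection_30d / .data$sepsis_events,
      frac_same_date_ab = .data$same_date_ab / .data$prior_infection_30d
    ) |>
    select("gender", "age_band", "p_infection", "p_ab_given_infection",
           "p_sepsis", "p_inf_given_sepsis", "frac_same_date_ab")
}

# Rough UK population pyramid over five-year bands 0-4 ... 100-104.
default_age_weights <- function() {
  w <- c(6.0, 5.7, 5.6, 6.0, 6.5, 6.7, 6.6, 6.2, 6.1, 6.5,
         6.9, 6.5, 5.7, 4.9, 4.0, 3.2, 2.4, 1.6, 0.8, 0.3, 0.1)
  setNames(w / sum(w), band_labels(age_breaks_five_year()))
}

#' Calibrate generator hazards from decision-tree probabilities
#'
#' Inverts the generator's closed-form ground truth so that a cohort simulated
#' with the returned parameters has, analytically, the supplied stratum-level
#' values of P(Infection), P(AB|Infection), P(Sepsis), P(Infection|Sepsis) and
#' the same-date-antibiotic fraction among linked cases.
#'
#' The inversion: with consultation rate r per 30 days (P(Infection) is read
#' as rate x 30 days), the fraction of person-time inside the
#' post-consultation window is pi = 1 - exp(-(W-1) r / 30). Then
#' `h = P(Sepsis) (1 - P(Inf|Sepsis)) / (1 - pi)` and the arm multipliers
#' follow from the linked-case split:
#' `m_ab = f Q / (a pi h)`, `m_no_ab = (1-f) Q / ((1-a) pi h)` with
#' `Q = P(Inf|Sepsis) P(Sepsis)`, `a = P(AB|Infection)`, `f` the same-date
#' fraction.
#'
#' @param targets Tibble with columns `gender`, `age_band`, `p_infection`,
#'   `p_ab_given_infection`, `p_sepsis`, `p_inf_given_sepsis`,
#'   `frac_same_date_ab`.
#' @param risk_window Risk-window width W in days.
#' @return Tibble of generator parameters (see [sim_config()] `params`).
#' @export
calibrate_hazards <- function(targets, risk_window = 30) {
  required_cols(targets, c("gender", "age_band", "p_infection",
                           "p_ab_given_infection", "p_sepsis",
                           "p_inf_given_sepsis", "frac_same_date_ab"),
                "targets")
  assert_prob(targets$p_infection, "p_infection", open_lower = TRUE)
  assert_prob(targets$p_ab_given_infection, "p_ab_given_infection",
              open_lower = TRUE, open_upper = TRUE)
  assert_prob(targets$p_sepsis, "p_sepsis", open_lower = TRUE)
  assert_prob(targets$p_inf_given_sepsis, "p_inf_given_sepsis",
              open_upper = TRUE)
  assert_prob(targets$frac_same_date_ab, "frac_same_date_ab")

  W <- risk_window
  targets |>
    mutate(
      pi_exposed = 1 - exp(-(W - 1) * .data$p_infection / 30),
      q_linked = .data$p_inf_given_sepsis * .data$p_sepsis,
      hazard_30d = .data$p_sepsis * (1 - .data$p_inf_given_sepsis) /
        (1 - .data$pi_exposed),
      mult_ab = .data$frac_same_date_ab * .data$q_linked /
        (.data$p_ab_given_infection * .data$pi_exposed * .data$hazard_30d),
      mult_no_ab = (1 - .data$frac_same_date_ab) * .data$q_linked /
        ((1 - .data$p_ab_given_infection) * .data$pi_exposed *
           .data$hazard_30d),
      rate_30d = .data$p_infection,
      ab_prob = .data$p_ab_given_infection
    ) |>
    select("gender", "age_band", "rate_30d", "ab_prob", "hazard_30d",
           "mult_no_ab", "mult_ab")
}

#' Generate a synthetic registered population
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$rng_seed`.
#' @return Tibble with one row per patient: `patient_id`, `practice_id`,
#'   `gender`, `birth_date`, `registration_start`, `up_to_standard_date`,
#'   `registration_end`, `death_date` (NA when alive).
#' @export
simulate_population <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  empty <- tibble(
    patient_id = integer(), practice_id = integer(), gender = character(),
    birth_date = as.Date(character()), registration_start = as.Date(character()),
    up_to_standard_date = as.Date(character()),
    registration_end = as.Date(character()), death_date = as.Date(character())
  )
  if (n == 0L) return(empty)

  with_seed_maybe(seed, {
    breaks5 <- age_breaks_five_year()
    band_idx <- sample.int(length(config$age_weights), n, replace = TRUE,
                           prob = config$age_weights)
    band_lo <- breaks5[band_idx]
    age_years <- band_lo + runif(n) * 5
    birth_date <- config$calendar_start - round(age_years * 365.25)

    gender <- sample(names(config$gender_split), n, replace = TRUE,
                     prob = config$gender_split)
    practice_id <- sample.int(config$n_practices, n, replace = TRUE)

    span_days <- as.numeric(config$calendar_end - config$calendar_start)
    pre <- runif(n) < config$prereg_frac
    reg_start <- dplyr::if_else(
      pre,
      config$calendar_start - round(runif(n) * 15 * 365.25),
      config$calendar_start + round(runif(n) * span_days)
    )
    reg_start <- pmax(reg_start, birth_date)

    reg_len <- round(rexp(n, rate = 1 / (config$mean_registration_years * 365.25)))
    dies <- runif(n) < config$death_frac
    death_raw <- reg_start +
      round(runif(n) * pmax(0, as.numeric(config$calendar_end - reg_start)))
    death_date <- dplyr::if_else(dies, death_raw, as.Date(NA))

    reg_end <- pmin(reg_start + reg_len, config$calendar_end)
    reg_end <- dplyr::if_else(!is.na(death_date), pmin(reg_end, death_date), reg_end)
    reg_end <- pmax(reg_end, reg_start)

    tibble(
      patient_id = seq_len(n),
      practice_id = practice_id,
      gender = gender,
      birth_date = birth_date,
      registration_start = reg_start,
      up_to_standard_date = reg_start,
      registration_end = reg_end,
      death_date = death_date
    )
  })
}

# Expand a population into patient x calendar-year risk segments with stratum
# parameters attached. Ages are fixed at each year start.
patient_year_grid <- function(population, config) {
  seg <- population |>
    mutate(
      int_start = pmax(.data$registration_start, config$calendar_start),
      int_end = pmin(.data$registration_end, config$calendar_end)
    ) |>
    filter(.data$int_end >= .data$int_start)
  if (nrow(seg) == 0L) return(seg |> mutate(year = integer(), days = integer()))

  y0 <- year(seg$int_start)
  y1 <- year(seg$int_end)
  reps <- y1 - y0 + 1L
  idx <- rep.int(seq_len(nrow(seg)), reps)
  grid <- seg[idx, ]
  grid$year <- y0[idx] + sequence(reps) - 1L
  grid |>
    mutate(
      seg_start = pmax(.data$int_start, year_start(.data$year)),
      seg_end = pmin(.data$int_end, year_end(.data$year)),
      days = as.integer(.data$seg_end - .data$seg_start) + 1L,
      age = age_at_year_start(.data$birth_date, .data$year),
      age_band = as.character(assign_age_band(.data$age, config$age_breaks))
    ) |>
    left_join(config$params, by = c("gender", "age_band"))
}

# Scatter `n_events` per grid row onto uniform days within each row's segment.
scatter_days <- function(grid, n_events) {
  idx <- rep.int(seq_len(nrow(grid)), n_events)
  total <- sum(n_events)
  tibble(
    patient_id = grid$patient_id[idx],
    event_date = grid$seg_start[idx] +
      floor(runif(total) * grid$days[idx]),
    row = idx
  )
}

#' Generate clinical events and prescriptions for a population
#'
#' @param population Output of [simulate_population()] (non-empty).
#' @param config The [sim_config()] used to generate the population.
#' @param seed Seed; defaults to `config$rng_seed`.
#' @return List with `clinical_events` (columns `patient_id`, `event_date`,
#'   `category` in rti/skin/uti/sepsis/frailty_deficit, `code`, `source`) and
#'   `prescriptions` (`patient_id`, `prescription_date`, `product_class`;
#'   same-day rows already collapsed).
#' @export
simulate_events <- function(population, config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(population) == 0L) {
    abort("`population` must be non-empty.", class = "sepsisnnt_data_error")
  }

  with_seed_maybe(seed, {
    grid <- patient_year_grid(population, config)

    # --- infection consultations, one Poisson draw per grid row and type ----
    shares <- config$infection_shares[infection_categories()]
    consults <- purrr::map(infection_categories(), function(tp) {
      lam <- grid$days * grid$rate_30d * shares[[tp]] / 30
      n_ev <- rpois(length(lam), lam)
      ev <- scatter_days(grid, n_ev)
      ev$category <- tp
      ev$ab <- rbinom(nrow(ev), 1L, grid$ab_prob[ev$row]) == 1L
      ev$row <- NULL
      ev
    }) |> list_rbind()

    prescriptions <- consults |>
      filter(.data$ab) |>
      distinct(.data$patient_id, prescription_date = .data$event_date) |>
      mutate(product_class = "antibiotic")

    # Day-level consultation summary used for hazard modification: a day's
    # prescription status is "any same-day antibiotic"; on multi-type days the
    # highest type multiplier applies.
    tm <- config$type_multipliers
    cons_days <- if (nrow(consults) > 0L) {
      consults |>
        mutate(tmult = unname(tm[.data$category])) |>
        group_by(.data$patient_id, .data$event_date) |>
        summarise(ab = any(.data$ab), tmult = max(.data$tmult),
                  .groups = "drop")
    } else {
      tibble(patient_id = integer(), event_date = as.Date(character()),
             ab = logical(), tmult = numeric())
    }

    # --- sepsis events by thinning a dominating Poisson process -------------
    period_mult <- rep(1, nrow(grid))
    if (!is.null(config$sepsis_period_multipliers)) {
      pm <- config$sepsis_period_multipliers
      m <- pm$multiplier[match(grid$year, pm$year)]
      period_mult <- dplyr::coalesce(m, 1)
    }
    tmax <- max(tm)
    dominate <- pmax(1, grid$mult_no_ab * tmax, grid$mult_ab * tmax)
    lam_sep <- grid$days * grid$hazard_30d * period_mult * dominate / 30
    n_cand <- rpois(length(lam_sep), lam_sep)
    cand <- scatter_days(grid, n_cand)
    cand$dominate <- dominate[cand$row]
    cand$mult_no_ab <- grid$mult_no_ab[cand$row]
    cand$mult_ab <- grid$mult_ab[cand$row]
    cand$row <- NULL

    sepsis <- thin_sepsis_candidates(cand, cons_days, config$risk_window)

    # --- frailty deficits ---------------------------------------------------
    deficits <- NULL
    if (config$simulate_frailty) {
      lam_def <- grid$days / 365.25 *
        config$deficit_rate_base * exp(config$deficit_rate_age * grid$age)
      n_def <- rpois(length(lam_def), lam_def)
      deficits <- scatter_days(grid, n_def)
      deficits$row <- NULL
      deficits$category <- "frailty_deficit"
      deficits$code <- sprintf("EFI%02d", sample.int(36L, nrow(deficits),
                                                     replace = TRUE))
    }

    clinical_events <- bind_rows(
      consults |>
        mutate(code = paste0(toupper(.data$category), "001")) |>
        select("patient_id", "event_date", "category", "code"),
      sepsis |> mutate(category = "sepsis", code = "SEPS001") |>
        select("patient_id", "event_date", "category", "code"),
      if (!is.null(deficits)) {
        deficits |> select("patient_id", "event_date", "category", "code")
      }
    ) |>
      mutate(source = "primary_care") |>
      arrange(.data$patient_id, .data$event_date, .data$category)

    list(clinical_events = clinical_events,
         prescriptions = prescriptions |> arrange(.data$patient_id,
                                                  .data$prescription_date))
  })
}

# Accept/reject candidate sepsis days against the post-consultation windows.
# Uses a single findInterval over (patient, day) keys; most recent
# consultation strictly before the candidate day decides the multiplier.
thin_sepsis_candidates <- function(cand, cons_days, risk_window) {
  if (nrow(cand) == 0L) {
    return(tibble(patient_id = integer(), event_date = as.Date(character())))
  }
  mult <- rep(1, nrow(cand))
  if (nrow(cons_days) > 0L) {
    base <- as.numeric(min(min(cons_days$event_date), min(cand$event_date)))
    stride <- as.numeric(max(max(cons_days$event_date),
                             max(cand$event_date))) - base + 2
    key <- function(pid, d) pid * stride + (as.numeric(d) - base)
    cons_days <- cons_days |> arrange(.data$patient_id, .data$event_date)
    ck <- key(cons_days$patient_id, cons_days$event_date)
    idx <- findInterval(key(cand$patient_id, cand$event_date) - 1, ck)
    gap <- as.numeric(cand$event_date) -
      as.numeric(cons_days$event_date[pmax(idx, 1L)])
    hit <- idx >= 1L &
      cons_days$patient_id[pmax(idx, 1L)] == cand$patient_id &
      gap >= 1 & gap <= risk_window - 1
    i <- pmax(idx, 1L)
    mult <- ifelse(
      hit,
      ifelse(cons_days$ab[i], cand$mult_ab, cand$mult_no_ab) *
        cons_days$tmult[i],
      1
    )
  }
  keep <- runif(nrow(cand)) < mult / cand$dominate
  cand[keep, c("patient_id", "event_date")]
}

#' Simulate a full synthetic EHR cohort
#'
#' Runs [simulate_population()] and [simulate_events()] under one seed.
#'
#' @inheritParams simulate_events
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$rng_seed`.
#' @return List of class `ehr_cohort`: `patients`, `clinical_events`,
#'   `prescriptions`, `config`, `seed`.
#' @export
simulate_cohort <- function(config, seed = config$rng_seed) {
  with_seed_maybe(seed, {
    patients <- simulate_population(config, seed = NULL)
    ev <- if (nrow(patients) > 0L) {
      simulate_events(patients, config, seed = NULL)
    } else {
      list(
        clinical_events = tibble(patient_id = integer(),
                                 event_date = as.Date(character()),
                                 category = character(), code = character(),
                                 source = character()),
        prescriptions = tibble(patient_id = integer(),
                               prescription_date = as.Date(character()),
                               product_class = character())
      )
    }
    structure(list(patients = patients,
                   clinical_events = ev$clinical_events,
                   prescriptions = ev$prescriptions,
                   config = config, seed = seed),
              class = "ehr_cohort")
  })
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>",
      nrow(x$patients), "patients,",
      nrow(x$clinical_events), "clinical events,",
      nrow(x$prescriptions), "prescriptions\n")
  invisible(x)
}

#' Analytic ground truth of the generator
#'
#' Returns, per stratum, the decision-tree quantities analytically implied by
#' the generator's parameters: with consultation rate r per 30 days, window
#' width W, exposure fraction `pi = 1 - exp(-(W-1) r / 30)`, prescribing
#' probability a, baseline hazard h and arm multipliers m1 (no AB), m2 (AB)
#' (times the share-weighted type multiplier), the marginal sepsis probability
#' is `h (1 - pi) + h pi mbar`, the linked fraction `pi mbar h / P(Sepsis)`,
#' and the arm probabilities `h m1 pi / r` and `h m2 pi / r`. When the two
#' multipliers are equal the risk difference is zero and the NNT is reported
#' as the `no_effect` sentinel (`effect` column, `nnt = Inf`), not an
#' overflow.
#'
#' @param config A [sim_config()].
#' @return Tibble per stratum with the five input probabilities, the derived
#'   arm probabilities, `risk_difference`, `nnt`, and `effect`.
#' @export
sim_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  W <- config$risk_window
  shares <- config$infection_shares[infection_categories()]
  tbar <- sum(shares * config$type_multipliers[infection_categories()])

  out <- config$params |>
    mutate(
      pi_exposed = 1 - exp(-(W - 1) * .data$rate_30d / 30),
      arm_mix = .data$ab_prob * .data$mult_ab +
        (1 - .data$ab_prob) * .data$mult_no_ab,
      p_infection = .data$rate_30d,
      p_sepsis = .data$hazard_30d * (1 - .data$pi_exposed) +
        .data$hazard_30d * .data$pi_exposed * .data$arm_mix * tbar,
      p_inf_given_sepsis = .data$hazard_30d * .data$pi_exposed *
        .data$arm_mix * tbar / .data$p_sepsis,
      p_ab_given_inf_sepsis = .data$ab_prob * .data$mult_ab / .data$arm_mix,
      p_sepsis_given_infection = .data$p_inf_given_sepsis * .data$p_sepsis /
        .data$p_infection,
      p_sepsis_no_ab = .data$hazard_30d * .data$mult_no_ab * tbar *
        .data$pi_exposed / .data$rate_30d,
      p_sepsis_ab = .data$hazard_30d * .data$mult_ab * tbar *
        .data$pi_exposed / .data$rate_30d
    )
  nn <- nnt(out$p_sepsis_no_ab, out$p_sepsis_ab)
  out |>
    mutate(risk_difference = nn$risk_difference, nnt = nn$nnt,
           effect = nn$effect) |>
    select("gender", "age_band", "p_infection", "p_sepsis",
           "p_inf_given_sepsis", "p_ab_given_infection" = "ab_prob",
           "p_ab_given_inf_sepsis", "p_sepsis_given_infection",
           "p_sepsis_no_ab", "p_sepsis_ab", "risk_difference", "nnt",
           "effect")
}

#' Write / read the four cohort tables
#'
#' `write_cohort_tables()` writes `patients.tsv`, `clinical_events.tsv`
#' (non-deficit events), `deficits.tsv` and `prescriptions.tsv` to `dir`,
#' each stamped with the digest of a [run_manifest()];
#' `read_cohort_tables()` reads them back.
#'
#' @param cohort An `ehr_cohort` (or a list with the same elements).
#' @param dir Output directory (created if needed).
#' @param manifest Optional [run_manifest()]; one is built by default.
#' @return `write_cohort_tables()` returns the manifest invisibly;
#'   `read_cohort_tables()` returns a list of the four tibbles.
#' @export
write_cohort_tables <- function(cohort, dir, manifest = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- manifest %||% run_manifest(config = cohort$config,
                                         seed = cohort$seed)
  ev <- cohort$clinical_events
  stamp_write(cohort$patients, file.path(dir, "patients.tsv"), manifest)
  stamp_write(filter(ev, .data$category != "frailty_deficit"),
              file.path(dir, "clinical_events.tsv"), manifest)
  stamp_write(filter(ev, .data$category == "frailty_deficit"),
              file.path(dir, "deficits.tsv"), manifest)
  stamp_write(cohort$prescriptions, file.path(dir, "prescriptions.tsv"),
              manifest)
  invisible(manifest)
}

#' @rdname write_cohort_tables
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(f) read_tsv(file.path(dir, f), comment = "#",
                             show_col_types = FALSE)
  ev <- rd("clinical_events.tsv")
  def <- rd("deficits.tsv")
  list(
    patients = rd("patients.tsv"),
    clinical_events = bind_rows(ev, def) |>
      arrange(.data$patient_id, .data$event_date),
    prescriptions = rd("prescriptions.tsv")
  )
}
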