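# Follow-up intervals, incident ascertainment, look-back linkage, source
# merging and stratum tabulation, each against a brute-force oracle.

study_start <- as.Date("2002-01-01")
study_end <- as.Date("2017-12-31")

test_that("follow-up intervals follow the latest-of / earliest-of rules", {
  pats <- tibble(
    patient_id = 1:3,
    registration_start = as.Date(c("2000-01-01", "2017-06-01", "2005-03-10")),
    up_to_standard_date = as.Date(c("1999-01-01", "2017-06-01", "2006-01-01")),
    registration_end = as.Date(c("2020-01-01", "2020-01-01", "2010-06-30")),
    death_date = as.Date(c(NA, NA, "2009-12-31"))
  )
  fu <- compute_follow_up(pats, study_start, study_end)
  # long-registered patient: the full study window, 16.0 person-years
  expect_equal(fu$start_date[1], study_start)
  expect_equal(fu$end_date[1], study_end)
  expect_equal(fu$person_years[1], 16.0, tolerance = 1e-3)
  # registered mid-2017: the 1-year qualification pushes start past study end
  expect_equal(fu$person_years[2], 0)
  # up-to-standard after registration+1y, death before registration end
  expect_equal(fu$start_date[3], as.Date("2006-03-10"))
  expect_equal(fu$end_date[3], as.Date("2009-12-31"))

  bad <- pats |> mutate(registration_end = as.Date("1999-01-01"))
  expect_error(compute_follow_up(bad, study_start, study_end),
               class = "sepsisnnt_data_error")
})

test_that("split person-years equal a per-day counting oracle", {
  pop <- simulate_population(sim_config(n_patients = 25, rng_seed = 21))
  fu <- compute_follow_up(pop, study_start, study_end)
  split <- split_person_years(fu, pop)
  expect_equal(sum(split$person_years), sum(fu$person_years),
               tolerance = 1e-9)

  # brute force: walk every day of every interval and classify it
  oracle <- numeric()
  for (i in seq_len(nrow(fu))) {
    if (fu$person_years[i] <= 0) next
    days <- seq(fu$start_date[i], fu$end_date[i], by = "day")
    bands <- assign_age_band(pmax(0, floor(as.numeric(
      as.Date(sprintf("%d-01-01", lubridate::year(days))) -
        pop$birth_date[pop$patient_id == fu$patient_id[i]]
    ) / 365.25)))
    key <- paste(pop$gender[pop$patient_id == fu$patient_id[i]], bands)
    tab <- table(key)
    for (k in names(tab)) {
      oracle[k] <- (if (is.na(oracle[k])) 0 else oracle[k]) + tab[[k]]
    }
  }
  got <- setNames(split$person_years,
                  paste(split$gender, split$age_band))
  expect_setequal(names(got), names(oracle))
  expect_equal(got[names(oracle)] * 365.25, oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("incident ascertainment keeps the first in-interval event only", {
  pats <- simple_patients(3)
  fu <- compute_follow_up(pats, study_start, study_end)
  ev <- tibble(
    patient_id = c(1L, 1L, 2L, 3L),
    event_date = as.Date(c("2005-02-01", "2006-06-01",  # first wins
                           "2001-05-01",                # before follow-up
                           "2010-01-01")),
    category = "sepsis", code = "SEPS001", source = "primary_care"
  )
  cases <- ascertain_incident_sepsis(ev, fu)
  expect_equal(cases$sepsis_date[cases$patient_id == 1],
               as.Date("2005-02-01"))
  # out-of-interval event ignored entirely; patient 2 contributes no case
  expect_false(2L %in% cases$patient_id)
  expect_true(3L %in% cases$patient_id)

  # an out-of-interval earlier event does not suppress an in-interval later
  # one unless prevalent suppression is requested
  ev2 <- bind_rows(ev, tibble(patient_id = 2L,
                              event_date = as.Date("2010-07-01"),
                              category = "sepsis", code = "SEPS001",
                              source = "primary_care"))
  expect_true(2L %in% ascertain_incident_sepsis(ev2, fu)$patient_id)
  expect_false(2L %in% ascertain_incident_sepsis(
    ev2, fu, suppress_prevalent = TRUE
  )$patient_id)
})

test_that("ascertainment matches an exhaustive scan oracle on random streams", {
  set.seed(31)
  pats <- simple_patients(40)
  fu <- compute_follow_up(pats, study_start, study_end)
  ev <- tibble(
    patient_id = sample(1:40, 300, replace = TRUE),
    event_date = as.Date("2000-01-01") + sample.int(7000, 300, replace = TRUE),
    category = sample(c("sepsis", "rti"), 300, replace = TRUE,
                      prob = c(0.3, 0.7)),
    code = "X", source = "primary_care"
  )
  cases <- ascertain_incident_sepsis(ev, fu)
  for (id in unique(ev$patient_id)) {
    d <- ev$event_date[ev$patient_id == id & ev$category == "sepsis"]
    d <- sort(d[d >= fu$start_date[fu$patient_id == id] &
                  d <= fu$end_date[fu$patient_id == id]])
    if (length(d) == 0) {
      expect_false(id %in% cases$patient_id)
    } else {
      expect_equal(cases$sepsis_date[cases$patient_id == id], d[1])
    }
  }
})

test_that("look-back linkage uses the open window and the most recent consultation", {
  sepsis_date <- as.Date("2010-06-15")
  cases <- tibble(patient_id = 1:4, sepsis_date = sepsis_date)
  ev <- tibble(
    patient_id = c(1L, 2L, 3L, 3L, 4L),
    event_date = sepsis_date - c(10, 30, 20, 5, 0),
    category = c("rti", "uti", "rti", "uti", "skin"),
    code = "X", source = "primary_care"
  )
  rx <- tibble(patient_id = c(1L, 3L),
               prescription_date = sepsis_date - c(10, 20))
  linked <- link_lookback(cases, ev, rx, window_days = 30)

  expect_true(linked$linked[1])
  expect_true(linked$ab_same_date[1])
  # exactly window_days before: outside the open window
  expect_false(linked$linked[2])
  # most recent of several defines exposure; the earlier AB consultation does
  # not set the same-date flag
  expect_equal(linked$consultation_date[3], sepsis_date - 5)
  expect_equal(linked$infection_type[3], "uti")
  expect_false(linked$ab_same_date[3])
  expect_equal(linked$n_ab_window[3], 1L)
  # a consultation on the sepsis date itself is not a preceding consultation
  expect_false(linked$linked[4])

  # one day inside the boundary is linked
  ev29 <- tibble(patient_id = 2L, event_date = sepsis_date - 29,
                 category = "uti", code = "X", source = "primary_care")
  expect_true(link_lookback(cases[2, ], ev29, rx)$linked)
})

test_that("widening the window can only add linked cases", {
  coh <- shared_sim()
  fu <- compute_follow_up(coh$patients, study_start, study_end)
  cases <- ascertain_incident_sepsis(coh$clinical_events, fu)
  l30 <- link_lookback(cases, coh$clinical_events, coh$prescriptions, 30)
  l60 <- link_lookback(cases, coh$clinical_events, coh$prescriptions, 60)
  expect_gte(sum(l60$linked), sum(l30$linked))
  # every 30-day-linked case stays linked at 60 days
  expect_true(all(l30$patient_id[l30$linked] %in%
                    l60$patient_id[l60$linked]))
})

test_that("source merging takes the per-patient union with precedence dedup", {
  primary <- tibble(patient_id = 1L, event_date = as.Date("2010-04-10"),
                    category = "sepsis", code = "A")
  hospital <- tibble(patient_id = 1L, event_date = as.Date("2010-03-31"),
                     category = "sepsis", code = "B")
  merged <- merge_event_sources(primary, hospital)
  expect_equal(min(merged$event_date), as.Date("2010-03-31"))

  # empty extra streams: identity
  expect_equal(
    merge_event_sources(primary)$event_date, primary$event_date
  )

  # same-day multi-source record deduplicates, keeping primary care
  dup <- merge_event_sources(
    primary, primary |> select(-code) |> mutate(code = "H")
  )
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$source, "primary_care")

  # random fixtures: equals the set union on (patient, date, category)
  set.seed(5)
  mk <- function(n) tibble(
    patient_id = sample(1:10, n, TRUE),
    event_date = as.Date("2010-01-01") + sample(0:50, n, TRUE),
    category = "sepsis", code = "X"
  )
  a <- mk(40); b <- mk(40); c <- mk(40)
  m <- merge_event_sources(a, b, c)
  u <- distinct(bind_rows(a, b, c), patient_id, event_date, category)
  expect_equal(nrow(m), nrow(u))
})

test_that("stratum tabulation conserves totals and matches a filter oracle", {
  coh <- shared_sim()
  fu <- compute_follow_up(coh$patients, study_start, study_end)
  cases <- ascertain_incident_sepsis(coh$clinical_events, fu) |>
    link_lookback(coh$clinical_events, coh$prescriptions, 30)
  tab <- tabulate_strata(cases, fu, coh$patients)

  expect_equal(sum(tab$n_sepsis), nrow(cases))
  expect_equal(sum(tab$n_prior_infection), sum(cases$linked))
  expect_equal(sum(tab$n_same_date_ab),
               sum(cases$linked & cases$ab_same_date, na.rm = TRUE))
  expect_equal(sum(tab$person_years), sum(fu$person_years),
               tolerance = 1e-9)

  # single all-covering stratum equals global totals
  one <- tabulate_strata(cases, fu, coh$patients |> mutate(gender = "all"),
                         age_breaks = c(0, Inf))
  expect_equal(one$n_sepsis, nrow(cases))
  expect_equal(one$person_years, sum(fu$person_years), tolerance = 1e-9)

  # per-stratum counts equal a brute-force filter
  cc <- cases |>
    left_join(select(coh$patients, patient_id, gender, birth_date),
              by = "patient_id") |>
    mutate(band = assign_age_band(pmax(0, floor(as.numeric(
      as.Date(sprintf("%d-01-01", lubridate::year(sepsis_date))) - birth_date
    ) / 365.25))))
  for (i in sample.int(nrow(tab), 5)) {
    sel <- cc$gender == tab$gender[i] & cc$band == tab$age_band[i]
    expect_equal(tab$n_sepsis[i], sum(sel))
    expect_equal(tab$n_prior_infection[i], sum(cc$linked[sel]))
  }

  # malformed bands are rejected
  expect_error(tabulate_strata(cases, fu, coh$patients,
                               age_breaks = c(0, 50, 40, Inf)),
               class = "sepsisnnt_config_error")
})
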