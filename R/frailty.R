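# 36-deficit electronic frailty index (eFI).
#
# Deficits are cumulative: once recorded they remain present in every later
# calendar year. The index is the fraction of the 36 deficit slots recorded,
# and the category cut points follow the published eFI convention
# (<= 0.12 nonfrail, (0.12, 0.24] mild, (0.24, 0.36] moderate, > 0.36
# severe). Frailty is conventionally evaluated from age 55; the functions
# here are age-agnostic and the restriction is applied where assessments are
# consumed.

#' Categorise a frailty index value
#'
#' @param index_value Frailty index in \[0, 1\] (deficits / 36).
#' @param cuts Upper bounds of the nonfrail, mild and moderate categories.
#' @return Ordered factor nonfrail < mild < moderate < severe. Boundary
#'   values belong to the lower category (right-closed intervals).
#' @examples
#' frailty_category(c(0, 5, 14) / 36)
#' @export
frailty_category <- function(index_value, cuts = c(0.12, 0.24, 0.36)) {
  if (any(index_value < 0 | index_value > 1, na.rm = TRUE)) {
    abort("Frailty index values must lie in [0, 1].",
          class = "sepsisnnt_data_error")
  }
  if (length(cuts) != 3 || any(diff(cuts) <= 0)) {
    abort("`cuts` must be three increasing thresholds.",
          class = "sepsisnnt_config_error")
  }
  cut(index_value, breaks = c(-Inf, cuts, Inf),
      labels = c("nonfrail", "mild", "moderate", "severe"),
      right = TRUE, ordered_result = TRUE)
}

#' Frailty category levels
#' @return Character vector of the four categories in severity order.
#' @export
frailty_levels <- function() c("nonfrail", "mild", "moderate", "severe")

#' Compute annual frailty assessments
#'
#' Maps deficit-coded clinical events onto the 36 eFI slots and returns one
#' assessment per patient per calendar year, with deficits accumulating over
#' years (a deficit recorded in year y counts in all years >= y).
#'
#' @param events Clinical events; rows with `category == "frailty_deficit"`
#'   are used.
#' @param years Calendar years to assess; defaults to the span of the deficit
#'   events.
#' @param slot_map Named integer vector mapping deficit codes to slots 1-36.
#'   By default codes of the form `EFI01` ... `EFI36` map to their number.
#' @param patients Optional patient table; when given, patients with no
#'   deficits are included with zero counts.
#' @param strict Error (instead of warn and ignore) on codes outside the
#'   slot map?
#' @param cuts Category cut points, see [frailty_category()].
#' @return Tibble `patient_id`, `year`, `deficit_count`, `index_value`,
#'   `category`.
#' @export
compute_annual_frailty <- function(events, years = NULL, slot_map = NULL,
                                   patients = NULL, strict = FALSE,
                                   cuts = c(0.12, 0.24, 0.36)) {
  required_cols(events, c("patient_id", "event_date", "category", "code"),
                "events")
  def <- events |> filter(.data$category == "frailty_deficit")

  if (is.null(slot_map)) {
    slot_map <- setNames(1:36, sprintf("EFI%02d", 1:36))
  }
  slot <- unname(slot_map[def$code])
  unknown <- is.na(slot)
  if (any(unknown)) {
    msg <- sprintf("%d deficit event(s) with codes outside the 36-slot map.",
                   sum(unknown))
    if (strict) abort(msg, class = "sepsisnnt_data_error")
    warn(paste(msg, "They were ignored."))
    def <- def[!unknown, ]
    slot <- slot[!unknown]
  }
  def$slot <- slot

  if (is.null(years)) {
    if (nrow(def) == 0L) {
      abort("No deficit events and no `years` given; nothing to assess.",
            class = "sepsisnnt_data_error")
    }
    years <- seq(min(year(def$event_date)), max(year(def$event_date)))
  }

  ids <- if (!is.null(patients)) patients$patient_id else unique(def$patient_id)

  # First year each (patient, slot) appears, then cumulative new slots.
  new_by_year <- def |>
    mutate(year = year(.data$event_date)) |>
    group_by(.data$patient_id, .data$slot) |>
    summarise(first_year = min(.data$year), .groups = "drop") |>
    count(.data$patient_id, .data$first_year, name = "n_new")

  crossing(patient_id = ids, year = as.integer(years)) |>
    left_join(new_by_year,
              by = c("patient_id", year = "first_year")) |>
    mutate(n_new = dplyr::coalesce(.data$n_new, 0L)) |>
    group_by(.data$patient_id) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(
      # slots first recorded before the assessment range still count
      carried = cumsum(.data$n_new)
    ) |>
    ungroup() |>
    add_pre_range_deficits(new_by_year, min(years)) |>
    mutate(
      deficit_count = .data$carried + .data$pre_range,
      index_value = .data$deficit_count / 36,
      category = frailty_category(.data$index_value, cuts = cuts)
    ) |>
    select("patient_id", "year", "deficit_count", "index_value", "category")
}

add_pre_range_deficits <- function(grid, new_by_year, first_assess_year) {
  pre <- new_by_year |>
    filter(.data$first_year < first_assess_year) |>
    group_by(.data$patient_id) |>
    summarise(pre_range = sum(.data$n_new), .groups = "drop")
  grid |>
    left_join(pre, by = "patient_id") |>
    mutate(pre_range = dplyr::coalesce(.data$pre_range, 0L))
}

#' Allocate person-years across frailty categories
#'
#' The full-population denominator carries no per-patient frailty, so stratum
#' person-years are allocated to categories using the category proportions
#' observed in the prescribing sample. The allocation conserves each
#' stratum's total exactly: any floating-point residue is assigned to the
#' category with the largest proportion (largest-remainder correction).
#'
#' @param person_years Tibble with stratum columns and `person_years`.
#' @param proportions Tibble with the same stratum columns, `category`, and
#'   `proportion`; proportions must sum to 1 within each stratum
#'   (tolerance 1e-9).
#' @return Tibble: stratum columns, `category`, `person_years`.
#' @export
allocate_person_years <- function(person_years, proportions) {
  required_cols(person_years, "person_years", "person_years")
  required_cols(proportions, c("category", "proportion"), "proportions")
  strata_cols <- setdiff(names(person_years), "person_years")

  sums <- proportions |>
    group_by(across(all_of(strata_cols))) |>
    summarise(s = sum(.data$proportion), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("Frailty proportions must sum to 1 within each stratum.",
          class = "sepsisnnt_data_error")
  }

  person_years |>
    inner_join(proportions, by = strata_cols,
               relationship = "one-to-many") |>
    group_by(across(all_of(strata_cols))) |>
    mutate(
      allocated = .data$person_years * .data$proportion,
      residue = first(.data$person_years) - sum(.data$allocated),
      allocated = .data$allocated +
        dplyr::if_else(row_number() == which.max(.data$proportion),
                       .data$residue, 0)
    ) |>
    ungroup() |>
    select(all_of(strata_cols), "category", person_years = "allocated")
}
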