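# Shared conventions: age bands, the age-at-year-start rule, seeds, validation.

#' Age bands used for sepsis tabulation
#'
#' Default analysis bands: 0-4, 5-14, then 10-year bands to 85+. Bands are
#' left-closed intervals over age in completed years; the final band is
#' open-ended.
#'
#' @return Numeric vector of band lower bounds, ending in `Inf`.
#' @export
age_breaks_sepsis <- function() {
  c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85, Inf)
}

#' Five-year age bands used for the sampling frame
#'
#' @param max_age Upper age limit of the frame; ages above it are clamped.
#' @return Numeric vector of band lower bounds, ending in `Inf`.
#' @export
age_breaks_five_year <- function(max_age = 104) {
  c(seq(0, max_age, by = 5), Inf)
}

band_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.finite(hi), paste0(lo, "-", hi - 1), paste0(lo, "+"))
}

validate_age_breaks <- function(breaks) {
  if (!is.numeric(breaks) || length(breaks) < 2L || anyNA(breaks)) {
    abort("`age_breaks` must be a numeric vector of at least two cut points.",
          class = "sepsisnnt_config_error")
  }
  if (any(diff(breaks) <= 0)) {
    abort("`age_breaks` must be strictly increasing (overlapping or empty bands).",
          class = "sepsisnnt_config_error")
  }
  if (breaks[1] > 0) {
    abort("`age_breaks` must start at 0 so that every age falls in a band.",
          class = "sepsisnnt_config_error")
  }
  invisible(breaks)
}

#' Assign ages to bands
#'
#' @param age Ages in completed years.
#' @param breaks Band lower bounds (see [age_breaks_sepsis()]).
#' @return Factor of band labels, levels in band order.
#' @export
assign_age_band <- function(age, breaks = age_breaks_sepsis()) {
  validate_age_breaks(breaks)
  if (any(age < 0, na.rm = TRUE)) {
    abort("Negative ages cannot be assigned to a band.",
          class = "sepsisnnt_data_error")
  }
  cut(age, breaks = breaks, labels = band_labels(breaks),
      right = FALSE, include.lowest = TRUE)
}

# Age convention used throughout: completed years at the start of the calendar
# year of interest, floor((Jan 1 of year - birth_date)/365.25), clamped at 0 so
# that infants born during the year count as age 0.
age_at_year_start <- function(birth_date, yr) {
  pmax(0, floor(as.numeric(year_start(yr) - birth_date) / 365.25))
}

year_start <- function(yr) lubridate::make_date(yr, 1L, 1L)
year_end <- function(yr) lubridate::make_date(yr, 12L, 31L)

# Run `expr` under `seed` when given, without disturbing the caller's RNG
# stream; with seed = NULL the global stream is used as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

assert_scalar_date <- function(x, name) {
  if (!inherits(x, "Date") || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single Date.", name),
          class = "sepsisnnt_config_error")
  }
  invisible(x)
}

assert_prob <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  bad <- is.na(x) | x < 0 | x > 1 |
    (open_lower & x == 0) | (open_upper & x == 1)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in %s0, 1%s; offending value: %s",
                  name, if (open_lower) "(" else "[",
                  if (open_upper) ")" else "]",
                  paste(utils::head(x[bad], 3), collapse = ", ")),
          class = "sepsisnnt_config_error")
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (any(is.na(x) | x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name),
          class = "sepsisnnt_config_error")
  }
  invisible(x)
}

# Columns required of each event table; used by several modules.
required_cols <- function(x, cols, name) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", name,
                  paste(missing, collapse = ", ")),
          class = "sepsisnnt_data_error")
  }
  invisible(x)
}

infection_categories <- function() c("rti", "skin", "uti")
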