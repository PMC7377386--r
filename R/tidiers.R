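# broom-style accessors and ggplot2 methods for fitted objects.

#' Tidy a single-stratum risk estimate
#'
#' @param x A `sepsis_risk` from [draw_uncertainty()].
#' @param ... Unused.
#' @return Tibble `quantity`, `plugin`, `estimate`, `lower`, `upper`.
#' @export
tidy.sepsis_risk <- function(x, ...) x$estimates

#' @rdname tidy.sepsis_risk
#' @export
glance.sepsis_risk <- function(x, ...) {
  tibble(
    n_draws = x$n_draws,
    prior = x$prior,
    frac_nonpositive_rd = x$frac_nonpositive_rd,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a stratified risk table
#'
#' @param x A `sepsis_risk_tbl` from [estimate_all_strata()].
#' @param ... Unused.
#' @return Long tibble: stratum identifiers, `quantity`, `estimate`,
#'   `lower`, `upper` (equivalent to [figure_series()] without axis
#'   ordering).
#' @export
tidy.sepsis_risk_tbl <- function(x, ...) {
  id_cols <- intersect(c("gender", "age_band", "period", "infection",
                         "frailty"), names(x))
  x |>
    as_tibble() |>
    select(all_of(id_cols), all_of(risk_quantities),
           all_of(paste0(risk_quantities, "_lower")),
           all_of(paste0(risk_quantities, "_upper"))) |>
    pivot_longer(-all_of(id_cols), names_to = "name") |>
    mutate(
      stat = case_when(
        grepl("_lower$", .data$name) ~ "lower",
        grepl("_upper$", .data$name) ~ "upper",
        TRUE ~ "estimate"
      ),
      quantity = sub("_(lower|upper)$", "", .data$name)
    ) |>
    select(-"name") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
}

#' @rdname tidy.sepsis_risk_tbl
#' @export
glance.sepsis_risk_tbl <- function(x, ...) {
  tibble(
    n_strata = nrow(x),
    n_draws = attr(x, "n_draws"),
    prior = attr(x, "prior"),
    n_failed = sum(!is.na(x$note))
  )
}

#' Plot a stratified risk table
#'
#' Point-and-interval plot of one derived quantity along an axis, coloured by
#' gender when present. NNT panels use a log y scale by default, as do the
#' probability panels.
#'
#' @param object A `sepsis_risk_tbl`.
#' @param quantity One of `"nnt"`, `"p_sepsis_no_ab"`, `"p_sepsis_ab"`,
#'   `"p_sepsis_given_infection"`.
#' @param axis Stratification column for the x axis.
#' @param log_y Use a log10 y scale?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sepsis_risk_tbl <- function(object, quantity = "nnt",
                                     axis = "age_band", log_y = TRUE, ...) {
  if (!quantity %in% risk_quantities) {
    abort(sprintf("`quantity` must be one of: %s",
                  paste(risk_quantities, collapse = ", ")),
          class = "sepsisnnt_config_error")
  }
  series <- figure_series(object, axis = axis) |>
    filter(.data$quantity == !!quantity, is.finite(.data$estimate))
  aes_args <- aes(x = .data[[axis]], y = .data$estimate,
                  ymin = .data$lower, ymax = .data$upper)
  p <- ggplot(series, aes_args)
  if ("gender" %in% names(series) && axis != "gender") {
    p <- p + geom_pointrange(aes(colour = .data$gender),
                             position = position_dodge(width = 0.4))
  } else {
    p <- p + geom_pointrange()
  }
  lab <- c(nnt = "NNT (antibiotic prescriptions per sepsis event prevented)",
           p_sepsis_no_ab = "P(sepsis | infection consultation, no antibiotic)",
           p_sepsis_ab = "P(sepsis | infection consultation, antibiotic)",
           p_sepsis_given_infection = "P(sepsis | infection consultation)")
  p <- p + labs(x = axis, y = lab[[quantity]]) + theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' @rdname autoplot.sepsis_risk_tbl
#' @param x A `sepsis_risk_tbl`.
#' @export
plot_nnt <- function(x, axis = "age_band", ...) {
  autoplot.sepsis_risk_tbl(x, quantity = "nnt", axis = axis, ...)
}
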