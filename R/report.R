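# Results tables, figure-ready series, and run manifests.

#' Run manifest
#'
#' A small provenance record attached to every written artifact: package
#' version, timestamp, seeds, a hash of the configuration, and digests of any
#' input files. Writers stamp its digest into a leading comment line so each
#' output references the run that produced it.
#'
#' @param config Optional configuration object (hashed, not stored verbatim).
#' @param seed Optional seed(s) used by the run.
#' @param files Optional character vector of input file paths to digest.
#' @return List of class `run_manifest` with a `digest` field.
#' @export
run_manifest <- function(config = NULL, seed = NULL, files = character()) {
  file_md5 <- if (length(files) > 0) tools::md5sum(files) else character()
  m <- list(
    package = "sepsisnnt",
    version = as.character(packageVersion("sepsisnnt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) hash(config) else NA_character_,
    file_md5 = file_md5
  )
  m$digest <- hash(m)
  class(m) <- "run_manifest"
  m
}

stamp_write <- function(x, path, manifest) {
  write_lines(sprintf("# manifest: %s", manifest$digest), path)
  write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Render the stratified results table
#'
#' Mirrors the published layout: one row per stratum with the five input
#' probabilities, the derived sepsis probabilities without/with antibiotics,
#' and the NNT with its 95% uncertainty interval, at the publication rounding
#' conventions (derived probabilities to 6 decimal places, inputs to 2,
#' P(Sepsis) to 6, NNT to the nearest integer). Strata that failed to
#' estimate are retained as flagged rows with missing values.
#'
#' @param estimates A `sepsis_risk_tbl` from [estimate_all_strata()].
#' @return A tibble; empty input yields a zero-row table with the full
#'   header.
#' @export
render_results_table <- function(estimates) {
  cols <- c("p_infection", "p_sepsis", "p_inf_given_sepsis",
            "p_ab_given_infection")
  id_cols <- intersect(c("gender", "age_band", "period", "infection",
                         "frailty"), names(estimates))
  out <- estimates |>
    as_tibble() |>
    mutate(
      p_infection = round(.data$p_infection, 2),
      p_sepsis = round(.data$p_sepsis, 6),
      p_inf_given_sepsis = round(.data$p_inf_given_sepsis, 2),
      p_ab_given_infection = round(.data$p_ab_given_infection, 2),
      p_sepsis_no_ab = round(.data$p_sepsis_no_ab, 6),
      p_sepsis_ab = round(.data$p_sepsis_ab, 6),
      nnt = round(.data$nnt),
      nnt_lower = round(.data$nnt_lower),
      nnt_upper = round(.data$nnt_upper),
      flagged = !is.na(.data$note)
    ) |>
    select(all_of(id_cols), all_of(cols), "p_sepsis_no_ab", "p_sepsis_ab",
           "nnt", "nnt_lower", "nnt_upper", "flagged")
  # plain tibble out: drop the fitted-object attributes
  for (a in c("n_draws", "prior", "seed", "id_cols")) attr(out, a) <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Write / read a results table
#'
#' The written file carries the manifest digest in a leading `#` comment;
#' reading it back recovers the values exactly at the declared precision.
#'
#' @param x A rendered results table ([render_results_table()]).
#' @param path Output path (tab-separated).
#' @param manifest Optional [run_manifest()]; one is created by default.
#' @return The path (write) or the re-parsed tibble (read).
#' @export
write_results_table <- function(x, path, manifest = NULL) {
  manifest <- manifest %||% run_manifest()
  stamp_write(x, path, manifest)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Figure-ready long series
#'
#' One row per stratum and derived quantity with the central estimate and
#' uncertainty interval, ordered along the requested axis, suitable for
#' plotting (the probability quantities are flagged for a log scale via the
#' `log_scale` attribute).
#'
#' @param estimates A `sepsis_risk_tbl`.
#' @param axis Stratification axis to order by: `"age_band"`, `"frailty"` or
#'   `"infection"`. Must be present in `estimates`.
#' @return Tibble: identifier columns, `quantity`, `estimate`, `lower`,
#'   `upper`.
#' @export
figure_series <- function(estimates,
                          axis = c("age_band", "frailty", "infection")) {
  axis <- match.arg(axis)
  if (!axis %in% names(estimates)) {
    abort(sprintf("Estimates are not stratified by `%s`.", axis),
          class = "sepsisnnt_config_error")
  }
  id_cols <- intersect(c("gender", "age_band", "period", "infection",
                         "frailty"), names(estimates))
  long <- estimates |>
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

  if (axis == "age_band") {
    lv <- unique(estimates$age_band)
    lv <- lv[order(as.numeric(sub("[-+].*$", "", lv)))]
    long <- long |>
      mutate(age_band = factor(.data$age_band, levels = lv)) |>
      arrange(.data$quantity, .data$age_band)
  } else {
    long <- long |> arrange(.data$quantity, .data[[axis]])
  }
  attr(long, "log_scale") <- c("p_sepsis_given_infection", "p_sepsis_no_ab",
                               "p_sepsis_ab")
  attr(long, "axis") <- axis
  class(long) <- c("sepsis_series", class(long))
  long
}
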