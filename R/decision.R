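# The Bayesian decision tree.
#
# Five stratum-level inputs:
#   P(Infection)            probability of an infection consultation per
#                           30 days (rate x 30 days)
#   P(Sepsis)               probability of a first sepsis event per 30 days
#   P(Infection | Sepsis)   fraction of sepsis cases with a consultation in
#                           the look-back window
#   P(AB | Infection)       same-day prescribing probability
#   P([AB|Inf] | Sepsis)    same-date-antibiotic fraction among linked cases
#
# Derived by Bayes' theorem:
#   P(Sepsis | Infection)        = P(Inf|Sep) P(Sep) / P(Inf)
#   P(Sepsis | no-AB arm)        = (1 - P([AB|Inf]|Sep)) P(Sep|Inf) / (1 - P(AB|Inf))
#   P(Sepsis | AB arm)           = P([AB|Inf]|Sep) P(Sep|Inf) / P(AB|Inf)
#   NNT                          = 1 / (P(Sep|no-AB) - P(Sep|AB))
#
# Uncertainty: each input with counts (k successes of n trials) gets a beta
# posterior (Jeffreys by default), the chain is evaluated per draw, and the
# central estimate / 95% uncertainty interval are the median / 2.5th-97.5th
# percentiles of the draws. Draws with non-positive risk difference propagate
# to the NNT distribution as censored at infinity and their fraction is
# reported.

prob_fields <- c("p_infection", "p_sepsis", "p_inf_given_sepsis",
                 "p_ab_given_infection", "p_ab_given_inf_sepsis")

#' Construct a probability set
#'
#' One row per stratum of the five decision-tree input probabilities, with
#' optional (numerator, denominator) counts enabling beta draws. When counts
#' are given and a probability is NULL, the probability is filled with k/n.
#'
#' @param p_infection,p_sepsis,p_inf_given_sepsis,p_ab_given_infection,p_ab_given_inf_sepsis
#'   Input probabilities (vectors allowed).
#' @param counts Optional named list of `c(k, n)` pairs (or two-column
#'   matrices for vector input) with names among `infection`, `sepsis`,
#'   `inf_given_sepsis`, `ab_given_infection`, `ab_given_inf_sepsis`.
#' @return Tibble of class `probability_sets` with columns `p_*` and,
#'   where counts were supplied, `k_*`/`n_*`.
#' @examples
#' probability_set(
#'   p_infection = 0.04, p_sepsis = 0.000012,
#'   p_inf_given_sepsis = 76 / 500, p_ab_given_infection = 0.61,
#'   p_ab_given_inf_sepsis = 24 / 76
#' )
#' @export
probability_set <- function(p_infection = NULL, p_sepsis = NULL,
                            p_inf_given_sepsis = NULL,
                            p_ab_given_infection = NULL,
                            p_ab_given_inf_sepsis = NULL,
                            counts = NULL) {
  vals <- list(infection = p_infection, sepsis = p_sepsis,
               inf_given_sepsis = p_inf_given_sepsis,
               ab_given_infection = p_ab_given_infection,
               ab_given_inf_sepsis = p_ab_given_inf_sepsis)
  out <- list()
  for (nm in names(vals)) {
    p <- vals[[nm]]
    kn <- counts[[nm]]
    if (is.null(p) && is.null(kn)) {
      abort(sprintf("Provide `p_%s` or counts$%s.", nm, nm),
            class = "sepsisnnt_config_error")
    }
    if (!is.null(kn)) {
      kn <- matrix(kn, ncol = 2)
      if (any(kn[, 1] > kn[, 2]) || any(kn < 0)) {
        abort(sprintf("counts$%s must satisfy 0 <= k <= n.", nm),
              class = "sepsisnnt_config_error")
      }
      out[[paste0("k_", nm)]] <- kn[, 1]
      out[[paste0("n_", nm)]] <- kn[, 2]
      if (is.null(p)) p <- kn[, 1] / kn[, 2]
    }
    assert_prob(p, paste0("p_", nm))
    out[[paste0("p_", nm)]] <- p
  }
  out <- as_tibble(out[c(
    prob_fields,
    intersect(c(paste0("k_", names(vals)), paste0("n_", names(vals))),
              names(out))
  )])
  class(out) <- c("probability_sets", class(out))
  out
}

#' P(Sepsis | Infection) by Bayes' theorem
#'
#' @param p A `probability_sets` tibble (or any tibble with the `p_*`
#'   columns).
#' @return Numeric vector `p_inf_given_sepsis * p_sepsis / p_infection`.
#'   Errors (rather than silently clipping) if any result exceeds 1, and on
#'   `p_infection = 0`.
#' @export
sepsis_given_infection <- function(p) {
  required_cols(p, c("p_infection", "p_sepsis", "p_inf_given_sepsis"), "p")
  if (any(p$p_infection == 0)) {
    abort("`p_infection` must be positive (division by P(Infection)).",
          class = "sepsisnnt_domain_error")
  }
  out <- p$p_inf_given_sepsis * p$p_sepsis / p$p_infection
  if (any(out > 1)) {
    abort("P(Sepsis|Infection) exceeds 1; inputs are inconsistent.",
          class = "sepsisnnt_domain_error")
  }
  out
}

#' Arm-specific sepsis probability
#'
#' @param p A `probability_sets` tibble.
#' @param arm `"ab"` or `"no_ab"`.
#' @return Numeric vector: for the antibiotic arm,
#'   `p_ab_given_inf_sepsis * P(Sepsis|Infection) / p_ab_given_infection`;
#'   for the no-antibiotic arm the complements are used.
#' @export
sepsis_given_arm <- function(p, arm = c("no_ab", "ab")) {
  arm <- match.arg(arm)
  required_cols(p, c(prob_fields), "p")
  psi <- sepsis_given_infection(p)
  if (arm == "ab") {
    if (any(p$p_ab_given_infection == 0)) {
      abort("Zero denominator P(AB|Infection) in the antibiotic arm.",
            class = "sepsisnnt_domain_error")
    }
    p$p_ab_given_inf_sepsis * psi / p$p_ab_given_infection
  } else {
    if (any(p$p_ab_given_infection == 1)) {
      abort("Zero denominator 1 - P(AB|Infection) in the no-antibiotic arm.",
            class = "sepsisnnt_domain_error")
    }
    (1 - p$p_ab_given_inf_sepsis) * psi / (1 - p$p_ab_given_infection)
  }
}

#' Number needed to treat
#'
#' Reciprocal of the risk difference between the no-antibiotic and antibiotic
#' arms. A non-positive difference is not an error: the result carries the
#' raw difference and an `effect` label, with `nnt = Inf` as the
#' censored-at-infinity sentinel for both the no-effect and harm cases.
#'
#' @param p_no_ab,p_ab Arm probabilities in \[0, 1\].
#' @return Tibble `risk_difference`, `nnt`, `effect`
#'   (benefit / no_effect / harm).
#' @examples
#' nnt(0.004647, 0.000833) # NNT 262.2
#' @export
nnt <- function(p_no_ab, p_ab) {
  assert_prob(p_no_ab, "p_no_ab")
  assert_prob(p_ab, "p_ab")
  rd <- p_no_ab - p_ab
  tibble(
    risk_difference = rd,
    nnt = dplyr::if_else(rd > 0, 1 / rd, Inf),
    effect = case_when(rd > 0 ~ "benefit", rd == 0 ~ "no_effect",
                       TRUE ~ "harm")
  )
}

risk_quantities <- c("p_sepsis_given_infection", "p_sepsis_no_ab",
                     "p_sepsis_ab", "nnt")

# Substream seed for one stratum: a hash of the shared seed and the
# stratum's probability/count content, so identical strata receive identical
# substreams wherever they sit in the batch. NULL seed stays NULL (ambient
# RNG stream).
stratum_seed <- function(seed, content) {
  if (is.null(seed)) return(NULL)
  strtoi(substr(hash(list(seed, as.list(content))), 1, 7), base = 16L)
}

# Evaluate the chain on a tibble/list with the five p_ fields; returns a
# tibble of the four derived quantities. Used for both the plug-in values and
# the per-draw evaluation.
evaluate_chain <- function(p) {
  psi <- p$p_inf_given_sepsis * p$p_sepsis / p$p_infection
  psi <- pmin(psi, 1)
  no_ab <- (1 - p$p_ab_given_inf_sepsis) * psi / (1 - p$p_ab_given_infection)
  ab <- p$p_ab_given_inf_sepsis * psi / p$p_ab_given_infection
  rd <- no_ab - ab
  tibble(
    p_sepsis_given_infection = psi,
    p_sepsis_no_ab = no_ab,
    p_sepsis_ab = ab,
    risk_difference = rd,
    nnt = dplyr::if_else(rd > 0, 1 / rd, Inf)
  )
}

#' Monte Carlo uncertainty for one stratum
#'
#' Draws every input probability from its beta posterior (Jeffreys
#' `Beta(k + 1/2, n - k + 1/2)` by default, or uniform-prior
#' `Beta(k + 1, n - k + 1)`), evaluates the decision-tree chain per draw, and
#' summarises each derived quantity by its median and 2.5th/97.5th
#' percentiles. Draws with non-positive risk difference enter the NNT
#' distribution as `Inf` (censored at infinity); their fraction is reported
#' in `frac_nonpositive_rd`.
#'
#' @param p A one-row `probability_sets` with counts for all five inputs.
#' @param n_draws Number of draws (default 10000; fewer than 100 warns).
#' @param seed Optional seed.
#' @param prior `"jeffreys"` or `"uniform"` beta prior.
#' @param return_draws Keep the matrix of per-draw input and derived values?
#' @return Object of class `sepsis_risk`: list with `estimates` (tibble
#'   `quantity`, `plugin`, `estimate` (median), `lower`, `upper`), `inputs`,
#'   `n_draws`, `seed`, `prior`, `frac_nonpositive_rd`, and optionally
#'   `draws`.
#' @export
draw_uncertainty <- function(p, n_draws = 10000, seed = NULL,
                             prior = c("jeffreys", "uniform"),
                             return_draws = FALSE) {
  prior <- match.arg(prior)
  if (nrow(p) != 1L) {
    abort("`p` must be a single stratum (one row); see estimate_all_strata().",
          class = "sepsisnnt_config_error")
  }
  kcols <- paste0("k_", c("infection", "sepsis", "inf_given_sepsis",
                          "ab_given_infection", "ab_given_inf_sepsis"))
  ncols <- sub("^k_", "n_", kcols)
  if (!all(c(kcols, ncols) %in% names(p))) {
    abort("Counts (k_*, n_*) are required for every input probability.",
          class = "sepsisnnt_config_error")
  }
  if (n_draws < 100) {
    warn("Fewer than 100 draws gives unstable uncertainty intervals.")
  }
  if (p$p_infection == 0 || p$p_ab_given_infection %in% c(0, 1)) {
    abort("Need p_infection > 0 and p_ab_given_infection in (0, 1).",
          class = "sepsisnnt_domain_error")
  }
  a0 <- if (prior == "jeffreys") 0.5 else 1

  draws <- with_seed_maybe(seed, {
    d <- purrr::map2(kcols, ncols, function(kc, nc) {
      k <- p[[kc]]
      n <- p[[nc]]
      rbeta(n_draws, k + a0, pmax(n - k, 0) + a0)
    })
    names(d) <- prob_fields
    as_tibble(d)
  })

  chain <- evaluate_chain(draws)
  plugin <- evaluate_chain(p)

  qs <- purrr::map(risk_quantities, function(qn) {
    x <- chain[[qn]]
    tibble(
      quantity = qn,
      plugin = plugin[[qn]],
      estimate = median(x),
      lower = quantile(x, 0.025, names = FALSE),
      upper = quantile(x, 0.975, names = FALSE)
    )
  }) |> list_rbind()

  structure(list(
    estimates = qs,
    inputs = p,
    n_draws = n_draws,
    seed = seed,
    prior = prior,
    frac_nonpositive_rd = mean(chain$risk_difference <= 0),
    draws = if (return_draws) list(inputs = draws, chain = chain)
  ), class = "sepsis_risk")
}

#' @export
print.sepsis_risk <- function(x, ...) {
  cat(sprintf("<sepsis_risk> %d beta draws (%s prior)\n", x$n_draws, x$prior))
  print(x$estimates)
  if (x$frac_nonpositive_rd > 0) {
    cat(sprintf("%.1f%% of draws had non-positive risk difference (NNT censored at Inf)\n",
                100 * x$frac_nonpositive_rd))
  }
  invisible(x)
}

#' Estimate all strata
#'
#' Runs [draw_uncertainty()] on every row of a `probability_sets` tibble.
#' Reproducibility uses one shared seed: per-stratum substream seeds are
#' drawn once from `seed`, so identical strata receive identical substreams
#' in identical positions. A failing stratum does not abort the batch; its
#' row is returned with NA estimates and the error message in `note`.
#'
#' @param prob_sets A `probability_sets` tibble; non-`p_*`/count columns are
#'   treated as stratum identifiers and carried through.
#' @inheritParams draw_uncertainty
#' @return Tibble of class `sepsis_risk_tbl`: identifier and input columns,
#'   then for each derived quantity its median, `*_lower`, `*_upper` and
#'   `*_plugin`, plus `frac_nonpositive_rd` and `note`.
#' @export
estimate_all_strata <- function(prob_sets, n_draws = 10000, seed = NULL,
                                prior = c("jeffreys", "uniform")) {
  prior <- match.arg(prior)
  n <- nrow(prob_sets)

  id_cols <- setdiff(names(prob_sets),
                     grep("^(p|k|n)_", names(prob_sets), value = TRUE))

  if (n == 0L) {
    qcols <- c(risk_quantities, paste0(risk_quantities, "_plugin"),
               paste0(risk_quantities, "_lower"),
               paste0(risk_quantities, "_upper"))
    empty <- dplyr::bind_cols(
      as_tibble(prob_sets),
      as_tibble(setNames(rep(list(numeric()), length(qcols)), qcols)),
      tibble(frac_nonpositive_rd = numeric(), note = character())
    )
    attr(empty, "n_draws") <- n_draws
    attr(empty, "prior") <- prior
    attr(empty, "id_cols") <- id_cols
    class(empty) <- c("sepsis_risk_tbl", class(empty))
    return(empty)
  }

  rows <- purrr::map(seq_len(n), function(i) {
    row <- prob_sets[i, ]
    res <- tryCatch(
      draw_uncertainty(row, n_draws = n_draws,
                       seed = stratum_seed(seed, row[setdiff(names(row),
                                                             id_cols)]),
                       prior = prior),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      est <- tibble(quantity = risk_quantities, plugin = NA_real_,
                    estimate = NA_real_, lower = NA_real_, upper = NA_real_)
      frac <- NA_real_
      note <- conditionMessage(res)
    } else {
      est <- res$estimates
      frac <- res$frac_nonpositive_rd
      note <- NA_character_
    }
    wide <- est |>
      pivot_longer(c("plugin", "estimate", "lower", "upper"),
                   names_to = ".stat") |>
      mutate(col = dplyr::case_match(
        .data$.stat,
        "estimate" ~ .data$quantity,
        "plugin" ~ paste0(.data$quantity, "_plugin"),
        .default = paste0(.data$quantity, "_", .data$.stat)
      )) |>
      select("col", "value") |>
      tidyr::pivot_wider(names_from = "col", values_from = "value")
    bind_rows(list(dplyr::bind_cols(
      row, wide, tibble(frac_nonpositive_rd = frac, note = note)
    )))
  }) |> list_rbind()

  attr(rows, "n_draws") <- n_draws
  attr(rows, "prior") <- prior
  attr(rows, "seed") <- seed
  attr(rows, "id_cols") <- id_cols
  class(rows) <- c("sepsis_risk_tbl", class(rows))
  rows
}
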