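# Decision-tree chain, NNT, and the Monte Carlo uncertainty procedure.

test_that("the Bayes chain reproduces hand arithmetic from published inputs", {
  # men 85+: 0.26 x 0.000416 / 0.05
  p_m85 <- probability_set(p_infection = 0.05, p_sepsis = 0.000416,
                           p_inf_given_sepsis = 0.26,
                           p_ab_given_infection = 0.61,
                           p_ab_given_inf_sepsis = 158 / 713)
  expect_equal(sepsis_given_infection(p_m85), 0.0021632, tolerance = 1e-10)

  # women 15-24: 0.15 x 0.000012 / 0.04
  p_f15 <- probability_set(p_infection = 0.04, p_sepsis = 0.000012,
                           p_inf_given_sepsis = 0.15,
                           p_ab_given_infection = 0.61,
                           p_ab_given_inf_sepsis = 24 / 76)
  expect_equal(sepsis_given_infection(p_f15), 0.000045, tolerance = 1e-10)

  # zero numerator propagates to zero
  p0 <- probability_set(p_infection = 0.05, p_sepsis = 0.001,
                        p_inf_given_sepsis = 0,
                        p_ab_given_infection = 0.5,
                        p_ab_given_inf_sepsis = 0.5)
  expect_equal(sepsis_given_infection(p0), 0)

  # domain errors: zero P(Infection); result above one
  expect_error(
    sepsis_given_infection(p0 |> dplyr::mutate(p_infection = 0)),
    class = "sepsisnnt_domain_error"
  )
  expect_error(
    sepsis_given_infection(probability_set(
      p_infection = 0.001, p_sepsis = 0.5, p_inf_given_sepsis = 0.9,
      p_ab_given_infection = 0.5, p_ab_given_inf_sepsis = 0.5
    )),
    class = "sepsisnnt_domain_error"
  )
})

test_that("arm probabilities split P(Sepsis|Infection) by prescribing status", {
  p <- probability_set(p_infection = 0.04, p_sepsis = 0.000012,
                       p_inf_given_sepsis = 76 / 500,
                       p_ab_given_infection = 0.61,
                       p_ab_given_inf_sepsis = 24 / 76)
  expect_equal(round(sepsis_given_arm(p, "no_ab"), 6), 0.000080)
  expect_equal(round(sepsis_given_arm(p, "ab"), 6), 0.000024)

  # independence case: both arms equal P(Sepsis|Infection)
  pi_ <- probability_set(p_infection = 0.05, p_sepsis = 0.0002,
                         p_inf_given_sepsis = 0.2,
                         p_ab_given_infection = 0.6,
                         p_ab_given_inf_sepsis = 0.6)
  psi <- sepsis_given_infection(pi_)
  expect_equal(sepsis_given_arm(pi_, "ab"), psi, tolerance = 1e-12)
  expect_equal(sepsis_given_arm(pi_, "no_ab"), psi, tolerance = 1e-12)

  # zero denominators identify the arm
  expect_error(
    sepsis_given_arm(pi_ |> dplyr::mutate(p_ab_given_infection = 1), "no_ab"),
    "no-antibiotic", class = "sepsisnnt_domain_error"
  )
  expect_error(
    sepsis_given_arm(pi_ |> dplyr::mutate(p_ab_given_infection = 0), "ab"),
    class = "sepsisnnt_domain_error"
  )
})

test_that("NNT is the reciprocal risk difference with sentinels", {
  expect_equal(nnt(0.004647, 0.000833)$nnt, 262.1919, tolerance = 1e-4)
  expect_equal(round(nnt(0.004647, 0.000833)$nnt), 262)
  expect_equal(nnt(0.002700, 0.000478)$nnt, 450.045, tolerance = 1e-4)

  same <- nnt(0.001, 0.001)
  expect_equal(same$effect, "no_effect")
  expect_true(is.infinite(same$nnt))
  expect_equal(same$risk_difference, 0)

  harm <- nnt(0.001, 0.002)
  expect_equal(harm$effect, "harm")
  expect_equal(harm$risk_difference, -0.001)
  expect_true(is.infinite(harm$nnt))

  # strictly decreasing in the risk difference
  rd <- seq(1e-5, 1e-2, length.out = 50)
  out <- nnt(rd, 0)$nnt
  expect_true(all(diff(out) < 0))
})

test_that("beta draws match closed-form quantiles and concentrate with n", {
  # all counts 1 of 2 with the Jeffreys prior: every input is Beta(1.5, 1.5)
  p12 <- probability_set(counts = list(
    infection = c(1, 2), sepsis = c(1, 2), inf_given_sepsis = c(1, 2),
    ab_given_infection = c(1, 2), ab_given_inf_sepsis = c(1, 2)
  ))
  r <- draw_uncertainty(p12, n_draws = 20000, seed = 8, return_draws = TRUE)
  x <- r$draws$inputs$p_infection
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(unname(quantile(x, probs)), qbeta(probs, 1.5, 1.5),
               tolerance = 0.02)
  # uniform prior alternative: Beta(2, 2)
  ru <- draw_uncertainty(p12, n_draws = 20000, seed = 8, prior = "uniform",
                         return_draws = TRUE)
  expect_equal(unname(quantile(ru$draws$inputs$p_infection, probs)),
               qbeta(probs, 2, 2), tolerance = 0.02)

  # concentration limit: huge counts collapse the interval onto the plug-in
  big <- probability_set(counts = list(
    infection = c(4e7, 1e9), sepsis = c(2e5, 1e9),
    inf_given_sepsis = c(5e7, 2e8), ab_given_infection = c(6e8, 1e9),
    ab_given_inf_sepsis = c(3e7, 1e8)
  ))
  rb <- draw_uncertainty(big, n_draws = 2000, seed = 9)
  est <- rb$estimates
  nb <- est[est$quantity == "p_sepsis_no_ab", ]
  expect_lt((nb$upper - nb$lower) / nb$estimate, 0.01)
  expect_equal(nb$estimate, nb$plugin, tolerance = 1e-3)

  # fewer than 100 draws warns; missing counts error
  expect_warning(draw_uncertainty(p12, n_draws = 50, seed = 1), "100")
  no_counts <- probability_set(p_infection = 0.1, p_sepsis = 0.001,
                               p_inf_given_sepsis = 0.2,
                               p_ab_given_infection = 0.5,
                               p_ab_given_inf_sepsis = 0.5)
  expect_error(draw_uncertainty(no_counts), class = "sepsisnnt_config_error")
})

test_that("the plug-in chain equals the mean-count evaluation", {
  ps <- published_prob_sets()
  row <- ps[ps$gender == "male" & ps$age_band == "85+", ]
  r <- draw_uncertainty(row, n_draws = 500, seed = 2)
  est <- r$estimates
  psi <- sepsis_given_infection(row)
  expect_equal(est$plugin[est$quantity == "p_sepsis_given_infection"], psi)
  expect_equal(est$plugin[est$quantity == "p_sepsis_no_ab"],
               sepsis_given_arm(row, "no_ab"))
  expect_equal(est$plugin[est$quantity == "nnt"],
               nnt(sepsis_given_arm(row, "no_ab"),
                   sepsis_given_arm(row, "ab"))$nnt)
})

test_that("stratified estimation is reproducible and matches per-stratum runs", {
  ps <- published_prob_sets()
  two <- ps[c(10, 10), ]  # identical strata
  est2 <- estimate_all_strata(two, n_draws = 400, seed = 31)
  expect_equal(est2$nnt[1], est2$nnt[2])
  expect_equal(est2$nnt_lower[1], est2$nnt_lower[2])

  # elementwise oracle: re-run each stratum with its substream seed
  est <- estimate_all_strata(ps[1:4, ], n_draws = 400, seed = 5)
  for (i in 1:4) {
    content <- ps[i, grep("^(p|k|n)_", names(ps), value = TRUE)]
    single <- draw_uncertainty(ps[i, ], n_draws = 400,
                               seed = sepsisnnt:::stratum_seed(5, content))
    expect_equal(est$nnt[i],
                 single$estimates$estimate[
                   single$estimates$quantity == "nnt"])
  }

  # a failing stratum is reported, not fatal
  broken <- ps[1:2, ]
  broken$p_infection[2] <- 0
  estb <- estimate_all_strata(broken, n_draws = 200, seed = 1)
  expect_true(is.na(estb$nnt[2]))
  expect_match(estb$note[2], "p_infection")
  expect_false(is.na(estb$nnt[1]))
})

test_that("plug-in NNT decreases with age from the 5-14 band onward", {
  est <- estimate_all_strata(published_prob_sets(), n_draws = 200, seed = 17)
  for (g in c("male", "female")) {
    x <- est$nnt_plugin[est$gender == g]
    expect_true(all(diff(x[-1]) < 0))
  }
})
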