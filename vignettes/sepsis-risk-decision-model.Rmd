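---
title: "Estimating sepsis risk after infection consultations and the antibiotic NNT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sepsis risk after infection consultations and the antibiotic NNT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisnnt)
library(dplyr)
```

## The question and the model

When a patient consults primary care with a common infection — a respiratory
tract infection (RTI), a skin infection, or an uncomplicated urinary tract
infection (UTI) — the clinician decides whether to prescribe an antibiotic.
Sepsis within the following 30 days is a rare but serious outcome, and the
trade-off between antimicrobial stewardship and patient safety turns on how
rare: how many prescriptions would need to be issued to prevent one sepsis
event (the number needed to treat, NNT), and how strongly that number depends
on age, gender and frailty.

Routinely collected electronic health records can answer this without
randomisation, at the cost of an observational design. The model is a
decision tree populated by five stratum-level probabilities, all estimable
from an EHR database:

* `P(Infection)` — probability of an infection consultation in a 30-day
  period, taken as the consultation rate per 30 days (rate and probability
  are interchangeable at these magnitudes; the conversion is documented
  because it is an approximation);
* `P(AB | Infection)` — probability that the consultation carries a same-day
  antibiotic prescription;
* `P(Sepsis)` — probability of a first sepsis event per 30 days of
  person-time;
* `P(Infection | Sepsis)` — fraction of sepsis cases with an infection
  consultation in the 30 days before the event;
* `P([AB|Infection] | Sepsis)` — among those linked consultations, the
  fraction with a same-date antibiotic.

Bayes' theorem then gives the quantities of interest:

$$
P(\mathrm{Sepsis}\mid \mathrm{Infection})
  = \frac{P(\mathrm{Infection}\mid \mathrm{Sepsis})\,P(\mathrm{Sepsis})}
         {P(\mathrm{Infection})},
$$

split by prescribing status:

$$
P(\mathrm{Sepsis}\mid \mathrm{AB\ arm})
  = \frac{P([\mathrm{AB|Inf}]\mid \mathrm{Sepsis})\,
          P(\mathrm{Sepsis}\mid \mathrm{Infection})}
         {P(\mathrm{AB}\mid \mathrm{Infection})},
\qquad
P(\mathrm{Sepsis}\mid \mathrm{no\mbox{-}AB\ arm})
  = \frac{(1 - P([\mathrm{AB|Inf}]\mid \mathrm{Sepsis}))\,
          P(\mathrm{Sepsis}\mid \mathrm{Infection})}
         {1 - P(\mathrm{AB}\mid \mathrm{Infection})},
$$

and the NNT is the reciprocal of their difference. The split satisfies the
law of total probability exactly — the package asserts this per Monte Carlo
draw — and the estimator makes no severity adjustment: prescribing is not
randomised, so confounding by indication biases the NNT upward, which is a
limitation of the design, not of the implementation.

```{r worked}
d <- uk_sepsis_strata() |> filter(gender == "female", age_band == "15-24")
p <- probability_set(
  p_infection = d$p_infection, p_sepsis = d$p_sepsis,
  p_inf_given_sepsis = d$prior_infection_30d / d$sepsis_events,
  p_ab_given_infection = d$p_ab_given_infection,
  p_ab_given_inf_sepsis = d$same_date_ab / d$prior_infection_30d
)
c(no_ab = sepsis_given_arm(p, "no_ab"), ab = sepsis_given_arm(p, "ab"))
```

Note the conditional probabilities enter as count ratios (76/500, 24/76),
not as their 2-decimal roundings: the published derived values reproduce
exactly at 6-decimal rounding only on the count scale, which is also the
scale on which the beta draws operate.

## Uncertainty

Each input probability carries a numerator and denominator: a count of
events over a count of trials (for the two per-30-day probabilities, the
"trials" are person-time expressed in 30-day units, so the denominator need
not be an integer). For probabilistic sensitivity analysis every input is
drawn from its beta posterior — Jeffreys `Beta(k + 1/2, n - k + 1/2)` by
default, with the uniform-prior `Beta(k + 1, n - k + 1)` as an option — the
chain is evaluated per draw, and each derived quantity is summarised by the
median of 10,000 draws with a 95% uncertainty interval at the 2.5th and
97.5th percentiles. Choices worth stating explicitly:

* the five inputs are drawn independently — no correlation structure is
  imposed;
* the central estimate is the median of draws; the plug-in value is reported
  alongside (`*_plugin` columns) and equals the deterministic chain;
* draws with a non-positive risk difference are propagated to the NNT
  distribution as censored at infinity and their fraction is reported
  (`frac_nonpositive_rd`), rather than being dropped or made negative;
* Jeffreys was preferred as the default because it is better behaved at the
  small linked-case counts seen in the youngest strata;
* display rounding follows the publication conventions: derived
  probabilities to 6 decimals, NNT to the nearest integer.

Per-stratum runs draw their substream seed from a hash of the shared seed
and the stratum's own counts, so results are reproducible and identical
strata yield identical estimates regardless of position in the batch.

## Cohort extraction conventions

* **Follow-up** runs from the latest of (registration start + 1 year, the
  practice's up-to-standard date, study start) to the earliest of
  (registration end, death, study end), with the inclusive-day convention
  `(end - start + 1)/365.25`; empty intervals are kept with zero
  person-years rather than dropped.
* **Incident events only**: the chronologically first in-interval sepsis
  code per patient. Recurrences are never counted. By default an earlier
  out-of-interval code does not suppress a later in-interval one (EHRs often
  restate history); `suppress_prevalent = TRUE` flips this.
* **Look-back window**: a consultation precedes a sepsis event when it lies
  strictly inside the open interval `(sepsis - W, sepsis)` with `W = 30`
  days (60 in sensitivity analyses). A consultation on the sepsis date
  itself is ambiguous (which was coded first?) and is excluded; so is one
  exactly `W` days before. When several consultations qualify, the most
  recent — the clinically proximate exposure — defines infection type and
  same-date antibiotic status; prescriptions elsewhere in the window are
  counted (`n_ab_window`) but do not define exposure.
* **Ages** are fixed at the start of each calendar year
  (`floor((Jan 1 - birth)/365.25)`, clamped at 0), for events and for
  person-time alike, so each person-day and each case lands in exactly one
  band and stratum person-years sum to the cohort total exactly.
* **Multiple sources**: sepsis streams from primary care, hospital
  admissions and mortality records are merged as a per-patient union with
  same-day deduplication (primary care taking precedence), and the first
  event across sources defines the incident date.

## Frailty

The 36-deficit electronic frailty index is computed per patient per calendar
year; deficits are cumulative, so the index is non-decreasing within a
patient. The category cut points are not restated in the source tables, so
the package adopts the published eFI convention — index ≤ 0.12 nonfrail,
(0.12, 0.24] mild, (0.24, 0.36] moderate, > 0.36 severe — and exposes them
as a parameter. The 36 deficits are an abstract slot map (`EFI01` ...
`EFI36` by default) because the licensed code dictionaries cannot be
redistributed; real code lists plug in via `slot_map`. Frailty is
conventionally evaluated from age 55. Because the full-population
denominator carries no frailty, stratum person-years are allocated to
categories using the proportions observed in the prescribing sample, with a
largest-remainder correction so the allocation conserves person-years to
machine precision.

## The sampling design

Consultation and prescribing rates come from a stratified random sample: in
each study year, `per_stratum_n = 10` patients per family practice, gender
and five-year age band (to 104), drawn without replacement from everyone
registered in that year; a stratum smaller than 10 is taken whole. Each
sampled patient-year contributes its follow-up days within that year.
Counts are pooled across years and practices within gender and analysis age
band — the pooled-count estimator with the design's equal allocation per
practice-year, which is how "equal weight per practice and year" is realised
here — and `estimate_rates()` flags, rather than zeroes, strata with no
person-time. Age-standardised aggregates (`standardize_rates()`) use equal
band weights unless external weights are supplied.

Because it divides pooled event counts by pooled person-time, the estimator
is a ratio estimator: consistent, with a finite-sample bias of order `1/n`
that is negligible at the design allocation (measured well below 0.1% of
the rate in the test suite) but never exactly zero — which is why the
unbiasedness check asserts a tight relative-bias bound rather than exact
equality in expectation.

## The synthetic cohort generator

No public EHR stands behind this analysis — the source database is
access-restricted — so the package ships a generator that emulates its
structure: registration intervals (a configurable fraction truncated by
death or deregistration), dated coded events for RTI/skin/UTI/sepsis,
same-day antibiotic prescriptions, practice identifiers, and accumulating
frailty deficits. The generative model is deliberately the simplest under
which the five estimands are well defined and exactly recoverable:

* consultations arise as a Poisson process at a per-stratum rate per
  30 days, split across infection types (default shares 0.60/0.25/0.15 for
  RTI/skin/UTI, reflecting their relative consultation frequency);
* each consultation is prescribed same-day with the stratum's probability;
* sepsis follows a piecewise-constant daily hazard: baseline `h/30`,
  multiplied by `m_no_ab` or `m_ab` on days strictly inside the
  post-consultation window of the most recent consultation — the same open
  interval the analysis uses, so generator and estimator agree about the
  estimand by construction;
* ages are fixed at the start of each simulated calendar year, and the
  calendar granularity is days;
* deficits accrue at `0.02 · exp(0.045 · age)` per person-year over the 36
  slots, chosen so that patients under 55 are mostly nonfrail while the
  oldest bands are predominantly moderately or severely frail.

The default parameters are calibrated by exact inversion of the generator's
closed-form ground truth to the packaged published strata
(`uk_sepsis_strata()`), so the default simulation *is* the published study's
probability structure; `sim_ground_truth()` returns the implied values of
every input and derived quantity, including the no-effect sentinel when the
two multipliers coincide. Because the per-stratum person-year denominators
of the source study are unpublished, the generator is calibrated only to
the printed probabilities, not to the true stratum sizes.

What the generator does **not** emulate — and therefore what passing
parameter-recovery tests do and do not show — matters: there is no
confounding by indication (prescribing is independent of unobserved
severity), no miscoding or missed consultations, no out-of-practice
prescribing, no regional variation, and no secular trend unless the
optional per-year sepsis multiplier is set. Recovery of ground truth
demonstrates that the estimator chain is correct under the stated model,
not that the observational biases of real records are absent.

## Verification sizes and numerical choices

The test-suite checks are sized so the whole suite runs comfortably on one
CPU, as the package's own choice of verification scale:

* distributional checks use exact binomial/Poisson tail bounds
  (family-wise 99%) on cohorts of 3,000-10,000 patients;
* the parameter-recovery check simulates roughly 5 × 10⁵ follow-up
  person-years at known hazards and requires the pipeline estimates of both
  arm probabilities to sit within |z| < 3 of ground truth, with z scored
  against the posterior draw spread;
* interval coverage uses 200 replicates of a ~12,000 person-year cohort
  with proportionally raised hazards (so each replicate has informative
  counts) at 1,000 draws, requiring ≥ 90% coverage of the true arm
  probabilities — the slack below the nominal 95% absorbs Monte Carlo error
  and the small first-event depletion bias (a few percent) that the
  closed-form truth ignores;
* the bracketing check on the oldest male stratum uses the published
  population-side counts with synthetic sample-side denominators of the
  design's order of magnitude (2 × 10⁵ sampled 30-day units, 10⁴ sampled
  consultations); published intervals cannot be reproduced exactly because
  those denominators are unpublished, so the check asserts only that the
  10,000-draw median falls inside the published interval.

Degenerate inputs are handled explicitly rather than numerically: zero
`P(Infection)` and boundary `P(AB|Infection)` raise domain errors naming
the offending quantity; a chain value above 1 is an error, never a silent
clip (per-draw values are clipped at 1 with the event counted, since a
posterior draw can legitimately graze the boundary); same-day consultation
ties break deterministically toward the higher-risk infection type; and
strata that cannot be estimated (no linked cases, no person-time) are
dropped with a warning at assembly, or carried as flagged NA rows through
`estimate_all_strata()` when the failure happens at draw time.

## Known limitations

The NNT inherits every bias of non-randomised prescribing data, most
importantly confounding by severity. The rate-to-probability conversion
(rate × 30 days) slightly overstates `P(Infection)` at the highest
consultation rates. The sampling estimator weights practice-years equally
rather than by practice size. The frailty index is applied from age 55
including the 55-64 range where deficit recording is thinner, with no
adjustment. None of these are resolved here; they bound the
interpretation, and the package's outputs should be read as
population-average decision-support estimates, not individual risks.
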