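---
title: "Methods: cost-benefit and probabilistic sensitivity analysis for e-consult platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-benefit and probabilistic sensitivity analysis for e-consult platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(econsultCBA)
```

## The model

`econsultCBA` evaluates a provider-to-provider virtual consultation
platform from the healthcare payer's point of view: only costs and savings
borne by the system that funds care are counted; patient travel or time
savings, and downstream clinical benefits such as earlier diagnosis, are
out of scope.

**Encounter cost.** Under a fee-for-service schedule, a clinical service is
paid as its Medical Service Unit (MSU) weight times the provincial rate per
MSU. One virtual encounter bills two coded services — the requesting
physician's call (11.5 MSU) and the specialist's call-back (25 MSU) — so at
the default rate of $2.68/MSU an encounter costs

$$c = (11.5 + 25) \times 2.68 = \$97.82,$$

paid whether or not the consult averts a referral. All money is 2022
Canadian dollars.

**Benefit of an averted referral.** If a consult in specialty $s$ replaces
an in-person referral, the payer avoids that specialty's comprehensive
consultation fee $f_s$ but has still paid $c$, so the net saving is
$f_s - c$. With $n_s$ consults in specialty $s$ and an avoidance
proportion $\pi$ (estimated from the post-consultation survey as a binomial
proportion), total benefit is

$$B = \sum_s n_s \, \pi \, (f_s - c).$$

Avoided-referral counts $n_s \pi$ are deliberately kept unrounded inside
all monetary arithmetic; rounding happens once, at display.

**Costs.** Implementation costs are a one-time onboarding fee per
specialist group (default mean $1,265, SD $230) booked at month zero, plus
an ongoing monthly license (default $10,000) over the analysis horizon. An
annual opportunity cost of capital $r$ (default 7%) can discount the
ongoing fees with monthly compounding, month $m$ weighted by
$(1+r)^{-m/12}$; onboarding at month zero is undiscounted. This convention
is one of several defensible readings of "including" a cost of capital, so
it is switch-controlled (`discounting_enabled`) rather than hard-wired.

**Point metrics.** Net benefit $B - C$, benefit-cost ratio $B / C$, return
on investment $(B - C)/C$; `cba_point()` computes these exactly before any
display rounding, so $\mathrm{BCR} - \mathrm{ROI} = 1$ identically.

## Probabilistic sensitivity analysis

Each uncertain input is given a parametric distribution calibrated by
method of moments: gamma for costs and monetary benefits
($k = (\mu/\sigma)^2$, $\theta = \sigma^2/\mu$), beta for proportions
($\nu = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu\nu$,
$\beta = (1-\mu)\nu$), or a degenerate point mass. The SD of each input is
taken, in order of precedence, from a stated SD, from a published 95% CI
via the normal-width rule $\sigma = (\mathrm{hi}-\mathrm{lo})/3.92$, or —
only when nothing better exists — from a fallback of 10% of the mean.
Proportions with known survey denominators use the binomial standard error
instead of the 10% rule.

The Monte Carlo engine (`run_psa()`, default 1,000 iterations) samples
every input per draw, evaluates the model, and summarises each metric by
its mean over draws and an empirical 95% percentile interval (2.5th/97.5th
percentiles with linear interpolation between order statistics,
`stats::quantile()` type 7). Benefits and costs are sampled independently;
no correlation structure is imposed.

**Mean of ratios, not ratio of means.** The headline ROI and BCR are means
of the per-draw ratios. Because the cost appears in the denominator,
Jensen's inequality makes this estimator strictly exceed the ratio of
means whenever cost variance is positive — with the reference-case
calibration, $E[B/C] \approx 2.78$ against $\mu_B/\mu_C \approx 2.69$.
Both are reported (`run_psa()` and `cba_point()` respectively); the
mean-of-ratios convention is the package's headline because it is the one
consistent with reporting a net benefit as a difference of means alongside
ratio estimates that exceed the ratio of those means, the pattern seen in
published evaluations of this kind.

**Reproducibility.** All randomness flows from one master seed. Each named
quantity draws from a substream seeded by a deterministic hash of
(master seed, quantity name), so adding a quantity to a specification
never perturbs the draws of the others, and a cost multiplier of 1
reproduces the reference run bit for bit. The one-way scenario multiplies
each *sampled* cost by a fixed factor (doubling, by default) after
sampling, leaving all other draws untouched.

## The reference case

`inst/extdata/reference_case.json` carries the calibration moments of a
provincial e-consult feasibility evaluation: mean benefit $389,439
(95% CI $331,417–$451,226$), mean cost $145,020 (95% CI
$100,014–$203,922$), an avoidance proportion of 511/608, and 6,072
completed consults. Two quantities deserve comment:

- The cost mean cannot be decomposed into its timeline from public
  information (nineteen months of licensing alone would exceed it, so the
  license evidently ramped up with adoption). The engine therefore treats
  the cost timeline (groups, months, discounting) as configuration, and
  the reference-case PSA calibrates the gamma distribution directly to the
  published cost moments rather than to a reconstructed ledger.
- $0.84 \times 6{,}072 = 5{,}100.48$, which rounds to 5,100, while the
  published count of referrals avoided is 5,101 — consistent with
  per-specialty rounding before summation or a slightly different consult
  total. `referrals_avoided()` keeps the unrounded total and rounds only
  for display; the two conventions differ by at most one referral.

## The synthetic-data generator

The generator (`generator_config()` and the `gen_*()` functions) emulates
the study conditions: 6,072 consults with the published top-ten specialty
mix and the remaining 26% pooled as `"other"`; 873 primary-care providers
and 143 specialists; 608 primary-care post-consultation responses with
Bernoulli avoidance at 0.84 and top-two-box satisfaction at 0.99; 653
specialist responses (satisfaction 0.96) of which 638 answer the
referral-necessity item at a 0.55/0.40/0.05
unnecessary/necessary/unsure split; 89 experience respondents with
usage-band weights 34/20/18/17 and the published top-two agreement rates;
onboarding fees drawn from gamma(mean $1,265, SD $230).

Choices without a published anchor, fixed once: the comprehensive-fee mean
is $174.17 — the published benefit total divided by referrals avoided,
plus the $97.82 encounter cost — which is a derived calibration, not a
published fee; its inter-specialty SD is $25, a plausible dispersion for
consultation fees of the represented specialties; the synthetic cost
ledger uses 20 specialist groups over a 12-month horizon. Per-specialty
fees are truncated below at the encounter cost by default, so net savings
are non-negative unless that behaviour is disabled; negative net savings
are permitted by the fee model itself (warned, not rejected), since
low-fee specialties are plausible in real schedules.

The necessity item needs one modelling note: the published grouped shares
(55% + 40% of 638 respondents) leave a 5% residual that a strict
four-level scale cannot produce, so the instrument is modelled with an
additional on-instrument `"unsure"` token whose share is reported as the
residual. Survey respondents are sampled without replacement from the
consult log, preserving the consult-to-response linkage of the real
per-consult pop-up survey.

What passing tests on generated data do **not** show about real data: the
generator draws every item independently (no correlation between, say,
satisfaction and avoidance, and no provider-level clustering of
responses), response propensity is uniform (no volunteer bias, which the
real convenience sample certainly has), specialty mix is stationary over
the window, and all consults are completed. Parameter-recovery tests
therefore validate the estimators and the pipeline plumbing, not the
external validity of any survey estimate.

## Numerical choices

- **Money** is carried as integer cents; display rounding is
  round-half-up (half away from zero), the convention of billing schedules
  and published tables, applied once per published figure. A $10^{-9}$
  bump absorbs binary-representation error just below exact halves.
- **Percent display**: whole percents for the provider-mix and survey
  tables, one decimal for the specialty-share table, one decimal for
  ratio metrics, whole dollars for money cells — each applied only in the
  renderer, which formats previously computed metrics and never
  recomputes them.
- **Ordering and ties**: specialty tallies order by descending count with
  alphabetical tie-breaks, so reports are permutation-invariant and
  deterministic.
- **Degenerate inputs**: empty consult logs yield empty tallies; an empty
  provider registry reports absent shares rather than 0/0; zero total
  cost reports undefined ratio metrics while still computing the net
  benefit; a point-mass PSA collapses every draw to the deterministic
  ratio-of-means result.
- **Validation**: fee schedules require unique non-empty code ids and a
  positive MSU rate; Likert values outside 1–5 and unknown usage bands or
  roles are rejected with the offending value named; a missing
  phone-consult code is reported by its code id.

## Problem sizes in the test suite

The suite regenerates all fixtures in code at test time: consult logs of
700–6,072 records, surveys at the published denominators (608/653/638/97/
89), PSA runs of 100–1,000 draws, moment-recovery checks at $10^5$ draws,
and a parameter-recovery loop of 60 generator replicates backed by a
$2\times10^4$-replicate mechanism-level coverage check against the exact
binomial enumeration. One caveat found by that enumeration: the exact
probability that a binomial proportion lands within two (true) standard
errors of its generating value is only approximately 95%, and for extreme
rates with modest denominators discreteness pushes it below — 93.9% for
$p = 0.99$, $n = 608$. Recovery assertions at the 95% level are therefore
made for the estimators whose exact coverage clears that bar, and the
extreme-rate estimators are checked against their exact enumerated
coverage instead.

## Known limitations

- No incremental cost-effectiveness against health outcomes (no QALYs),
  no multi-year budget-impact or Markov modelling, no currency conversion
  or inflation adjustment.
- Descriptive survey analysis only: binomial standard errors, no
  hypothesis tests, no weighting, no correction for voluntary response.
- Independent sampling in the PSA; correlated benefit-cost draws (e.g.
  adoption driving both) would widen or narrow intervals in ways the
  current engine cannot express.
- The comprehensive-fee mapping is an input; the package ships no real
  provincial fee data.
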