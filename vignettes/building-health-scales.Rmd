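---
title: "Building biological and lived health scales from ordinal survey items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building biological and lived health scales from ordinal survey items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `healthscales`, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, the numerical choices, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The scientific question

Self-reported general health (SRGH) — "In general, how would you rate your
health?" on a five-point scale — is the most widely used single health
measure, yet what respondents have in mind when answering is unclear. The
ICF framework separates *capacity* (what a person could do without any
assistance: biological health) from *performance* (what the person does do,
assistance included: lived health). Disability surveys that ask both
variants of the same activity-difficulty items make the distinction
measurable: a biological health scale (BHS) and a lived health scale (LHS)
can be calibrated as latent traits, and their relative strength as
predictors of SRGH can be compared. The package implements that full
pipeline.

## Stage 1: instrument and preprocessing

The instrument (`default_item_bank()`) has 42 biological and 31 lived items
in seven domains, rated 1 (no/little difficulty) to 4 (cannot do). Five
sensory items per form are placeholders that exist only to be removed:
vision/hearing questions do not distinguish the with/without-assistance
variants. The published roster names 37 biological and 26 lived items; the
difference to the printed totals (42/31) is exactly the sensory block, so
the bank carries 5 generic sensory placeholders per form.

Preprocessing applies three rules in a fixed order:

1. `drop_sensory_items()` — column-only removal;
2. `collapse_categories()` — raw codes 2 ("moderate") and 3 ("severe") have
   low frequency and are merged: 1→0, 2,3→1, 4→2. A second application is
   rejected rather than silently absorbed;
3. `apply_eligibility_filter()` — only respondents with at least one
   *observed* biological difficulty (collapsed response 1 or 2) are kept.
   Respondents whose biological responses are entirely missing cannot
   qualify; the rule requires an observed difficulty. The sensory drop runs
   first because the eligibility rule refers to the *remaining* items.

`weighted_descriptives()` reproduces the sample-description layout (gender,
age group, education, SRGH distribution, condition counts, weighted
percentages per population). Education is carried as an inert covariate:
present in the description, unused downstream.

## Stage 2: IRT assumption screening

* **Unidimensionality.** The full bifactor analysis with analytic bifactor
  rotations used in the original analysis is out of scope; the package uses
  a simpler surrogate — the first-to-second eigenvalue ratio of the
  polychoric correlation matrix (ratio > 3 reported as supporting a strong
  general factor) together with inspection of minimum-residual one-factor
  loadings. This is deliberate: the original analysis itself proceeded with
  unidimensional models after its check, and its decision rule is not
  quantified, so a heavier implementation would add machinery without a
  testable contract.
* **Local independence.** Residual correlations `r_ij − λ_i λ_j` from the
  one-factor solution; pairs strictly above 0.2 are flagged. The original
  report does not state how it chose which member of a dependent cluster to
  retain; the package drops the member with the smaller loading and exposes
  a `retain` override to reproduce any published retained set.
* **Monotonicity.** Item means conditional on rest-score (total collapsed
  score over the other items), in ~10 quantile bins with average-rank tie
  handling; an adjacent bin-mean *decrease* larger than `tolerance`
  (default 0.03) times the category range (2) is a violation. Fewer than
  20 observations per bin reduce the bin count, logged.

The polychoric estimator is the standard two-step: thresholds from marginal
cumulative proportions via the inverse normal, then the correlation
maximizing the bivariate-normal cell likelihood (`optimize` on
[−0.999, 0.999]; the bivariate CDF by Gauss–Legendre integration of the
density over the correlation parameter). Estimates are clipped at ±0.999;
degenerate pairs are marked missing and logged.

A note on scales: the 0.2 residual criterion lives on the polychoric
(latent-response) scale. The test suite's "shared nuisance factor"
construction therefore injects the nuisance on that scale — a 0.6 nuisance
loading on the *GRM trait* scale is attenuated by the ordinal link to a
residual of ~0.15 and would sit below the criterion by design, not by
failure of the screen.

## Stage 3: graded response model

`P(X ≥ k | θ) = logistic(a(θ − b_k))` with D = 1 — no 1.7 scaling
constant. This matches the plausible metric of the published parameter
values (discriminations 0.6–5.0), and all recovery comparisons are defined
in this metric.

* **Quadrature:** 61 equally spaced nodes on [−6, 6], standard-normal
  weights renormalized to sum to 1. Doubling the node count changes fitted
  parameters by < 0.01 (tested).
* **EM:** E-step posteriors over the grid per respondent (compiled
  accumulation); M-step per item (per cell for split items) by `nlminb`
  from the current values with the thresholds reparameterized as
  `(b1, b1 + exp(δ))` to enforce ordering, so each cycle cannot decrease
  the expected complete-data log-likelihood and the marginal log-likelihood
  trace is non-decreasing (asserted within 1e-8).
* **Split calibration:** one joint EM; items flagged for DIF get separate
  parameters per demographic cell, unflagged items are anchors with shared
  parameters, and θ ~ N(0,1) in every cell. The original report does not
  describe its linking strategy; anchor-linked joint calibration is the
  standard choice that keeps all cells on one scale.
* **Missing data:** responses missing by design (lived items of
  non-assisted respondents, subgroup items) are omitted from the
  respondent's likelihood product — missing at random given θ.
* **Degenerate inputs:** a constant item is excluded with a warning; an
  item cell with an unobserved top category collapses to two categories
  with a warning; non-convergence flags the fit instead of erroring.
* **Weights:** calibration is unweighted; sampling weights enter the
  descriptives only, following the original analysis's apparent practice
  (stated as an open question there).
* **Scores:** EAP (posterior mean) with posterior SD; `rescale_scores()`
  maps the sample minimum to 0 and maximum to 100 (higher = worse health).
  Whether the original 0–100 transform used sample min–max or theoretical
  bounds is not stated; min–max is used because it reproduces the published
  "range = [0; 100]" behaviour exactly and is invariant to the latent
  location/scale.

## Stage 4: DIF detection

For each item and grouping variable (population, age ≤65/>65, gender,
condition count 0 / 1–2 / >2) three nested proportional-odds models are
fitted to the collapsed item response: M1 `item ~ score`, M2 `+ group`,
M3 `+ group + group×score`. The DIF statistic is
`ΔR² = R²(M3) − R²(M1)` (McFadden), i.e. uniform and non-uniform DIF
combined — the original criterion names one number without distinguishing
the two; M2 is reported for diagnostics. Items with ΔR² strictly above
0.02 are flagged. The matching score is the EAP from the current
calibration (the "hybrid" in the method's name refers to IRT-score
matching), and purification iterates calibrate → score → scan until the
flag set stabilizes (max 10 rounds, warning on oscillation). Variables are
scanned marginally and flagged variables crossed into calibration cells,
which is what produces cell labels like "institutionalized young". The
proportional-odds MLE is an in-package `nlminb` fit with analytic
gradient and log-gap intercept parameterization, verified against a
grid-search likelihood oracle.

## Stage 5: forest importance

CART variance-reduction regression trees on bootstrap samples, `mtry`
predictors drawn without replacement at every node, terminal nodes of at
most `min_node` (5) cases; SRGH is treated as numeric 1–5. With exactly two
predictors, mtry = 2 means both are always candidates — kept for fidelity
to the stated configuration. The cited implementation of conditional
importance uses conditional-inference trees as base learners; CART is used
here because the acceptance surface is the importance *ranking*, which the
permutation scheme (not the base learner) determines. Unconditional
permutation importance is the OOB MSE increase after permuting a predictor
among a tree's OOB cases, averaged over trees; the conditional scheme
permutes within cells defined by the tree's own split points on every other
predictor whose absolute Pearson correlation with the target exceeds 0.2
(the scheme's customary default, configurable). Cells of size one
contribute no permutation. Both measures are reported; per-tree values are
retained so the average can be re-checked exactly, and both schemes are
verified against brute-force re-prediction oracles under a shared
permutation-seed protocol (one permutation per tree × predictor, in column
order; trees with fewer than two OOB cases draw nothing).

## The synthetic world

`simulate_survey()` states one world and keeps it fixed:

* Latent traits: bivariate standard normal per respondent with correlation
  0.79 (community-dwelling) / 0.85 (institutionalized) — the published
  score correlations, used as the generating truth. Group differences are
  expressed through item parameters and mixing, not latent shifts, because
  the original report states no group latent distributions.
* Item parameters: the package's reference calibration (the published
  per-item values, including group-split cells) where available;
  deterministic plausible fill-ins (a ∈ {1.2, 1.8, 2.4}, thresholds spread
  over [−0.5, 1] with unit gap) for the sensory placeholders and
  items outside the final scales. Raw 4-category codes are produced by
  splitting the collapsed middle category 70/30 into "moderate"/"severe",
  emulating the low severe frequency that motivated the collapse.
* Demographic mixing from the published sample description: 58.5%/82% old,
  63.3%/65.5% female, condition-count and education margins per population.
* Assistance: `P(assisted) = logistic(intercept_pop + 1.0 · θ_lived)` with
  intercepts −0.2 (community: roughly half receive assistance) and +2.0
  (institutionalized: nearly constant support), mirroring the reported
  qualitative pattern. Lived items are administered only to assisted
  respondents; the two subgroup items (driving, menstrual care) get a 0.4
  administration probability, menstrual care restricted to women.
* SRGH: proportional odds on the lived trait only (slope 1.5, cutpoints
  −4.2, −1.5, 0.8, 3.0 chosen once to approximate the published SRGH
  margins), coded 1 = very good … 5 = very bad. A mixing coefficient
  `srgh_bio_mix` can add a biological contribution for power studies; the
  default 0 encodes the conclusion to be recovered as the generator's
  truth.
* Weights: log-normal(0, 0.5); positive by construction.

Not emulated: the survey's sampling design and stratification, questionnaire
skip logic beyond the rules above, and real item wording effects. A green
pipeline test therefore establishes that the *methods* recover a stated
world of this structure — not that the published point estimates would be
reproduced on the restricted microdata, which are not available at desk
scale.

## Numerical choices and known limitations

* Score-correlation checks must respect classical attenuation:
  `cor(EAP_b, EAP_l) ≈ ρ √(rel_b rel_l)` with EAP reliabilities
  `rel = var(θ̂)/(var(θ̂) + mean(se²))` ≈ 0.92–0.94 here, so the raw score
  correlation sits ~0.05 below the generating ρ by construction. The test
  suite asserts the disattenuated correlation (model-internal quantities
  only) against the configured ρ, and the raw correlation against its
  attenuation-predicted value.
* The proportional-odds fitter guards against separation by flagging
  |β| > 30 as non-converged rather than erroring; DIF scans skip items
  constant within a group level.
* EM convergence is `max |Δparameter| < 1e-3` (default), capped at 200
  cycles with a flagged, non-erroring result; recovery runs use 300.
* All stochastic outputs are pure functions of (inputs, seed): the
  generator seeds R's RNG once; forests consume R's RNG inside compiled
  code; permutation importances re-seed per call.
* Purification at small n (a few hundred respondents) can oscillate
  because ΔR² estimates are noisy around the 0.02 criterion; the loop
  returns the last specification with a warning after 10 rounds.
* The 0–100 rescale is sample-relative: scores from different samples or
  scales are not directly comparable (the BHS and LHS are calibrated on
  different item sets, as in the original design).
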