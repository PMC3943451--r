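# healthscales

Builds a **biological health scale (BHS)** and a **lived health scale
(LHS)** from ordinal disability-survey items and asks which of the two
better predicts **self-reported general health (SRGH)**.

The distinction comes from the ICF framework: *biological health* is
capacity — the difficulty a person has carrying out activities **without**
any technical aid or personal assistance; *lived health* is performance —
the difficulty in the same activities **with** whatever assistance the
person actually uses. Surveys such as the 2008 Spanish national disability
survey (EDAD) ask both variants, plus the usual single-item SRGH rating
(very good … very bad). That survey's microdata are restricted, so the
package ships a synthetic generator that emulates its structure (two
residence populations, correlated latent traits, assistance-dependent item
administration) with known ground truth; every stage of the analysis is
testable without any download.

## The model

Items are 4-category difficulty ratings collapsed to three
(0 = none/little, 1 = moderate/severe, 2 = cannot). Each scale is
calibrated with **Samejima's graded response model** (logistic metric,
D = 1):

```
P(X_ij >= k | theta_i) = logistic(a_j (theta_i - b_jk)),   k = 1, 2
```

with discrimination `a_j > 0`, increasing thresholds `b_j1 < b_j2`, and
`theta ~ N(0,1)`. Calibration is marginal maximum likelihood via EM on a
61-node quadrature grid. Before calibration, the IRT assumptions are
screened (eigenvalue ratio of the polychoric matrix, residual correlations
> 0.2 for local dependence, rest-score bin means for monotonicity).
**Differential item functioning (DIF)** across study population, age group,
gender and number of health conditions is detected with iterative hybrid
ordinal logistic regression — nested proportional-odds models matched on
the EAP score, flagged when McFadden's pseudo-R² changes by more than
0.02 — and flagged items are calibrated separately per group inside one
joint EM (anchor items link the scale). Respondents are EAP-scored and
rescaled to 0–100 (0 = best health, 100 = worst).

Step two regresses SRGH (numeric 1–5) on the two scores with a **random
forest** (1000 CART trees, mtry = 2) and compares **conditional permutation
importance** (Strobl's scheme, which permutes a predictor within cells
defined by the tree's own split points on correlated predictors — exactly
what is needed here, because the two scores correlate ~0.8).

## Worked example

```r
library(healthscales)

cfg <- pipeline_config(sim = simulation_config(), ntree = 100L, seed = 5L)
report <- run_pipeline(cfg)
print(report)
```

which prints (seed 5, default generator: 1000 community-dwelling + 500
institutionalized respondents, latent correlation 0.79/0.85, SRGH driven by
lived health only):

```
<pipeline_report>
  1480 respondents scored
  community_dwelling: conditional importance bhs=-0.0008 lhs=0.1202
  institutionalized: conditional importance bhs=-0.0195 lhs=0.1474
```

The conditional importance of the lived score dominates in both
populations — the generator's truth (SRGH depends on the lived trait only)
is recovered. The accompanying Spearman correlations in
`report$associations$correlations` show the same ordering
(community-dwelling: r_S = 0.51 lived vs 0.45 biological; institutionalized
0.59 vs 0.50 at this n and seed). `write_report(report, "out/")` serializes
descriptives, calibration tables (item / split cell / Discr / Thr1 / Thr2),
scores, box-plot statistics and importances with an md5 manifest.

A command-line front end ships in `inst/cli/healthscales`
(`simulate`, `calibrate`, `score`, `dif`, `importance`, `run-all`;
`--config <json> --seed <int> --out <dir>`).

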