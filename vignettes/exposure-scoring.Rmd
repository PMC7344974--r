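---
title: "Scoring near-field occupational exposures and evaluating exposure models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring near-field occupational exposures and evaluating exposure models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expoband)
```

## The model

`expoband` implements a semi-quantitative scoring model for occupational
inhalation exposure in indoor workplaces.  The model assumes a single
near-field source — the contaminant reaching the worker's breathing zone is
emitted within about a metre of it — and ignores far-field/background
contributions, dermal uptake and ingestion.  This reflects how regulatory
personal monitoring data are collected (a sampler in the breathing zone), and
it is what makes a simple multiplicative structure defensible: each of twelve
modifying factors scales the expected exposure independently.

For a situation profile (one classification choice per factor) the raw score
is

$$
S \;=\; \frac{P_f \cdot (E_p E_h E_m) \cdot (\eta_{gv} L_c \cdot PPE) \cdot H
        \cdot (T_h T_f D)}{V},
$$

where the eleven numerator factors are job position, emission potential,
historical exposure, process type, general ventilation/containment, localized
controls, personal protective equipment, health-hazard category, task
duration, task frequency and distance from the source, and the divisor $V$ is
the room-volume score (larger rooms dilute a near-field source).  The
reported **exposure score** is $\ln S$.  Each factor's classifications carry
scores between 1.0 and 10.0 that were calibrated on observed exposure ratios
(for example, tasks without local exhaust ventilation run roughly three times
higher than with it, and unprotected workers about five times higher than
workers with >90% effective PPE); every factor has a "no exposure"
classification scored 1.0, so an office worker's profile multiplies out to 1.

The log score is banded into four **exposure categories**:

| category | description | score range |
|---|---|---|
| 1 | no exposure | 1.00 |
| 2 | low | 1.01–4.76 |
| 3 | medium | 4.77–9.38 |
| 4 | high | 9.39–14.01 |

The upper limit 14.01 is exactly the score of the maximal profile
($\ln(3 \cdot 5 \cdot 5 \cdot 2 \cdot 3 \cdot 3 \cdot 5 \cdot 6 \cdot 3 \cdot
5 \cdot 2 / 1)$), and the cut points 4.76 and 9.38 sit at 34% and 67% of it.

```{r}
prof <- load_fixture("worked_profile")   # FRP lamination, ship manufacturing
res <- compute_exposure_score(prof)
res
score_breakdown(res)
```

## Numerical conventions and edge cases

Several choices are deliberately pinned down because the banding is defined
at 2-decimal precision:

* **No-exposure convention.** $\ln 1 = 0$, but the model's stated default
  outcome for the trivial profile is 1.0.  We therefore report the score
  1.00 (category 1) iff *every* factor is at a score-1.0 classification.
  Any non-trivial profile whose log product falls below 1.01 is clamped up
  to 1.01 — so it lands in category 2, never in the no-exposure band — and
  the clamp is flagged in the result.  Scores strictly between 1.00 and
  1.01 therefore cannot occur; with the packaged table the smallest
  non-trivial profiles do fall below 1.01 (e.g. a single 1.2-scored factor
  in a large room), which is why the clamp, rather than an error, is the
  chosen behaviour.
* **Banding.** Scores are rounded half-up to 2 decimals (half-up because the
  band limits are printed at 2 dp and `round()`'s round-half-to-even would
  misplace exact boundary cases such as 4.765) and banded by inclusive
  ranges.  Scores above 14.01 + 0.005 are rejected as inconsistent with the
  factor table.
* **Label matching.** Classification labels match case-insensitively with
  collapsed whitespace and unicode dashes normalised; configured aliases
  (e.g. the worked example's "Manual handling with low-level cleaning" for
  the score-2.0 process class) resolve to their canonical classification.
  There is no fuzzy matching: a typo is an error that names the valid
  labels.
* **The factor table is data.** Scores live in a versioned YAML file, so a
  recalibration is a config change, not a code change.  The liquid and
  solid emission-potential classifications currently share the same score
  set; the phase is still recorded for provenance and future divergence.

## Measurement statistics

Exposure measurements (8h-TWA concentrations, ppm) are treated as lognormal.
`summarize_measurements()` reports n, AM, GM, GSD, min, max; the GSD uses the
**sample (n−1)** log-SD.  The published validation tables do not state their
convention (at 2 dp the printed values are consistent with either for these
group sizes); n−1 is chosen because it makes the grouped identities below
exact.  Groups of size 1 have no spread estimate: their GSD and 90th
percentile are reported as absent and they contribute zero within-group
variance.

The closed-form 90th percentile is $X_{0.90} = GM \cdot GSD^{1.282}$, with
the exponent kept at the conventional rounded value 1.282 rather than
$z_{0.90} = 1.28155$, matching how the reference estimates were produced.
The n-weighted pooled GM is $\exp(\sum n_c \ln GM_c / \sum n_c)$.

## Evaluating a model against measurements

Agreement between log-transformed model estimates $\hat y_i$ and measured
exposures $y_i$ is summarised by

* bias $= \overline{\hat y - y}$ (ln ppm) and relative bias
  $(e^{\text{bias}} - 1) \times 100\%$,
* precision $= \sqrt{\sum ((\hat y_i - y_i) - \text{bias})^2 / (n_0 - 1)}$ —
  written as the square root of the mean squared deviation about the bias so
  that "bias ± precision" reads on one ln scale,
* accuracy $=$ mean absolute error $\overline{|\hat y - y|}$,
* residuals $\hat y_i - y_i$ with Bland–Altman 95% limits of agreement
  (mean ± 1.96 × SD; 1.96 is the conventional multiplier, the reference
  analysis states "95% limits" without a formula).

When only grouped summaries are available and every individual in group $c$
shares one estimate $a_c$, two identities recover the individual-level
statistics exactly under the n−1 GSD convention:

$$
\text{bias} = \frac{\sum_c n_c (a_c - \ln GM_c)}{\sum_c n_c},
\qquad
\sum_{i \in c} (d_i - b)^2 = n_c (a_c - \ln GM_c - b)^2
  + (n_c - 1)(\ln GSD_c)^2 .
$$

The MAE has no such identity; `grouped_accuracy_approx()` provides the
folded-normal analytic approximation and `evaluate_model()` labels its
accuracy column accordingly.  Exact MAE, residuals and limits of agreement
require individual values — measured or simulated.

```{r}
est <- load_fixture("model_estimates")
ms  <- load_fixture("measurement_summaries")
evaluate_model(est, ms, column = "p90")
pearson_log(log(est$p90), est$score)
```

## The simulator: what it emulates and what it does not

`simulate_measurements()` draws seeded lognormal individual values matching
per-situation (n, GM, GSD) summaries, because the validation dataset
publishes only summaries.  The `exact_moments` mode affinely adjusts the
log draws so the sample GM and sample GSD equal the targets exactly, which
is what makes the raw-data and grouped-summary evaluation routes provably
agree in the tests.  The simulator emulates within-group lognormal spread
only: it does not reproduce between-day autocorrelation, censoring at
detection limits, or any worker-level random effects present in real
monitoring campaigns.  A passing oracle-equivalence test therefore shows the
*arithmetic* is right, not that real styrene exposures are lognormal.

Problem sizes used in the test suite were chosen to make the statistical
assertions sharp at comfortable runtime: parameter-recovery at $n = 10^4$
draws (3% tolerance), the exceedance tail check at $n = 10^5$ against the
closed-form normal tail, oracle-equivalence on 100 seeded grouped datasets
(1e-9 tolerance), and scoring-model invariants over 1,000 random profiles
plus exhaustive enumeration of all attainable raw products (every configured
score is of the form $2^a 3^b 5^c$, so the full $1.8 \times 10^8$-combination
grid collapses to 1,426 distinct products).

## Reproducibility limits of the bundled reference values

The bundled dataset transcribes the published per-company tables.  Three
groups of printed reference values cannot be regenerated from those tables
at their printed precision, and the package does not pretend otherwise:

* the measured 90th percentiles (e.g. 36.02 for GM 11.78, GSD 2.39) were
  computed from unrounded GM/GSD; from the 2-dp printed inputs the formula
  gives 36.00.  Each printed 90th does lie inside the interval implied by
  ±0.005 input rounding, which is what the tests assert;
* the published overall agreement table is not derivable from any single
  consistent application of the definitions above to the published
  summaries — its overall MAE (1.28) is not the n-weighted mean of its
  subgroup MAEs (1.02, 1.69), which the MAE definition forces — so the
  faithful grouped reconstruction matches its 50th-percentile bias (−0.98
  vs −1.00) but not the remaining entries;
* the subgroup correlations between scores and 90th-percentile estimates
  (0.67, 0.85) were computed on unrounded estimates; ln of 2-dp values near
  0.1 ppm is rounding-sensitive, and the printed table yields 0.645 and
  0.776 (the overall 0.93 does reproduce).

The corresponding acceptance-style tests assert the printed values anyway
and fail, intentionally, as documentation of the gap; the implementation is
validated instead by the exact identities and closed-form oracles above.

## Known limitations

* Near-field only: no far-field/background term, no dermal or ingestion
  routes, no two-box dispersion physics.
* The score is a ranking tool, not a concentration estimate; calibrating
  score to ppm (e.g. by mixed-effects regression on a larger measurement
  set) is out of scope.
* No handling of censored (below detection limit) measurements and no
  between/within-worker variance decomposition.
* PPE classes mix equipment sets with protection percentages; mapping real
  respiratory protection onto a class remains expert judgement.
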