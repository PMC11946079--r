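---
title: "Multi-objective evaluation of water-fertilizer orthogonal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective evaluation of water-fertilizer orthogonal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfeval)
```

## The problem

Greenhouse fertigation trials in arid-region substrate culture ask a
multi-objective question: which combination of an irrigation regime and
stage-split fertilizer rates best balances fruit yield, fruit quality and
resource-use efficiency? `wfeval` implements the full evaluation chain for
such trials laid out on an L9(3^4) orthogonal array: four factors —
irrigation amount (IA, as a fraction of crop evapotranspiration ET~c~) and
the fertilizer rate at the seedling (FI), flowering/fruit-setting (FII) and
peak-fruit (FIII) stages — each at three levels, screened in nine runs
(treatments T1–T9) with three replicate plots.

The irrigation levels are ET~c~ fractions: severe deficit (DIS, 50%), mild
deficit (DIM, 75%) and full irrigation (FI, 100%); irrigation demand itself
comes from pan evaporation through `I = Ep * Kcp * A` with stage pan
coefficients 0.6 / 1.3 / 1.1 (`irrigation_requirement()`). Fertilizer levels
are per-stage rates of 562.5, 750 and 937.5 kg/ha. The packaged treatment
table (`load_treatments()`) records the realized seasonal volumes and stage
rates per treatment and year; the applied volumes realize the designed
fractions exactly (DIM/FI = 75%, DIS/FI = 50% in both years), which is what
makes the "25% water saving" arithmetic of the mild-deficit optimum an exact
design property rather than a measurement.

## The evaluation chain

**Range analysis** (`range_analysis()`): because the L9 array is balanced,
the mean response at each level of a factor averages over all levels of the
other factors, so the per-factor level means `k̄` isolate additive main
effects. The range `R = max(k̄) − min(k̄)` ranks factor influence; the best
level mean (largest for a benefit response, smallest for a cost response)
selects each factor's optimum.

**Efficiency metrics** (`wue()`, `pfp()`): water use efficiency
`WUE = Y/IA` (kg/m³) and partial factor productivity `PFP = Y/F` (kg/kg).
`F` is the per-season total across the three stage applications; the
per-stage scope of `F` is not meaningful for a productivity ratio, so no
per-stage PFP is defined. WUE uses each year's own irrigation volume and the
two years are then averaged, matching the two-year-average reporting
convention used elsewhere in the pipeline.

**Entropy weighting** (`entropy_weights()`): indicators are
direction-adjusted (cost indicators Hd, TA and NA are inverted by the
min-max complement `x' = max(x) − x + min(x)`, which keeps values
non-negative), normalized to column shares (`y_ij = x_ij / Σ_i x_ij`), and
scored. The information entropy `E_i = −(1/ln n) Σ_j y_ij ln y_ij` (with
`0·ln 0 = 0`) measures how little an indicator discriminates among
treatments; the classical weights are `H_i = (1 − E_i)/Σ(1 − E_i)`. The
exponential-form variant replaces the linear kernel with

$$H_x = \frac{e^{k(\sum_i E_i - E_x + 1)} - e^{kE_x}}
            {\sum_l \left[e^{k(\sum_i E_i - E_l + 1)} - e^{kE_l}\right]}$$

whose slope coefficient `k` tunes weight dispersion. For entropies in
`[0, 1]` these weights are provably non-negative, sum to one and are
non-increasing in entropy, and for small entropy spreads they are *less*
dispersed than the classical weights — the point of the modification, since
trial indicators typically all have high entropy and the classical kernel
then exaggerates tiny entropy differences. The printed form of this formula
in our source material is typographically garbled; the implementation above
is the unique reading consistent with its symbols and stated intent, and the
classical weights remain available as `method = "classical"`. The default
`k = 1` is deliberately neutral; `k` is exposed because the appropriate
dispersion is problem-specific.

A small non-negative shift (`delta = 0.01`) is added to the normalized
matrix before composite scoring (`S = Σ H·z`) so zero shares cannot null a
treatment's contribution. Entropies themselves are computed from the
*unshifted* shares under the `0·ln 0 = 0` convention — the shift exists to
protect the score aggregation, not the entropy, and shifting before the
entropy step is available behind `entropy_on_shifted = TRUE` for comparison.
The shift is affine and we do not renormalize after it; scores are compared
within a run only, so the uniform offset is immaterial.

**TOPSIS with virtual ideal solutions** (`topsis()`): after cost inversion,
columns are vector-normalized (`z = x/√Σx²`; the conventional TOPSIS choice —
min-max scaling is available via `norm = "minmax"`). The real ideals
`Z±` are the column-wise extremes; the virtual ideals extrapolate them,
`V+ = 2Z+ − Z−` and `V− = 2Z− − Z+`. Distances are root-weighted-Euclidean
`√Σ w_j(ref_j − z_j)²` (a no-root variant would break the closed-form checks
below), blended as `S± = αD± + βF±` with defaults `α = 0.9`, `β = 0.1`, and
the closeness `C = S−/(S+ + S−)` ranks treatments (ties broken by id order).
`V−` may have negative coordinates; distances are unaffected and nothing is
clipped.

Two closed forms make the method auditable: a treatment sitting exactly at
`Z+` has `D+ = 0`, `D− = d`, `F+ = d`, `F− = 2d` (where `d` is the weighted
distance between `Z+` and `Z−`), hence `C = 1.1d/1.2d = 11/12`; one at `Z−`
symmetrically gets `1/12`. So with `β > 0` closeness never reaches 0 or 1 —
the virtual ideals compress the extremes while spreading the interior, and
`α = 1, β = 0` recovers classical TOPSIS exactly. Both identities are
asserted in the test suite at `1e-12`.

**Pipeline** (`run_evaluation()`): replicate aggregation (means over
replicates, then years), advisory indicator screening
(`screen_indicators()`; a fruit-shape-index-like indicator flagged as
unstable is dropped, but never a whole category), Spearman rank correlations
among indicators (`spearman_matrix()`; constant indicators are excluded as
their rank correlation is undefined, and pairwise significance uses the
exact rank-correlation null distribution where ranks are untied), entropy
weighting and composite scores *within* each of the three dimensions (yield
C11; quality C21–C29; efficiency C31–C32), a single global 12-indicator
TOPSIS, and the water/fertilizer input reductions of the top-ranked
treatment against each full-irrigation treatment. Per-category and global
scoring answer different questions — "which treatment is best for quality?"
versus "which is best overall?" — so the default mode runs both. No
correlation-strength threshold is imposed at screening: exclusion is left
config-driven because stability, not collinearity, is the stated reason an
indicator leaves the panel.

## The synthetic trial generator

No raw plot data are distributed, so `generate_trial()` simulates the
study conditions with known ground truth: two years, nine treatments, three
replicate plots (27 plots per year), and twelve indicators. Ten indicators
(yield plus the nine quality traits) are generated as

```
value = (baseline + sum of factor effects + year offset) * (1 + cv * e),
e ~ N(0, 1)
```

— additive factor effects on the natural scale with *multiplicative*
Gaussian noise, so a 5% CV means 5% of the local mean and positive-valued
indicators stay positive at plausible CVs (values driven non-positive are
resampled; at the default CV this is a ~1-in-10^9 event per draw). WUE and
PFP are never simulated directly: they are derived per replicate from the
generated yield and the packaged input table, so the efficiency identities
hold exactly on synthetic data. The year effect is a shared additive offset
(±1% of baseline) standing in for a random year effect; simulating a full
mixed model is out of scope, as is any mechanistic crop or water-balance
model, and no spatial plot correlation is generated.

The default panel's baselines and effects are plausible magnitudes for
greenhouse tomato (yield 60 t/ha, VC 25 mg/100 g, SSC 5.5%, ...), with
irrigation as the dominant factor and severe deficit raising hardness,
acidity and nitrate while depressing the rest. They are design choices for
testing, explicitly *not* calibrated to any measured dataset — so passing
recovery tests demonstrates that the pipeline recovers a known additive
truth under Gaussian plot noise, not that real fruit responds additively.
Real trials add year-by-treatment interaction, non-additive water-fertilizer
coupling and measurement error structure the generator does not emulate.

`make_dominant_scenario()` rewrites the panel so one treatment is strictly
best on every direction-adjusted indicator: each factor contributes a margin
(default 20% of baseline) only at the target's level, and since two rows of
an L9 array share at most one column, every rival concedes at least three
margins per indicator. The target's irrigation-level yield effect is boosted
harder (default +100% of baseline) because the derived ratios WUE = Y/IA and
PFP = Y/F would otherwise favour low-input rivals: the mid-volume target
needs a yield ratio exceeding the worst-case input ratios (1.5 for water
vs severe-deficit rivals, 1.33 for fertilizer vs the lowest-total rival).
Those margins follow from the input table's arithmetic, not from tuning.

## Worked example

```{r example}
trial <- generate_trial(trial_config(seed = 42))
trial

report <- run_evaluation(trial)
report

round(report$weights$global, 3)
report$topsis[order(report$topsis$rank), c("closeness", "rank")]
```

A dominant-treatment scenario is recovered through the full chain:

```{r dominant}
cfg <- make_dominant_scenario(trial_config(seed = 7, cv = 0.05),
                              target = "T5", margin = 0.2)
run_evaluation(generate_trial(cfg))$ranking
```

## Numerical choices and degenerate inputs

* Normalization rejects zero-sum (entropy path) and zero-norm (TOPSIS path)
  columns by name rather than silently producing `NaN`.
* An all-identical decision matrix makes `S+ = S− = 0`; `closeness()`
  refuses it (there is nothing to rank) rather than inventing a convention.
* Entropies are clamped to `[0, 1]` after computation to absorb
  floating-point excursions of order `1e-16` at the boundaries.
* Ties: range-analysis factor ordering is stable in column order; optimal
  levels and configured optima break ties toward the lower level; TOPSIS
  ranking breaks closeness ties by alternative id order. All deterministic.
* Validation is row-specific: the treatment loader names the offending
  row/column, aggregation names the first missing (treatment, indicator)
  cell.

## Problem sizes used in the validation suite

The packaged tests run the closed-form TOPSIS identities on 1,000 random
9 x 12 matrices, the entropy-weight simplex/monotonicity properties on
1,000 random entropy vectors, oracle-equivalence checks (range analysis,
weighted distances, Spearman with ties, composite scores) on 500 random
instances each, exact optimum recovery on 50 random noiseless
configurations, and dominant-treatment recovery on 200 seeded noisy trials
(CV 0.05, 20% margins), requiring at least 95% rank-one recovery. These
sizes give stable Monte-Carlo estimates while keeping the default test run
fast.

## Limitations

The package evaluates *designed-trial summaries*; it does not fit the
mixed-effects ANOVA a full analysis would add (year and replicate as random
effects), construct general Taguchi arrays beyond L9(3^4), or model the
physiology behind the indicators. The exponential-form weight formula is our
reconstruction of a garbled printed source, with the classical method always
available as a fallback; and any headline percentages a real study reports
from measured plot data are only reproducible with that data — here the
reproducible quantities are the design arithmetic and the method's
closed-form and recovery properties.
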