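---
title: "Methods behind the atrial-fibrillation decision aid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the atrial-fibrillation decision aid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdecide)
```

## The decision problem

In non-valvular atrial fibrillation (NVAF), anticoagulation trades a lower
stroke risk against a higher major-bleeding risk, and both risks vary so
widely with comorbidity that the benefit-to-harm balance can reverse
between patients. A population-average recommendation is therefore a poor
substitute for two separately individualized risk estimates. `afdecide`
computes stroke and bleeding risk independently for each patient and each
treatment option, and wraps the numbers in the communication scaffolding —
education script, icon arrays, worksheet, physician prompt — that a decision
aid needs to be usable with older patients.

## Risk model

### Stroke

The untreated annual stroke rate is indexed by the CHADS₂ score: one point
each for congestive heart failure, hypertension, age ≥ 75 years and
diabetes, two points for prior stroke or TIA. The rate table (events per
person-year) for scores 0–6 is

```{r}
rate_tables()$chads2_stroke_rates
```

Treatment effects are multiplicative relative risk reductions from
randomized-trial meta-analysis: 21% for aspirin, 67% for warfarin. The
warfarin multiplier is exactly 1 − 0.67 = 0.33, not 1/3, because the effect
is specified to two digits. Adding aspirin to warfarin is modelled as
conferring no additional stroke protection, so the combination uses the
warfarin multiplier.

### Bleeding

Bleeding risk is score-indexed only on warfarin, via HEMORR₂HAGES: one
point each for hepatic or renal disease, ethanol abuse, malignancy,
age > 75, reduced platelet count or function, uncontrolled hypertension,
anemia, genetic factors, excessive fall risk and prior stroke, and two
points for a prior major bleed — the rebleeding factor the acronym's
subscript 2 denotes, retained here because without it the score cannot
reach the range its rate table covers. Scores of 5 and above share the top
rate band:

```{r}
rate_tables()$hemorrhages_bleed_rates
```

Note the deliberate asymmetry of the two age criteria (≥ 75 for CHADS₂,
strictly > 75 for HEMORR₂HAGES): the source instruments define their
thresholds differently and the package preserves both rather than silently
merging them. One shared `prior_stroke_tia` flag feeds both scores, and one
shared `age` field feeds both criteria.

Off warfarin there is no validated score, so the untreated ("baseline")
annual bleed rate comes from a small table stratified by age band
(lower bounds inclusive) and prior major bleed:

```{r}
rate_tables()$baseline_bleed_table
```

The published evidence base for baseline bleeding specifies the
stratifying covariates (age and comorbidity) but not the cell rates. The
table above is this package's calibration decision, made once: the corner
cells are fixed so that the attainable 5-year baseline range rounds to
1–26% and the aspirin range (relative risk 2) to 1–45% — the ranges the
tool displays — and the interior cells are monotone interpolations in age
and in prior bleed. Aspirin multiplies the baseline rate by a relative
risk of 2, chosen from the same meta-analysis that provides the baseline
rates; for aspirin plus warfarin the package applies the aspirin relative
risk of 2 multiplicatively on top of the warfarin rate, consistent with
the multiplicative treatment of aspirin elsewhere in the model. No source
states a combination-therapy bleeding model; this is a documented design
choice, not an inherited fact.

### Horizon conversion and display

One-year risks are small enough that patients tend to undervalue them, so
rates are converted to a 5-year horizon with the declining exponential
approximation of life expectancy: a constant annual rate $r$ over $t$
years gives cumulative risk $P = 1 - e^{-rt}$. The horizon is
parameterized (`years`) but defaults to 5. For display, probabilities are
rounded half away from zero to integer percents; raw probabilities are
kept at full precision internally, and rounding happens exactly once, at
the display boundary. This convention reproduces every displayed range
endpoint; whether the original implementation rounded identically is not
verifiable, which is why the convention is stated here rather than assumed
silently.

```{r}
horizon_risk(0.182, 5)          # worst CHADS2 score, untreated
round_pct(horizon_risk(0.182, 5))
```

### Attainable ranges

`enumerate_ranges()` brute-forces the discrete input space of each pathway
— the 7 CHADS₂ levels for stroke, the 6 HEMORR₂HAGES bands for bleeding on
warfarin, the 8 baseline cells otherwise — and returns the rounded minimum
and maximum. The test suite checks it against an independent oracle that
instead sweeps real patient profiles (every combination of the relevant
flags crossed with an age grid covering all band boundaries) through the
full per-patient pipeline, confirming that no profile can produce a value
outside the enumerated range and that both extremes are attained.

```{r}
range_table()
```

## Option menus and report structure

Patients without coronary artery disease see no treatment, aspirin, and
warfarin. CAD patients stay on antiplatelet or anticoagulant therapy by
practice norm, so "no treatment" is never offered to them: those on
aspirin choose between aspirin and aspirin plus warfarin; those on
warfarin between aspirin and warfarin. A CAD patient on no medication is
not a described presentation context and is rejected rather than silently
assigned a menu. Menu order follows the order in which the contexts are
described; on-screen ordering is otherwise a free choice.

The report presents sections in the tool's administration order:
communication opener, education, one screen per option (icon arrays for
stroke and bleed plus practical issues), sequelae, the combined
all-options screen, value clarification, worksheet, physician prompt. All
spoken-script text lives in an editable JSON asset
(`inst/extdata/script_passages.json`) so locale variants can be swapped;
the shipped default is the tool's original wording. Every number printed
on a screen is taken from the corresponding `risk_estimate` object — never
recomputed — so screens cannot drift from the engine.

Sequelae are rendered as text, not as a third pictograph: for stroke,
half recover, a quarter are disabled, a quarter die; for major bleeding,
three quarters recover and "a small number" are disabled or die. The
internal distribution splits that bleeding residual evenly
(0.125/0.125) so it normalizes, but the rendered text deliberately keeps
the qualitative wording because no quantitative split is stated anywhere.

Icon arrays use a denominator of 100 — the natural reading of
integer-percent pictographs, though no source states the denominator —
filled left-to-right, top-to-bottom. Both the glyph (text) and SVG
renderings are byte-deterministic, which the snapshot-style tests rely on.

## Synthetic profiles

`generate_fixtures()` draws each comorbidity flag independently with
probability 0.5, age uniformly on 40–95 years, and the current medication
uniformly over its three levels, under a caller-supplied seed and without
touching the global RNG state. These settings are chosen to cover the
discrete input space quickly — at n = 4096 the probability of missing
either CHADS₂ extreme is below 10⁻⁹ — not to mimic an NVAF clinic
population, where comorbidity prevalences are far from 50% and strongly
age-correlated. Passing tests on these fixtures therefore demonstrates
correctness of the deterministic pipeline over its whole input space, not
calibration of the underlying rate tables against any cohort.

## Numerical choices and degenerate inputs

- Percent rounding guards against binary floating-point representation
  pushing an exact half just below the boundary (e.g. `100 * 0.455`)
  by rounding to 9 decimals before the half-away step.
- Age-band lower bounds are inclusive (60 falls in 60–69).
- `horizon_risk()` requires strictly positive horizons; as the horizon
  approaches zero all displayed risks reach 0%.
- Profiles must state every field explicitly when parsed from files; the
  only soft validation is uncontrolled hypertension without a hypertension
  history, which warns (the record is suspicious but interpretable) rather
  than errors.
- Test-suite problem sizes — fixture sweeps of 25–512 profiles and an
  oracle space of 2¹⁰ flag combinations × 10 ages — were chosen as the
  smallest sets that still cover every rate-table cell and both extremes
  of each score.

## Known limitations

The rate tables derive from Medicare-age cohorts; validity below roughly
65 years is unestablished, although the package accepts ages from 18. The
aspirin bleeding relative risk is constant across individuals, ignoring
possible interactions with bleeding risk factors, and warfarin bleeding
risk is treated as constant over time. Intracranial and extracranial
bleeds are not distinguished, although their sequelae differ. Warfarin's
myocardial-infarction benefit is deliberately outside the calculus. None
of these are implementation gaps: they mirror the boundaries of the
evidence the tool encodes.
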