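# afdecide

Individualized antithrombotic decision support for non-valvular atrial
fibrillation (NVAF).

Patients with NVAF face a genuine trade-off: anticoagulation lowers their
stroke risk but raises their risk of a major bleed, and both risks vary so
widely with comorbidities that the benefit-to-harm ratio can reverse from
one patient to the next. `afdecide` computes both risks separately for an
individual patient under each reasonable treatment option — no treatment,
aspirin, warfarin, and aspirin plus warfarin — and renders them as an
icon-array decision report together with the patient-communication
scaffolding (education script, per-option and combined screens, worksheet,
physician prompt) that turns the numbers into a usable decision aid.

## The model

For a patient with comorbidity profile *x*:

- **Stroke.** The CHADS₂ score (1 point each for congestive heart failure,
  hypertension, age ≥ 75, diabetes; 2 points for prior stroke/TIA) indexes a
  table of untreated annual stroke rates, *r*₀ … *r*₆ =
  1.9, 2.8, 4.0, 5.9, 8.5, 12.5, 18.2 per 100 person-years. Treatment
  applies a relative risk reduction: 21% for aspirin, 67% for warfarin
  (adding aspirin to warfarin confers no additional stroke protection).
- **Bleeding.** On warfarin, the HEMORR₂HAGES score (1 point each for
  hepatic/renal disease, ethanol abuse, malignancy, age > 75, reduced
  platelets, uncontrolled hypertension, anemia, genetic factors, fall risk,
  prior stroke; 2 points for a prior major bleed) indexes annual major-bleed
  rates 1.9, 2.5, 5.3, 8.4, 10.4 per 100 person-years for scores 0–4 and
  12.3 for scores ≥ 5. Off warfarin, a baseline table stratified by age
  band and prior major bleed gives the untreated rate; aspirin doubles it
  (relative risk 2).
- **Horizon.** Annual rates *r* become 5-year cumulative risks by the
  declining exponential approximation of life expectancy,
  *P* = 1 − e^(−5*r*), displayed as integer percents (rounded half away
  from zero) and drawn as 100-icon pictographs.

Enumerating the whole discrete risk-factor space, the attainable 5-year
stroke risk runs from 9 to 60% with no therapy, 7 to 51% on aspirin and 3
to 26% on warfarin; the 5-year bleeding risk runs from 9 to 46% on
warfarin, 1 to 45% on aspirin and 1 to 26% untreated.

## Worked example

```r
library(afdecide)

p <- patient_profile(age = 78, chf = TRUE, hypertension = TRUE)
chads2_score(p)        # 3  (CHF + hypertension + age >= 75)
hemorrhages_score(p)   # 1  (age > 75)

risk_estimate(p, "warfarin")
#> Warfarin over 5 years: stroke 9%, major bleed 12%
#>   annual rates: stroke 0.0195, bleed 0.0250 per person-year

enumerate_ranges("none", "stroke")
#> min max
#>   9  60
```

The estimate reads: out of 100 people with this profile taking warfarin
for 5 years, about 9 are expected to have a stroke (down from 26 with no
treatment) and about 12 a major bleed (up from 6 untreated). `render_report(p)` prints the full
patient-facing document — education script, one icon-array screen per
available option, the combined screen, worksheet and physician prompt — and
`render_report(p, format = "html")` the same as a self-contained HTML page
with inline SVG pictographs.

A command-line wrapper ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "afdecide", package = "afdecide"))')
Rscript "$CLI" calc --profile patient.json            # decision report
Rscript "$CLI" ranges                                 # attainable-range table
Rscript "$CLI" fixtures --n 100 --seed 1 --out f.json # synthetic profiles
```

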