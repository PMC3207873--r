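Package: afdecide
Title: Individualized Stroke and Bleeding Risk Decision Aid for Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support engine for antithrombotic therapy in
    non-valvular atrial fibrillation. Computes CHADS2 stroke-risk and
    HEMORR2HAGES bleeding-risk scores from a patient's comorbidity profile,
    maps scores to annual event rates, applies relative-risk treatment
    effects for aspirin and warfarin, and converts annual rates to 5-year
    risks with the declining exponential approximation of life expectancy.
    Renders icon-array pictographs (text and SVG), per-option and combined
    treatment screens, the patient education script, a worksheet and a
    physician prompt as a complete decision report, and ships a command-line
    interface for single-patient reports, attainable-range tables and
    synthetic test profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
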