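# Additive clinical risk scores. Both are plain point sums over the profile
# flags; the age criteria differ deliberately between the two instruments
# (>= 75 for CHADS2, > 75 for HEMORR2HAGES) and are kept distinct.

#' CHADS2 stroke-risk score
#'
#' One point each for congestive heart failure, hypertension, age >= 75
#' years and diabetes; two points for prior stroke or TIA. Range 0-6.
#'
#' @param profile A `patient_profile`.
#' @return Integer score in \[0, 6\].
#' @examples
#' chads2_score(patient_profile(age = 80, chf = TRUE, prior_stroke_tia = TRUE))
#' @export
chads2_score <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  as.integer(
    profile$chf + profile$hypertension + (profile$age >= 75) +
      profile$diabetes + 2L * profile$prior_stroke_tia
  )
}

#' HEMORR2HAGES bleeding-risk score
#'
#' One point each for hepatic or renal disease, ethanol abuse, malignancy,
#' age > 75 years, reduced platelet count or function, uncontrolled
#' hypertension, anemia, genetic factors, excessive fall risk and prior
#' stroke; two points for a prior major bleed (the rebleeding factor that
#' gives the score its subscript 2). Range 0-12.
#'
#' @param profile A `patient_profile`.
#' @return Integer score in \[0, 12\].
#' @export
hemorrhages_score <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  as.integer(
    profile$hepatic_or_renal_disease + profile$ethanol_abuse +
      profile$malignancy + (profile$age > 75) + profile$reduced_platelets +
      profile$uncontrolled_hypertension + profile$anemia +
      profile$genetic_factors + profile$fall_risk + profile$prior_stroke_tia +
      2L * profile$prior_major_bleed
  )
}
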