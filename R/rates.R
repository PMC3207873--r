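# Annual event-rate tables and treatment effects. Rates are events per
# person-year. The CHADS2 and HEMORR2HAGES tables come from the scores'
# derivation cohorts; the baseline (untreated) bleeding table is a
# calibrated age x prior-bleed stratification, monotone in both dimensions,
# whose attainable 5-year range matches the tool's displayed 1-26% (and
# 1-45% on aspirin).

.CHADS2_STROKE_RATES <- c(
  `0` = 0.019, `1` = 0.028, `2` = 0.040, `3` = 0.059,
  `4` = 0.085, `5` = 0.125, `6` = 0.182
)

# Bands 0-4 individually; scores of 5 and above share the top band.
.HEMORRHAGES_BLEED_RATES <- c(
  `0` = 0.019, `1` = 0.025, `2` = 0.053, `3` = 0.084,
  `4` = 0.104, `5+` = 0.123
)

# Rows: age band (lower bound inclusive); columns: prior major bleed.
.BASELINE_BLEED_TABLE <- matrix(
  c(
    0.0012, 0.010,
    0.005,  0.015,
    0.012,  0.030,
    0.025,  0.060
  ),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("<60", "60-69", "70-79", ">=80"),
                  c("no_prior_bleed", "prior_bleed"))
)

.ASPIRIN_STROKE_RRR <- 0.21
.WARFARIN_STROKE_RRR <- 0.67
.ASPIRIN_BLEED_RR <- 2

#' Risk-engine constant tables
#'
#' Returns every embedded constant of the risk engine: the CHADS2 annual
#' stroke-rate table, the HEMORR2HAGES annual major-bleed rate bands for
#' patients on warfarin, the baseline (untreated) bleeding table stratified
#' by age band and prior major bleed, the treatment relative effects, and
#' the default horizon. The same tables ship as a machine-readable JSON file
#' in `system.file("extdata", "rate_tables.json", package = "afdecide")`.
#'
#' @return A named list of tables and scalars.
#' @export
rate_tables <- function() {
  list(
    chads2_stroke_rates = .CHADS2_STROKE_RATES,
    hemorrhages_bleed_rates = .HEMORRHAGES_BLEED_RATES,
    baseline_bleed_table = .BASELINE_BLEED_TABLE,
    aspirin_stroke_rrr = .ASPIRIN_STROKE_RRR,
    warfarin_stroke_rrr = .WARFARIN_STROKE_RRR,
    aspirin_bleed_rr = .ASPIRIN_BLEED_RR,
    default_horizon_years = 5
  )
}

#' Annual stroke rate for a CHADS2 score
#'
#' Table lookup of the untreated annual stroke rate (events per person-year)
#' for each CHADS2 score.
#'
#' @param score Integer CHADS2 score in \[0, 6\].
#' @return Annual rate (events per person-year).
#' @export
annual_stroke_rate <- function(score) {
  if (length(score) != 1L || is.na(score) || score != trunc(score) ||
      score < 0 || score > 6) {
    stop("CHADS2 score must be a single integer between 0 and 6", call. = FALSE)
  }
  unname(.CHADS2_STROKE_RATES[[as.character(as.integer(score))]])
}

#' Annual major-bleed rate on warfarin for a HEMORR2HAGES score
#'
#' Table lookup of the annual major-bleeding rate on warfarin. Scores of 5
#' and above share the top rate band.
#'
#' @param score Integer HEMORR2HAGES score in \[0, 12\].
#' @return Annual rate (events per person-year).
#' @export
warfarin_bleed_rate <- function(score) {
  if (length(score) != 1L || is.na(score) || score != trunc(score) ||
      score < 0 || score > 12) {
    stop("HEMORR2HAGES score must be a single integer between 0 and 12",
         call. = FALSE)
  }
  key <- if (score >= 5) "5+" else as.character(as.integer(score))
  unname(.HEMORRHAGES_BLEED_RATES[[key]])
}

baseline_bleed_band <- function(age) {
  if (age < 60) 1L else if (age < 70) 2L else if (age < 80) 3L else 4L
}

#' Baseline annual major-bleed rate (no antithrombotic)
#'
#' Stratified lookup by age band (<60, 60-69, 70-79, >=80; lower bounds
#' inclusive) and prior major bleed.
#'
#' @param profile A `patient_profile`.
#' @return Annual rate (events per person-year).
#' @export
baseline_bleed_rate <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  col <- if (profile$prior_major_bleed) 2L else 1L
  .BASELINE_BLEED_TABLE[baseline_bleed_band(profile$age), col]
}

#' Treatment-modified annual stroke rate
#'
#' Applies the relative risk reduction of the chosen antithrombotic to an
#' untreated annual stroke rate: 21% for aspirin, 67% for warfarin. Adding
#' aspirin to warfarin confers no additional stroke risk reduction, so the
#' combination uses the warfarin multiplier.
#'
#' @param base Untreated annual stroke rate, >= 0.
#' @param option A treatment option; see [treatment_options()].
#' @return Annual rate under treatment.
#' @export
treated_stroke_rate <- function(base, option) {
  if (length(base) != 1L || is.na(base) || base < 0) {
    stop("'base' must be a single non-negative rate", call. = FALSE)
  }
  option <- as_treatment_option(option)
  mult <- switch(option,
    none = 1,
    aspirin = 1 - .ASPIRIN_STROKE_RRR,
    warfarin = 1 - .WARFARIN_STROKE_RRR,
    `aspirin+warfarin` = 1 - .WARFARIN_STROKE_RRR
  )
  base * mult
}

#' Treatment-modified annual major-bleed rate
#'
#' No treatment uses the baseline stratified rate; aspirin doubles it
#' (relative risk 2); warfarin uses the HEMORR2HAGES table; aspirin plus
#' warfarin applies the aspirin relative risk of 2 on top of the warfarin
#' rate.
#'
#' @param profile A `patient_profile`.
#' @param option A treatment option; see [treatment_options()].
#' @return Annual rate under treatment.
#' @export
treated_bleed_rate <- function(profile, option) {
  stopifnot(inherits(profile, "patient_profile"))
  option <- as_treatment_option(option)
  switch(option,
    none = baseline_bleed_rate(profile),
    aspirin = baseline_bleed_rate(profile) * .ASPIRIN_BLEED_RR,
    warfarin = warfarin_bleed_rate(hemorrhages_score(profile)),
    `aspirin+warfarin` =
      warfarin_bleed_rate(hemorrhages_score(profile)) * .ASPIRIN_BLEED_RR
  )
}
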