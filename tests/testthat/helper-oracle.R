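# Shared test helpers: canonical profiles and an exhaustive brute-force
# oracle for attainable risk ranges that walks real patient profiles (all
# 2^k relevant flag combinations crossed with an age grid spanning every
# band boundary) through the full per-patient pipeline, independently of
# the score-level enumeration in enumerate_ranges().

minimal_profile <- function(age = 60, ...) {
  patient_profile(age = age, ...)
}

# worst-case profile: CHADS2 = 6, HEMORR2HAGES = 12
maximal_profile <- function(age = 80) {
  patient_profile(
    age = age, chf = TRUE, hypertension = TRUE, diabetes = TRUE,
    prior_stroke_tia = TRUE, hepatic_or_renal_disease = TRUE,
    ethanol_abuse = TRUE, malignancy = TRUE, reduced_platelets = TRUE,
    prior_major_bleed = TRUE, uncontrolled_hypertension = TRUE,
    anemia = TRUE, genetic_factors = TRUE, fall_risk = TRUE
  )
}

oracle_age_grid <- c(40L, 59L, 60L, 69L, 70L, 75L, 76L, 79L, 80L, 95L)

# flags that can move the outcome's rate for the given option
oracle_flags <- function(option, outcome) {
  if (outcome == "stroke") {
    c("chf", "hypertension", "diabetes", "prior_stroke_tia")
  } else if (option %in% c("warfarin", "aspirin+warfarin")) {
    c(
      "hepatic_or_renal_disease", "ethanol_abuse", "malignancy",
      "reduced_platelets", "uncontrolled_hypertension", "anemia",
      "genetic_factors", "fall_risk", "prior_stroke_tia", "prior_major_bleed"
    )
  } else {
    "prior_major_bleed"
  }
}

exhaustive_range <- function(option, outcome, years = 5,
                             ages = oracle_age_grid) {
  flags <- oracle_flags(option, outcome)
  grid <- expand.grid(
    rep(list(c(FALSE, TRUE)), length(flags)),
    KEEP.OUT.ATTRS = FALSE
  )
  names(grid) <- flags
  pct <- unlist(lapply(ages, function(age) {
    vapply(seq_len(nrow(grid)), function(i) {
      args <- as.list(grid[i, , drop = FALSE])
      # keep the record internally consistent to avoid validation warnings
      if (isTRUE(args$uncontrolled_hypertension)) args$hypertension <- TRUE
      args$age <- age
      profile <- do.call(patient_profile, args)
      est <- risk_estimate(profile, option, years)
      if (outcome == "stroke") est$stroke_pct else est$bleed_pct
    }, integer(1))
  }))
  c(min = min(pct), max = max(pct))
}
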