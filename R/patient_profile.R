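# Patient record: the data-entry fields a facilitator fills in before the
# encounter. One shared age field feeds both risk scores (CHADS2 uses
# age >= 75, HEMORR2HAGES uses age > 75), and one shared prior_stroke_tia
# flag feeds both scores.

#' Comorbidity flag names of a patient profile
#'
#' The boolean risk-factor fields of [patient_profile()], in canonical order.
#' Together with `age` and `current_medication` these are exactly the fields
#' of the patient record.
#'
#' @return Character vector of flag names.
#' @export
profile_flags <- function() {
  c(
    "chf", "hypertension", "diabetes", "prior_stroke_tia",
    "hepatic_or_renal_disease", "ethanol_abuse", "malignancy",
    "reduced_platelets", "prior_major_bleed", "uncontrolled_hypertension",
    "anemia", "genetic_factors", "fall_risk", "cad"
  )
}

profile_fields <- function() c("age", profile_flags(), "current_medication")

medication_levels <- function() c("none", "aspirin", "warfarin")

#' Construct a patient profile
#'
#' Builds the structured patient record used throughout the package: age in
#' years, fourteen binary comorbidity / context flags, and the antithrombotic
#' the patient currently takes. Flags default to `FALSE` for programmatic
#' construction; file input goes through [parse_profile()], which requires
#' every field to be present explicitly.
#'
#' @param age Integer age in years, between 18 and 120.
#' @param chf Congestive heart failure.
#' @param hypertension History of hypertension.
#' @param diabetes Diabetes mellitus.
#' @param prior_stroke_tia Prior stroke or transient ischemic attack.
#' @param hepatic_or_renal_disease Hepatic or renal disease.
#' @param ethanol_abuse Ethanol abuse.
#' @param malignancy Malignancy.
#' @param reduced_platelets Reduced platelet count or function.
#' @param prior_major_bleed Prior major bleed (rebleeding risk factor).
#' @param uncontrolled_hypertension Uncontrolled hypertension.
#' @param anemia Anemia.
#' @param genetic_factors Genetic bleeding-risk factors.
#' @param fall_risk Excessive fall risk.
#' @param cad Coexisting coronary artery disease (drives the option menu).
#' @param current_medication One of `"none"`, `"aspirin"`, `"warfarin"`.
#'
#' @return An object of class `patient_profile`.
#' @examples
#' p <- patient_profile(age = 80, chf = TRUE, hypertension = TRUE)
#' chads2_score(p)
#' @export
patient_profile <- function(age,
                            chf = FALSE,
                            hypertension = FALSE,
                            diabetes = FALSE,
                            prior_stroke_tia = FALSE,
                            hepatic_or_renal_disease = FALSE,
                            ethanol_abuse = FALSE,
                            malignancy = FALSE,
                            reduced_platelets = FALSE,
                            prior_major_bleed = FALSE,
                            uncontrolled_hypertension = FALSE,
                            anemia = FALSE,
                            genetic_factors = FALSE,
                            fall_risk = FALSE,
                            cad = FALSE,
                            current_medication = "none") {
  profile <- list(
    age = age, chf = chf, hypertension = hypertension, diabetes = diabetes,
    prior_stroke_tia = prior_stroke_tia,
    hepatic_or_renal_disease = hepatic_or_renal_disease,
    ethanol_abuse = ethanol_abuse, malignancy = malignancy,
    reduced_platelets = reduced_platelets,
    prior_major_bleed = prior_major_bleed,
    uncontrolled_hypertension = uncontrolled_hypertension,
    anemia = anemia, genetic_factors = genetic_factors,
    fall_risk = fall_risk, cad = cad,
    current_medication = current_medication
  )
  validate_profile(profile)
}

validation_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("afdecide_validation_error", "error", "condition"),
    list(message = msg, call = NULL, field = field)
  ))
}

parse_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("afdecide_parse_error", "error", "condition"),
    list(message = msg, call = NULL, field = field)
  ))
}

#' Validate a patient profile
#'
#' Enforces the profile invariants: age an integer in \[18, 120\], every flag
#' a single non-missing logical, and `current_medication` one of the three
#' recognised values. Uncontrolled hypertension without a hypertension
#' history is inconsistent but clinically interpretable, so it raises a
#' warning rather than an error.
#'
#' @param profile A list or `patient_profile` with all fields present.
#' @return The validated `patient_profile` (age coerced to integer).
#' @export
validate_profile <- function(profile) {
  age <- profile$age
  if (is.null(age) || length(age) != 1L || is.na(suppressWarnings(as.numeric(age)))) {
    validation_error("field 'age' must be a single number", "age")
  }
  age <- as.numeric(age)
  if (age != trunc(age)) {
    validation_error("field 'age' must be a whole number of years", "age")
  }
  if (age < 18 || age > 120) {
    validation_error(
      sprintf("field 'age' must be between 18 and 120 years, got %s", age),
      "age"
    )
  }
  profile$age <- as.integer(age)

  for (flag in profile_flags()) {
    v <- profile[[flag]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !is.logical(as.logical(v)) ||
        is.na(as.logical(v))) {
      validation_error(sprintf("field '%s' must be TRUE or FALSE", flag), flag)
    }
    profile[[flag]] <- as.logical(v)
  }

  med <- profile$current_medication
  if (is.null(med) || length(med) != 1L || !med %in% medication_levels()) {
    validation_error(
      sprintf(
        "field 'current_medication' must be one of %s",
        paste(sQuote(medication_levels()), collapse = ", ")
      ),
      "current_medication"
    )
  }

  if (profile$uncontrolled_hypertension && !profile$hypertension) {
    warning(
      "uncontrolled_hypertension is TRUE but hypertension is FALSE; ",
      "check the record",
      call. = FALSE
    )
  }

  structure(profile[profile_fields()], class = "patient_profile")
}

#' Parse a patient profile from a key-value record
#'
#' Strict parser for profiles read from JSON or other key-value input: every
#' field must be present (no implicit defaults), no unknown keys are
#' tolerated, flags are coerced to logical and age to integer, and the
#' result is validated.
#'
#' @param record A named list (e.g. from `jsonlite::read_json()`).
#' @return A validated `patient_profile`.
#' @seealso [read_profile()] for file input, [profile_to_list()] for the
#'   inverse.
#' @export
parse_profile <- function(record) {
  if (!is.list(record) || is.null(names(record))) {
    parse_error("profile record must be a named key-value mapping")
  }
  missing <- setdiff(profile_fields(), names(record))
  if (length(missing) > 0L) {
    parse_error(
      sprintf(
        "profile record is missing required field(s): %s",
        paste(sQuote(missing), collapse = ", ")
      ),
      missing[[1L]]
    )
  }
  unknown <- setdiff(names(record), profile_fields())
  if (length(unknown) > 0L) {
    validation_error(sprintf(
      "unknown field(s) in profile record: %s; accepted fields are: %s",
      paste(sQuote(unknown), collapse = ", "),
      paste(profile_fields(), collapse = ", ")
    ))
  }
  for (flag in profile_flags()) {
    v <- record[[flag]]
    if (is.character(v) && length(v) == 1L &&
        tolower(v) %in% c("true", "false")) {
      v <- tolower(v) == "true"
    }
    if (is.numeric(v) && length(v) == 1L && v %in% c(0, 1)) v <- v == 1
    record[[flag]] <- v
  }
  validate_profile(record[profile_fields()])
}

#' Convert a profile to a plain named list
#'
#' The inverse of [parse_profile()]: `parse_profile(profile_to_list(p))` is
#' identical to `p` for every valid profile.
#'
#' @param profile A `patient_profile`.
#' @return A named list suitable for JSON serialisation.
#' @export
profile_to_list <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  out <- unclass(profile)
  out$age <- as.integer(out$age)
  out
}

#' Read a patient profile from a JSON file
#'
#' @param path Path to a JSON object with exactly the fields of
#'   [patient_profile()].
#' @return A validated `patient_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("profile file not found: %s", path), call. = FALSE)
  }
  record <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_profile(as.list(record))
}

#' Write a patient profile to a JSON file
#'
#' @param profile A `patient_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(
    profile_to_list(profile), path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Generate synthetic patient profiles
#'
#' Deterministic fixture generator covering the full risk-factor space: each
#' flag is drawn independently with probability 0.5, age is uniform on
#' \[40, 95\] years, and the current medication is uniform over its three
#' levels. For `n >= 4096` the set contains, with overwhelming probability,
#' profiles at both extremes of the CHADS2 score.
#'
#' @param n Number of profiles, at least 1.
#' @param seed Integer seed; the same seed always yields the same profiles.
#'   The global random-number state is left untouched.
#' @return A list of `n` `patient_profile` objects.
#' @export
generate_fixtures <- function(n, seed) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != trunc(n)) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  flags <- profile_flags()
  lapply(seq_len(n), function(i) {
    args <- as.list(stats::runif(length(flags)) < 0.5)
    names(args) <- flags
    args$age <- sample(40:95, 1L)
    args$current_medication <- sample(medication_levels(), 1L)
    # fixtures deliberately span the whole flag space, including combinations
    # (uncontrolled hypertension without a hypertension history) that the
    # validator flags as inconsistent for hand-entered records
    suppressWarnings(do.call(patient_profile, args))
  })
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("Patient profile: age %d, on %s\n", x$age, x$current_medication))
  on_flags <- profile_flags()[vapply(profile_flags(), function(f) x[[f]],
                                     logical(1))]
  if (length(on_flags) == 0L) {
    cat("  no risk factors\n")
  } else {
    cat("  risk factors:", paste(on_flags, collapse = ", "), "\n")
  }
  cat(sprintf(
    "  CHADS2 = %d, HEMORR2HAGES = %d\n",
    chads2_score(x), hemorrhages_score(x)
  ))
  invisible(x)
}
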