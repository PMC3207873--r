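# Which options are shown to whom, and the practical-issue and sequelae
# content attached to each. Patients with coronary artery disease stay on
# antiplatelet therapy by local practice norm, so "no treatment" is never
# offered to them, and the menu depends on what they take now.

#' Treatment options available to a patient
#'
#' Patients without coronary artery disease are offered no treatment,
#' aspirin, and warfarin. Patients with coronary artery disease currently
#' taking aspirin are offered aspirin alone or aspirin plus warfarin; those
#' taking warfarin alone are offered aspirin alone or warfarin alone. A
#' CAD patient on no antithrombotic is not a presentation context the menu
#' logic describes and is rejected.
#'
#' @param profile A `patient_profile`.
#' @return An object of class `option_menu`: list with `options` (ordered
#'   character vector of treatment options) and `context_note`.
#' @export
available_options <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  if (!profile$cad) {
    menu <- list(
      options = c("none", "aspirin", "warfarin"),
      context_note = paste(
        "No coexisting coronary artery disease:",
        "no treatment, aspirin alone, and warfarin alone are presented."
      )
    )
  } else if (profile$current_medication == "aspirin") {
    menu <- list(
      options = c("aspirin", "aspirin+warfarin"),
      context_note = paste(
        "Coronary artery disease, currently taking aspirin:",
        "aspirin alone and aspirin plus warfarin are presented."
      )
    )
  } else if (profile$current_medication == "warfarin") {
    menu <- list(
      options = c("aspirin", "warfarin"),
      context_note = paste(
        "Coronary artery disease, currently taking warfarin:",
        "aspirin alone and warfarin alone are presented."
      )
    )
  } else {
    stop(
      "no option menu is defined for coronary artery disease with no ",
      "current antithrombotic medication",
      call. = FALSE
    )
  }
  structure(menu, class = "option_menu")
}

#' @export
print.option_menu <- function(x, ...) {
  cat(x$context_note, "\n")
  cat("  options:",
      paste(vapply(x$options, option_label, character(1)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Practical issues of a treatment option
#'
#' No treatment and aspirin carry no regular blood tests and no activity or
#' diet restrictions. Any warfarin-containing option requires monthly blood
#' tests, avoiding activities that can cause serious injury, and watching
#' the amount of green, leafy vegetables in the diet.
#'
#' @param option A treatment option; see [treatment_options()].
#' @return Character vector of practical-issue lines.
#' @export
practical_issues <- function(option) {
  option <- as_treatment_option(option)
  if (option %in% c("none", "aspirin")) {
    c(
      "no need for regular blood tests",
      "no restriction of activities or diet"
    )
  } else {
    c(
      "monthly blood tests",
      "avoid activities that can cause serious injury",
      "watch the amount of green, leafy vegetables in the diet"
    )
  }
}

#' Sequelae distribution of an outcome
#'
#' What happens to people who have the event. For stroke: about half
#' recover, one quarter are disabled, one quarter die. For a major bleed:
#' about three quarters recover and a small number are disabled or die; the
#' residual quarter is split evenly between disability and death for
#' internal arithmetic, but rendered text keeps the qualitative "a small
#' number" wording.
#'
#' @param outcome `"stroke"` or `"major_bleed"`.
#' @return An object of class `sequelae_distribution`: list with `outcome`,
#'   `recover`, `disabled`, `die`; the three fractions sum to 1.
#' @export
sequelae <- function(outcome = c("stroke", "major_bleed")) {
  outcome <- match.arg(outcome)
  dist <- if (outcome == "stroke") {
    list(recover = 0.50, disabled = 0.25, die = 0.25)
  } else {
    list(recover = 0.75, disabled = 0.125, die = 0.125)
  }
  structure(c(list(outcome = outcome), dist), class = "sequelae_distribution")
}

#' @export
print.sequelae_distribution <- function(x, ...) {
  cat(sprintf(
    "%s sequelae: %.1f%% recover, %.1f%% disabled, %.1f%% die\n",
    gsub("_", " ", x$outcome), 100 * x$recover, 100 * x$disabled, 100 * x$die
  ))
  invisible(x)
}
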