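# Multi-year risk conversion and the per-option risk estimate. Annual rates
# become t-year cumulative risks through the declining exponential
# approximation of life expectancy (DEALE): risk = 1 - exp(-r * t).

#' Treatment options
#'
#' The four antithrombotic strategies the tool can present.
#'
#' @return Character vector
#'   `c("none", "aspirin", "warfarin", "aspirin+warfarin")`.
#' @export
treatment_options <- function() {
  c("none", "aspirin", "warfarin", "aspirin+warfarin")
}

as_treatment_option <- function(option) {
  if (length(option) != 1L || !option %in% treatment_options()) {
    stop(
      sprintf(
        "treatment option must be one of %s",
        paste(sQuote(treatment_options()), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  option
}

#' Display label for a treatment option
#'
#' @param option A treatment option; see [treatment_options()].
#' @return Human-readable label.
#' @export
option_label <- function(option) {
  switch(as_treatment_option(option),
    none = "No treatment",
    aspirin = "Aspirin",
    warfarin = "Warfarin",
    `aspirin+warfarin` = "Aspirin + warfarin"
  )
}

#' Convert an annual rate to a multi-year cumulative risk
#'
#' Declining exponential approximation: a constant annual event rate `r`
#' over `t` years gives cumulative risk `1 - exp(-r * t)`.
#'
#' @param rate Annual event rate, >= 0 (events per person-year).
#' @param years Horizon in years, > 0.
#' @return Probability in \[0, 1).
#' @examples
#' horizon_risk(0.182, 5) # 0.5975...
#' @export
horizon_risk <- function(rate, years) {
  if (any(is.na(rate)) || any(rate < 0)) {
    stop("'rate' must be non-negative", call. = FALSE)
  }
  if (any(is.na(years)) || any(years <= 0)) {
    stop("'years' must be positive", call. = FALSE)
  }
  1 - exp(-rate * years)
}

#' Round a probability to an integer percent
#'
#' Display convention: 100 times the probability, rounded half away from
#' zero to the nearest integer. Raw probabilities are kept at full precision
#' internally; this is applied only at display boundaries.
#'
#' @param p Probability (or vector of probabilities) in \[0, 1).
#' @return Integer percent in \[0, 100\].
#' @export
round_pct <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1)) {
    stop("'p' must be a probability in [0, 1)", call. = FALSE)
  }
  # guard against binary representation pushing an exact .5 just below it
  v <- round(100 * p, 9)
  as.integer(floor(v + 0.5))
}

#' Individualized risk estimate for one treatment option
#'
#' Composes the full pipeline for one patient and one option: risk score ->
#' annual rate -> treatment relative effect -> multi-year conversion ->
#' rounded integer percent, separately for stroke and major bleeding.
#'
#' @param profile A `patient_profile`.
#' @param option A treatment option; see [treatment_options()].
#' @param years Horizon in years (default 5).
#' @return An object of class `risk_estimate` with elements `option`,
#'   `years`, `stroke_rate_annual`, `bleed_rate_annual`, `stroke_risk`,
#'   `bleed_risk` (raw probabilities) and `stroke_pct`, `bleed_pct`
#'   (rounded integer percents).
#' @examples
#' p <- patient_profile(age = 60)
#' risk_estimate(p, "warfarin") # stroke 3%, bleed 9%
#' @export
risk_estimate <- function(profile, option, years = 5) {
  stopifnot(inherits(profile, "patient_profile"))
  option <- as_treatment_option(option)
  if (length(years) != 1L || is.na(years) || years <= 0) {
    stop("'years' must be a single positive number", call. = FALSE)
  }
  stroke_rate <- treated_stroke_rate(
    annual_stroke_rate(chads2_score(profile)), option
  )
  bleed_rate <- treated_bleed_rate(profile, option)
  stroke_risk <- horizon_risk(stroke_rate, years)
  bleed_risk <- horizon_risk(bleed_rate, years)
  structure(
    list(
      option = option,
      years = years,
      stroke_rate_annual = stroke_rate,
      bleed_rate_annual = bleed_rate,
      stroke_risk = stroke_risk,
      bleed_risk = bleed_risk,
      stroke_pct = round_pct(stroke_risk),
      bleed_pct = round_pct(bleed_risk)
    ),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf(
    "%s over %g years: stroke %d%%, major bleed %d%%\n",
    option_label(x$option), x$years, x$stroke_pct, x$bleed_pct
  ))
  cat(sprintf(
    "  annual rates: stroke %.4f, bleed %.4f per person-year\n",
    x$stroke_rate_annual, x$bleed_rate_annual
  ))
  invisible(x)
}

#' Attainable risk range for an option and outcome
#'
#' Brute-force enumeration of the discrete input space behind an outcome
#' pathway: all CHADS2 scores 0-6 for stroke; all HEMORR2HAGES rate bands
#' for bleeding on warfarin (with or without added aspirin); all age-band by
#' prior-bleed cells of the baseline table for bleeding with no treatment or
#' aspirin. Returns the minimum and maximum rounded percent over the space.
#'
#' @param option A treatment option; see [treatment_options()].
#' @param outcome `"stroke"` or `"bleed"`.
#' @param years Horizon in years (default 5).
#' @return Named integer vector `c(min = , max = )`.
#' @examples
#' enumerate_ranges("none", "stroke") # 9 to 60
#' @export
enumerate_ranges <- function(option, outcome = c("stroke", "bleed"),
                             years = 5) {
  option <- as_treatment_option(option)
  outcome <- match.arg(outcome)
  rates <- if (outcome == "stroke") {
    vapply(0:6, function(s) treated_stroke_rate(annual_stroke_rate(s), option),
           numeric(1))
  } else if (option %in% c("warfarin", "aspirin+warfarin")) {
    mult <- if (option == "aspirin+warfarin") .ASPIRIN_BLEED_RR else 1
    vapply(c(0:4, 5L), warfarin_bleed_rate, numeric(1)) * mult
  } else {
    mult <- if (option == "aspirin") .ASPIRIN_BLEED_RR else 1
    as.vector(.BASELINE_BLEED_TABLE) * mult
  }
  pct <- round_pct(horizon_risk(rates, years))
  c(min = min(pct), max = max(pct))
}

#' Attainable-range table for every option and outcome
#'
#' Runs [enumerate_ranges()] over all option-outcome pairs.
#'
#' @param years Horizon in years (default 5).
#' @return A data frame with columns `option`, `outcome`, `min_pct`,
#'   `max_pct`.
#' @export
range_table <- function(years = 5) {
  grid <- expand.grid(
    outcome = c("stroke", "bleed"),
    option = treatment_options(),
    stringsAsFactors = FALSE
  )[, c("option", "outcome")]
  ranges <- mapply(
    function(opt, out) enumerate_ranges(opt, out, years),
    grid$option, grid$outcome
  )
  data.frame(
    option = grid$option,
    outcome = grid$outcome,
    min_pct = as.integer(ranges["min", ]),
    max_pct = as.integer(ranges["max", ]),
    row.names = NULL
  )
}
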