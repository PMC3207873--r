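test_that("CHADS2 scoring assigns the documented weights", {
  expect_identical(chads2_score(minimal_profile(age = 60)), 0L)
  expect_identical(chads2_score(minimal_profile(prior_stroke_tia = TRUE)), 2L)
  expect_identical(chads2_score(minimal_profile(age = 75)), 1L)
  expect_identical(chads2_score(minimal_profile(age = 74)), 0L)
  expect_identical(
    chads2_score(patient_profile(age = 80, chf = TRUE, hypertension = TRUE,
                                 diabetes = TRUE, prior_stroke_tia = TRUE)),
    6L
  )
})

test_that("HEMORR2HAGES scoring assigns the documented weights", {
  expect_identical(hemorrhages_score(minimal_profile(age = 60)), 0L)
  expect_identical(
    hemorrhages_score(minimal_profile(prior_major_bleed = TRUE)), 2L
  )
  # older-age criterion is strictly greater than 75, unlike CHADS2
  expect_identical(hemorrhages_score(minimal_profile(age = 75)), 0L)
  expect_identical(hemorrhages_score(minimal_profile(age = 76)), 1L)
  expect_identical(hemorrhages_score(maximal_profile(age = 80)), 12L)
})

test_that("both scores stay in range over the whole flag space", {
  profiles <- generate_fixtures(512, seed = 11)
  chads <- vapply(profiles, chads2_score, integer(1))
  hemorr <- vapply(profiles, hemorrhages_score, integer(1))
  expect_true(all(chads >= 0L & chads <= 6L))
  expect_true(all(hemorr >= 0L & hemorr <= 12L))
})

test_that("rate tables look up correctly and reject out-of-range scores", {
  expect_identical(annual_stroke_rate(0), 0.019)
  expect_identical(annual_stroke_rate(6), 0.182)
  expect_error(annual_stroke_rate(7), "CHADS2")
  expect_error(annual_stroke_rate(-1), "CHADS2")

  expect_identical(warfarin_bleed_rate(0), 0.019)
  expect_identical(warfarin_bleed_rate(5), 0.123)
  expect_identical(warfarin_bleed_rate(12), 0.123) # capped top band
  expect_error(warfarin_bleed_rate(13), "HEMORR2HAGES")

  # strictly increasing up to the cap
  stroke <- vapply(0:6, annual_stroke_rate, numeric(1))
  expect_true(all(diff(stroke) > 0))
  bleed <- vapply(0:5, warfarin_bleed_rate, numeric(1))
  expect_true(all(diff(bleed) > 0))
})

test_that("baseline bleeding table is stratified by age band and prior bleed", {
  expect_identical(baseline_bleed_rate(minimal_profile(age = 50)), 0.0012)
  expect_identical(
    baseline_bleed_rate(minimal_profile(age = 85, prior_major_bleed = TRUE)),
    0.060
  )
  # band lower bounds are inclusive
  expect_identical(baseline_bleed_rate(minimal_profile(age = 59)), 0.0012)
  expect_identical(baseline_bleed_rate(minimal_profile(age = 60)), 0.005)
  expect_identical(baseline_bleed_rate(minimal_profile(age = 80)), 0.025)
  # monotone in age and in prior bleed
  ages <- c(50, 65, 75, 85)
  no_bleed <- vapply(ages, function(a) {
    baseline_bleed_rate(minimal_profile(age = a))
  }, numeric(1))
  bleed <- vapply(ages, function(a) {
    baseline_bleed_rate(minimal_profile(age = a, prior_major_bleed = TRUE))
  }, numeric(1))
  expect_true(all(diff(no_bleed) > 0))
  expect_true(all(diff(bleed) > 0))
  expect_true(all(bleed > no_bleed))
})

test_that("treatment effects modify rates by the stated relative risks", {
  expect_equal(treated_stroke_rate(0.10, "none"), 0.10)
  expect_equal(treated_stroke_rate(0.10, "aspirin"), 0.079)
  expect_equal(treated_stroke_rate(0.10, "warfarin"), 0.033)
  # adding aspirin to warfarin confers no extra stroke protection
  expect_equal(treated_stroke_rate(0.10, "aspirin+warfarin"), 0.033)
  expect_error(treated_stroke_rate(-0.1, "none"), "non-negative")
  expect_error(treated_stroke_rate(0.1, "heparin"), "option")

  p <- minimal_profile(age = 50)
  expect_identical(treated_bleed_rate(p, "none"), 0.0012)
  expect_identical(treated_bleed_rate(p, "aspirin"), 0.0024)
  expect_identical(treated_bleed_rate(p, "warfarin"), 0.019)
  expect_identical(treated_bleed_rate(p, "aspirin+warfarin"), 0.038)
})

test_that("horizon conversion follows the declining exponential form", {
  expect_identical(horizon_risk(0, 5), 0)
  expect_equal(horizon_risk(0.182, 5), 1 - exp(-0.91))
  expect_equal(round(horizon_risk(0.182, 5), 4), 0.5975)
  expect_equal(round(horizon_risk(0.019, 5), 4), 0.0906)
  expect_error(horizon_risk(-0.1, 5), "rate")
  expect_error(horizon_risk(0.1, 0), "years")

  # strictly increasing in rate and in years
  rates <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(horizon_risk(rates, 5)) > 0))
  yrs <- 1:30
  expect_true(all(diff(vapply(yrs, function(t) horizon_risk(0.05, t),
                              numeric(1))) > 0))
})

test_that("small-rate limit agrees with the linear approximation", {
  for (rt in c(0.02, 0.01, 0.005, 0.001)) {
    ratio <- horizon_risk(rt / 5, 5) / rt
    expect_lt(abs(ratio - 1), 0.01)
  }
})

test_that("percent rounding is half away from zero at the display boundary", {
  expect_identical(round_pct(0.0906), 9L)
  expect_identical(round_pct(0.455), 46L)
  expect_identical(round_pct(0.5975), 60L)
  expect_identical(round_pct(0.004999), 0L)
  expect_identical(round_pct(0.005), 1L)
  expect_identical(round_pct(0), 0L)
  expect_error(round_pct(1), "probability")
  expect_error(round_pct(-0.1), "probability")
})

test_that("risk_estimate composes scores, rates, treatment and horizon", {
  p0 <- minimal_profile(age = 60)
  est <- risk_estimate(p0, "warfarin")
  expect_identical(est$stroke_pct, 3L)
  expect_identical(est$bleed_pct, 9L)

  worst <- maximal_profile(age = 80)
  expect_identical(risk_estimate(worst, "none")$stroke_pct, 60L)

  # limit of a vanishing horizon
  tiny <- risk_estimate(worst, "none", years = 1e-9)
  expect_identical(tiny$stroke_pct, 0L)
  expect_identical(tiny$bleed_pct, 0L)
})

test_that("estimate fields equal the pipeline recomputed from parts", {
  profiles <- generate_fixtures(40, seed = 3)
  for (p in profiles) {
    for (opt in treatment_options()) {
      est <- risk_estimate(p, opt)
      stroke_rate <- treated_stroke_rate(annual_stroke_rate(chads2_score(p)),
                                         opt)
      expect_identical(est$stroke_rate_annual, stroke_rate)
      expect_identical(est$stroke_pct,
                       round_pct(horizon_risk(stroke_rate, 5)))
      expect_identical(est$bleed_pct,
                       round_pct(horizon_risk(treated_bleed_rate(p, opt), 5)))
      expect_true(est$stroke_risk >= 0 && est$stroke_risk < 1)
      expect_true(est$bleed_risk >= 0 && est$bleed_risk < 1)
      expect_true(est$stroke_pct >= 0L && est$stroke_pct <= 100L)
      expect_true(est$bleed_pct >= 0L && est$bleed_pct <= 100L)
    }
  }
})

test_that("stroke risk orders warfarin below aspirin below no treatment", {
  profiles <- generate_fixtures(60, seed = 5)
  for (p in profiles) {
    none <- risk_estimate(p, "none")$stroke_risk
    asa <- risk_estimate(p, "aspirin")$stroke_risk
    war <- risk_estimate(p, "warfarin")$stroke_risk
    expect_lt(war, asa)
    expect_lt(asa, none)
  }
})

test_that("range enumeration matches the exhaustive profile-space oracle", {
  cases <- expand.grid(
    option = treatment_options(),
    outcome = c("stroke", "bleed"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    opt <- cases$option[i]
    out <- cases$outcome[i]
    expect_identical(
      enumerate_ranges(opt, out),
      exhaustive_range(opt, out),
      info = paste(opt, out)
    )
  }
})

test_that("range enumeration respects a shorter horizon", {
  r1 <- enumerate_ranges("none", "stroke", years = 1)
  r5 <- enumerate_ranges("none", "stroke", years = 5)
  expect_true(all(r1 < r5))
  tiny <- enumerate_ranges("none", "stroke", years = 1e-9)
  expect_identical(unname(tiny), c(0L, 0L))
})

test_that("embedded rate constants match the shipped audit JSON", {
  shipped <- jsonlite::read_json(
    system.file("extdata", "rate_tables.json", package = "afdecide"),
    simplifyVector = TRUE
  )
  tables <- rate_tables()
  expect_equal(unlist(shipped$chads2_stroke_rates),
               tables$chads2_stroke_rates)
  expect_equal(unlist(shipped$hemorrhages_bleed_rates),
               tables$hemorrhages_bleed_rates)
  expect_equal(shipped$baseline_bleed_table$no_prior_bleed,
               unname(tables$baseline_bleed_table[, "no_prior_bleed"]))
  expect_equal(shipped$baseline_bleed_table$prior_bleed,
               unname(tables$baseline_bleed_table[, "prior_bleed"]))
  expect_equal(shipped$aspirin_stroke_rrr, tables$aspirin_stroke_rrr)
  expect_equal(shipped$warfarin_stroke_rrr, tables$warfarin_stroke_rrr)
  expect_equal(shipped$aspirin_bleed_rr, tables$aspirin_bleed_rr)
})
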