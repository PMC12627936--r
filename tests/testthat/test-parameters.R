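test_that("default fixture echoes the published anchor values and validates", {
  p <- default_parameters()
  expect_identical(unname(p$initial_distribution), c(0.205, 0.394, 0.401))
  expect_identical(p$admitted_fraction, 0.39)
  expect_identical(p$discount_rate_annual, 0.035)
  expect_identical(p$horizon_years, 20)
  expect_identical(p$cycles_per_year, 52)
  expect_identical(validate_parameters(p), character(0))
})

test_that("parameter file round-trips bit-exactly and applies defaults", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  q <- load_parameters(f)
  expect_identical(q$initial_distribution, p$initial_distribution)
  expect_identical(q$full_adherence_transitions, p$full_adherence_transitions)
  expect_identical(q$exacerbation_recovery, p$exacerbation_recovery)
  expect_identical(q$zero_adherence_odds_ratios, p$zero_adherence_odds_ratios)
  expect_identical(q$outpatient_interval_weeks, p$outpatient_interval_weeks)  # incl. 13/3
  expect_identical(q$utilities, p$utilities)
  expect_identical(q$costs$rescue_weekly, p$costs$rescue_weekly)
  expect_identical(q$utility_adjustment, p$utility_adjustment)
  for (nm in names(p$distributions)) {
    expect_identical(q$distributions[[nm]]$family, p$distributions[[nm]]$family)
    expect_identical(unname(q$distributions[[nm]]$params),
                     unname(p$distributions[[nm]]$params))
  }

  # omitted optional fields take documented defaults
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  raw$discount_rate_annual <- NULL
  raw$cohort_start_age <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, f2, auto_unbox = TRUE, digits = NA)
  q2 <- load_parameters(f2)
  expect_identical(q2$discount_rate_annual, 0.035)
  expect_identical(q2$cohort_start_age, 40)

  # missing required field -> schema error naming it
  raw$initial_distribution <- NULL
  jsonlite::write_json(raw, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(f2), "initial_distribution")
})

test_that("validation reports every violation and names the offending field", {
  p <- default_parameters()
  bad <- unclass(p)
  bad$initial_distribution <- c(Controlled = 0.2, PartiallyControlled = 0.394,
                                Uncontrolled = 0.306)  # sums to 0.9
  bad$costs$outpatient_visit <- -5
  bad$full_adherence_transitions["Controlled", "Exacerbation"] <- 1.2
  v <- validate_parameters(bad)
  expect_gte(length(v), 3)
  expect_match(v, "initial_distribution", all = FALSE)
  expect_match(v, "costs.outpatient_visit", all = FALSE)
  expect_match(v, "full_adherence_transitions", all = FALSE)

  # constructor surfaces out-of-range transition probabilities
  expect_error(
    toy_parameters(full_adherence_transitions = {
      tr <- toy_parameters()$full_adherence_transitions; tr[1, 4] <- 1.2; tr
    }),
    "full_adherence_transitions")
})

test_that("random plausible parameter sets always validate (100+ seeds) and are seeded", {
  for (s in 1:120)
    expect_identical(validate_parameters(random_plausible_parameters(s)), character(0))
  expect_identical(random_plausible_parameters(1), random_plausible_parameters(1))
  expect_false(identical(random_plausible_parameters(1), random_plausible_parameters(2)))
})

test_that("life table loading validates and carries the last row forward", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("age\tqx", "40\t0.001", "41\t0.0011"), f)
  lt <- load_life_table(f)
  expect_equal(nrow(lt), 2)
  expect_equal(annual_mortality(lt, 45), 0.0011)   # carry-forward past table end
  expect_equal(annual_mortality(lt, 40.9), 0.001)  # integer-part lookup

  writeLines(c("age\tqx", "41\t0.001", "40\t0.0011", "43\t0.002"), f)
  expect_error(load_life_table(f), "contiguous")
  writeLines(c("age\tqx", "40\t1.5"), f)
  expect_error(load_life_table(f), "\\[0,1\\]")

  # optional sex column is blended per age
  writeLines(c("age\tqx\tsex", "40\t0.001\tM", "40\t0.003\tF"), f)
  expect_equal(annual_mortality(load_life_table(f), 40), 0.002)
})

test_that("weekly mortality follows the complement-power rule", {
  lt0 <- life_table(40:41, c(0, 1))
  expect_identical(weekly_mortality(lt0, 40), 0)
  expect_identical(weekly_mortality(lt0, 41), 1)

  lt <- life_table(40:40, 0.01)
  # frozen from an arbitrary-precision evaluation of 1 - 0.99^(1/52)
  expect_equal(weekly_mortality(lt, 40), 1.93257012947598e-4, tolerance = 1e-12)

  # inverse identity and monotonicity across the q range
  qs <- seq(0, 0.999, length.out = 200)
  wk <- weekly_mortality(life_table(seq_along(qs), qs), seq_along(qs))
  expect_true(all(diff(wk) >= 0))
  expect_equal(1 - (1 - wk)^52, qs, tolerance = 1e-12)
})

test_that("moment-matched distribution tags hit their targets", {
  b <- beta_from_mean_se(0.8, 0.05)
  expect_equal(b$params[1] / sum(b$params), 0.8)
  g <- gamma_from_mean_se(163, 32.6)
  expect_equal(g$params[1] * g$params[2], 163)
  ln <- lognormal_from_mean_se(3, 0.6)
  expect_equal(exp(ln$params[1] + ln$params[2]^2 / 2), 3)
  expect_length(validate_dist_spec(b), 0)
  expect_match(validate_dist_spec(structure(
    list(family = "beta", params = c(-1, 2), mean = 0.5), class = "dist_spec")),
    "shape", all = FALSE)
})
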