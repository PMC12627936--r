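test_that("discount factors match the closed form", {
  expect_identical(discount_factor(0, 0.035, 52), 1)
  expect_equal(discount_factor(52, 0.035, 52), 1 / 1.035, tolerance = 1e-15)
  # frozen from arbitrary-precision 1.035^-20
  expect_equal(discount_factor(1040, 0.035, 52), 0.50256588443167, tolerance = 1e-12)
})

test_that("a static immortal cohort lives exactly the horizon", {
  p <- toy_parameters()      # no transitions, no exacerbations, no asthma death
  tr <- run_cohort(p, 1, zero_life_table())
  expect_equal(life_years(tr), 20)
  expect_equal(count_exacerbations(tr), 0)
  expect_equal(unname(tr$occupancy[nrow(tr$occupancy), ]), c(1, 0, 0, 0, 0))
  expect_equal(qalys(tr, p), 20, tolerance = 1e-12)  # utility 1, no discounting
})

test_that("two-state toy matches an independent hand recursion", {
  # single control state, weekly exacerbation entry 0.1, certain one-week
  # recovery, no death, 10 cycles
  tr3 <- toy_parameters()$full_adherence_transitions
  tr3["Controlled", "Exacerbation"] <- 0.1
  p <- toy_parameters(full_adherence_transitions = tr3,
                      horizon_years = 10 / 52, discount_rate_annual = 0)
  trace <- run_cohort(p, 1, zero_life_table())

  # oracle: 2-state recursion tracked by hand
  pc <- 1; px <- 0; inc <- numeric(10); occ_c <- numeric(10); occ_x <- numeric(10)
  for (c in 1:10) {
    inc[c] <- 0.1 * pc
    new_pc <- 0.9 * pc + px
    new_px <- 0.1 * pc
    pc <- new_pc; px <- new_px
    occ_c[c] <- pc; occ_x[c] <- px
  }
  expect_equal(trace$incident_exacerbations, inc, tolerance = 1e-14)
  expect_equal(unname(trace$occupancy[-1, "Controlled"]), occ_c, tolerance = 1e-14)
  expect_equal(unname(trace$occupancy[-1, "Exacerbation"]), occ_x, tolerance = 1e-14)
  expect_equal(count_exacerbations(trace), sum(inc), tolerance = 1e-14)

  # doubling the entry probability increases the expected count
  tr3["Controlled", "Exacerbation"] <- 0.2
  p2 <- toy_parameters(full_adherence_transitions = tr3,
                       horizon_years = 10 / 52, discount_rate_annual = 0)
  expect_gt(count_exacerbations(run_cohort(p2, 1, zero_life_table())),
            count_exacerbations(trace))
})

test_that("constant-hazard life years match the geometric series within 1e-9", {
  s <- 0.999                               # weekly survival
  p <- toy_parameters()
  trace <- run_cohort(p, 1, constant_weekly_survival_life_table(s))
  n <- 1040
  expect_equal(life_years(trace), s * (1 - s^n) / (1 - s) / 52, tolerance = 1e-9)
})

test_that("rate-zero QALYs equal utility-weighted life years exactly", {
  p <- default_parameters()
  p$discount_rate_annual <- 0
  p$utility_adjustment <- flat_utility_adjustment()
  p$utilities <- list(Controlled = 1, PartiallyControlled = 1, Uncontrolled = 1,
                      ExacerbationAdmitted = 1, ExacerbationNonAdmitted = 1)
  trace <- run_cohort(p, 0.5, default_life_table())
  expect_equal(qalys(trace, p), life_years(trace), tolerance = 1e-12)

  # linearity: halving all utilities halves QALYs
  p2 <- default_parameters()
  trace2 <- run_cohort(p2, 0.5, default_life_table())
  q1 <- qalys(trace2, p2)
  p2$utilities <- lapply(p2$utilities, function(u) u / 2)
  expect_equal(qalys(trace2, p2), q1 / 2, tolerance = 1e-12)

  # discounting can only shrink QALYs
  expect_lte(qalys(trace2, p2), qalys(trace2, p2, rate_annual = 0))
})

test_that("exacerbation utility is the admitted/non-admitted mixture", {
  p <- toy_parameters(admitted_fraction = 0.39,
                      utilities = list(Controlled = 1, PartiallyControlled = 1,
                                       Uncontrolled = 1, ExacerbationAdmitted = 0.5,
                                       ExacerbationNonAdmitted = 0.7),
                      discount_rate_annual = 0)
  # hand-built trace: whole cohort in the exacerbation state for 52 cycles
  occ <- matrix(0, 53, 5, dimnames = list(NULL, CONTROL_STATES))
  occ[, 4] <- 1
  trace <- manual_trace(occ, rep(0, 52))
  expect_equal(qalys(trace, p), 0.39 * 0.5 + 0.61 * 0.7, tolerance = 1e-12)  # 0.622
})

test_that("cost streams follow their stated rules", {
  # fully controlled static cohort, GBP 100 visits, 26 cycles, no discounting
  p <- toy_parameters(horizon_years = 0.5, discount_rate_annual = 0)
  p$costs$outpatient_visit <- 100
  trace <- run_cohort(p, 1, zero_life_table())
  cc <- costs(trace, p, 1)
  expect_equal(cc[["outpatient"]], 100, tolerance = 1e-12)  # 26 * (1/26) * 100
  expect_equal(cc[["exacerbation_admitted"]] + cc[["exacerbation_nonadmitted"]], 0)

  # maintenance scales linearly with adherence and vanishes at a = 0
  p$costs$maintenance_weekly <- 10
  expect_equal(costs(trace, p, 0)[["maintenance"]], 0)
  expect_equal(costs(trace, p, 0.5)[["maintenance"]],
               costs(trace, p, 1)[["maintenance"]] / 2, tolerance = 1e-12)

  # rescue accrues per occupied week
  p$costs$rescue_weekly["Controlled"] <- 2
  expect_equal(costs(trace, p, 1)[["rescue"]], 2 * 26, tolerance = 1e-12)
})

test_that("summaries aggregate the four outputs and respect bounds", {
  p <- default_parameters()
  trace <- run_cohort(p, 0.7, default_life_table())
  s <- summarize_outcomes(trace, p, 0.7)
  expect_gte(s$total_exacerbations, 0)
  expect_lte(s$life_years, p$horizon_years)
  expect_lte(s$qalys_discounted, qalys(trace, p, rate_annual = 0))
  expect_true(all(s$costs_discounted >= 0))
  expect_equal(s$costs_discounted[["total"]],
               sum(s$costs_discounted[setdiff(names(s$costs_discounted), "total")]),
               tolerance = 1e-12)
})

test_that("mass is conserved and death is monotone over random parameterizations", {
  lt <- default_life_table()
  for (s in 1:25) {
    p <- random_plausible_parameters(s)
    p$horizon_years <- 2                     # 104 cycles is enough to catch drift
    trace <- run_cohort(p, runif(1), lt)
    expect_true(all(abs(rowSums(trace$occupancy) - 1) < 1e-9))
    expect_true(all(diff(trace$occupancy[, "Dead"]) >= -1e-15))
    expect_true(all(trace$incident_exacerbations >= 0))
  }
})

test_that("trace export writes an audited per-cycle table", {
  p <- toy_parameters(horizon_years = 4 / 52)
  trace <- run_cohort(p, 1, zero_life_table())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(trace, p, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# asthmod")
  body <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), 5)   # cycles + 1
  expect_true(all(c("Controlled", "incident_exacerbations", "discount_factor")
                  %in% names(body)))
})
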