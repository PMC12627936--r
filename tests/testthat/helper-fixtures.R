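# fixtures are built in code; no binary data anywhere in the suite

# life table with zero mortality at every age
zero_life_table <- function() life_table(0:110, rep(0, 111))

# life table with the constant annual mortality implied by weekly survival s
constant_weekly_survival_life_table <- function(s) {
  q_annual <- 1 - s^52
  life_table(0:110, rep(q_annual, 111))
}

# minimal valid parameter set; overridable field by field.
# defaults: no movement, no exacerbations, no asthma death, OR 1, flat
# utility adjustment -- the "static cohort" used by closed-form oracles.
toy_parameters <- function(...) {
  tr <- matrix(0, 3, 4, dimnames = list(
    c("Controlled", "PartiallyControlled", "Uncontrolled"),
    c("Controlled", "PartiallyControlled", "Uncontrolled", "Exacerbation")))
  base <- list(
    initial_distribution = c(Controlled = 1, PartiallyControlled = 0, Uncontrolled = 0),
    full_adherence_transitions = tr,
    exacerbation_recovery = c(Controlled = 1, PartiallyControlled = 0, Uncontrolled = 0),
    zero_adherence_odds_ratios = c(Controlled = 1, PartiallyControlled = 1, Uncontrolled = 1),
    exacerbation_case_fatality = 0,
    admitted_fraction = 0.39,
    utilities = list(Controlled = 1, PartiallyControlled = 1, Uncontrolled = 1,
                     ExacerbationAdmitted = 1, ExacerbationNonAdmitted = 1),
    costs = list(maintenance_weekly = 0, outpatient_visit = 0,
                 rescue_weekly = c(Controlled = 0, PartiallyControlled = 0,
                                   Uncontrolled = 0, Exacerbation = 0),
                 exacerbation_nonadmitted = 0, exacerbation_admitted = 0),
    outpatient_interval_weeks = c(Controlled = 26, PartiallyControlled = 13,
                                  Uncontrolled = 13 / 3),
    discount_rate_annual = 0,
    horizon_years = 20,
    cycles_per_year = 52,
    cohort_start_age = 40,
    sex_mix = 0.5
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  do.call(asthma_parameters, base)
}

# hand-built trace (for reward-function unit tests that need exact occupancy)
manual_trace <- function(occupancy, incident, cycles_per_year = 52, start_age = 40) {
  n <- nrow(occupancy) - 1
  structure(list(occupancy = occupancy, incident_exacerbations = incident,
                 ages = start_age + seq_len(n) / cycles_per_year,
                 cycles_per_year = cycles_per_year),
            class = "cohort_trace")
}

# ---- microsimulation oracle -------------------------------------------
# simulates individual patient paths with the SAME per-cycle matrices the
# cohort engine uses; an independent estimate of occupancy, exacerbations,
# life years and undiscounted QALYs, with Monte-Carlo standard errors.
microsim_oracle <- function(p, a, lt, n_paths, seed) {
  set.seed(seed)
  n_cycles <- round(p$horizon_years * p$cycles_per_year)
  age_at <- floor(p$cohort_start_age + (seq_len(n_cycles) - 1) / p$cycles_per_year)

  u_ex <- p$admitted_fraction * p$utilities$ExacerbationAdmitted +
    (1 - p$admitted_fraction) * p$utilities$ExacerbationNonAdmitted
  u_state <- c(p$utilities$Controlled, p$utilities$PartiallyControlled,
               p$utilities$Uncontrolled, u_ex, 0)

  state <- sample.int(3, n_paths, replace = TRUE, prob = p$initial_distribution)
  exac <- numeric(n_paths)
  alive_weeks <- numeric(n_paths)
  qaly_weeks <- numeric(n_paths)

  cache <- list()
  for (cyc in seq_len(n_cycles)) {
    key <- as.character(age_at[cyc])
    cm <- cache[[key]]
    if (is.null(cm)) {
      M <- build_matrix(p, a, age_at[cyc], lt)
      cm <- t(apply(unclass(M), 1, cumsum))
      cache[[key]] <- cm
    }
    u <- runif(n_paths)
    new_state <- state
    for (s in 1:4) {
      idx <- which(state == s)
      if (length(idx))
        new_state[idx] <- 1L + findInterval(u[idx], cm[s, 1:4])
    }
    exac <- exac + (new_state == 4L & state != 4L)
    adj <- (1 - p$sex_mix) *
      p$utility_adjustment$male[max(1, findInterval(age_at[cyc], p$utility_adjustment$age_from))] +
      p$sex_mix *
      p$utility_adjustment$female[max(1, findInterval(age_at[cyc], p$utility_adjustment$age_from))]
    alive_weeks <- alive_weeks + (new_state != 5L)
    qaly_weeks <- qaly_weeks + u_state[new_state] * adj
    state <- new_state
  }

  occ_final <- tabulate(state, nbins = 5) / n_paths
  mse <- function(x) c(mean = mean(x), se = sd(x) / sqrt(n_paths))
  list(
    occupancy_final = occ_final,
    occupancy_final_se = sqrt(occ_final * (1 - occ_final) / n_paths),
    exacerbations = mse(exac),
    life_years = mse(alive_weeks / p$cycles_per_year),
    qalys_undiscounted = mse(qaly_weeks / p$cycles_per_year)
  )
}
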