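#' Discount factor for a model cycle
#'
#' `(1 + rate_annual)^(-cycle / cycles_per_year)`; cycle 0 is undiscounted.
#'
#' @param cycle Cycle index (>= 0, vectorized).
#' @param rate_annual Annual discount rate.
#' @param cycles_per_year Cycles per year.
#' @return Discount factor(s).
#' @examples
#' discount_factor(52, 0.035, 52)   # 1/1.035
#' @export
discount_factor <- function(cycle, rate_annual, cycles_per_year) {
  (1 + rate_annual)^(-cycle / cycles_per_year)
}

#' Run the deterministic weekly cohort recursion
#'
#' Propagates the cohort's state occupancy through
#' `horizon_years * cycles_per_year` weekly cycles. Occupancy row 0 places
#' the initial distribution over the three control states; each subsequent
#' row is the previous row times the age-specific transition matrix at the
#' given adherence level (the cohort ages 1/52 year per cycle; the life
#' table is looked up on the integer age). The expected flow of the cohort
#' into the exacerbation state is recorded each cycle.
#'
#' @param p An `asthma_parameters` object.
#' @param a Adherence rate in \[0, 1\].
#' @param lt A `life_table` (default [default_life_table()]).
#' @return A `cohort_trace`: list with `occupancy` ((cycles+1) x 5 matrix),
#'   `incident_exacerbations` (length cycles), `ages` (cohort age at the end
#'   of each cycle), and `cycles_per_year`.
#' @export
run_cohort <- function(p, a, lt = default_life_table()) {
  n_cycles <- round(p$horizon_years * p$cycles_per_year)
  occ <- matrix(0, n_cycles + 1, 5, dimnames = list(NULL, CONTROL_STATES))
  occ[1, 1:3] <- p$initial_distribution
  incident <- numeric(n_cycles)

  # matrices vary only with integer age; cache per distinct age
  age_at <- floor(p$cohort_start_age + (seq_len(n_cycles) - 1) / p$cycles_per_year)
  cache <- list()
  v <- occ[1, ]
  for (c in seq_len(n_cycles)) {
    key <- as.character(age_at[c])
    M <- cache[[key]]
    if (is.null(M)) {
      M <- build_matrix(p, a, age_at[c], lt)
      cache[[key]] <- M
    }
    incident[c] <- sum(v[1:3] * M[1:3, 4])
    v <- as.vector(v %*% M)
    s <- sum(v)
    if (abs(s - 1) > 1e-9)
      stop("numerical consistency error: occupancy mass drifted to ", s, call. = FALSE)
    occ[c + 1, ] <- v
  }

  structure(list(
    occupancy = occ,
    incident_exacerbations = incident,
    ages = p$cohort_start_age + seq_len(n_cycles) / p$cycles_per_year,
    cycles_per_year = p$cycles_per_year
  ), class = "cohort_trace")
}

#' Expected exacerbations over the horizon
#'
#' @param t A `cohort_trace`.
#' @return Expected number of exacerbations per cohort member.
#' @export
count_exacerbations <- function(t) {
  sum(t$incident_exacerbations)
}

#' Undiscounted life years over the horizon
#'
#' Sum over cycles of the alive fraction times the cycle length.
#'
#' @param t A `cohort_trace`.
#' @return Life years (<= horizon).
#' @export
life_years <- function(t) {
  alive <- 1 - t$occupancy[-1, "Dead"]
  sum(alive) / t$cycles_per_year
}

# sex-mixed age multiplier from the utility adjustment table
utility_multiplier <- function(p, ages) {
  ua <- p$utility_adjustment
  i <- findInterval(floor(ages), ua$age_from)
  i[i < 1] <- 1L
  (1 - p$sex_mix) * ua$male[i] + p$sex_mix * ua$female[i]
}

#' Discounted quality-adjusted life years
#'
#' Per cycle, occupancy is weighted by state utility (the exacerbation
#' state uses the admitted/non-admitted mixture
#' `admitted_fraction * u_admitted + (1 - admitted_fraction) * u_nonadmitted`),
#' by the age/sex utility multiplier, by the cycle length, and by the
#' discount factor.
#'
#' @param t A `cohort_trace`.
#' @param p The `asthma_parameters` used to generate it.
#' @param rate_annual Discount rate override (default: from `p`; pass 0 for
#'   undiscounted QALYs).
#' @return Discounted QALYs.
#' @export
qalys <- function(t, p, rate_annual = p$discount_rate_annual) {
  u_ex <- p$admitted_fraction * p$utilities$ExacerbationAdmitted +
    (1 - p$admitted_fraction) * p$utilities$ExacerbationNonAdmitted
  u <- c(p$utilities$Controlled, p$utilities$PartiallyControlled,
         p$utilities$Uncontrolled, u_ex)
  n <- length(t$incident_exacerbations)
  df <- discount_factor(seq_len(n), rate_annual, t$cycles_per_year)
  adj <- utility_multiplier(p, t$ages)
  per_cycle <- as.vector(t$occupancy[-1, 1:4, drop = FALSE] %*% u)
  sum(per_cycle * adj * df) / t$cycles_per_year
}

#' Discounted, decomposed NHS/PSS costs
#'
#' Accumulates four discounted cost streams per cycle (2022 GBP):
#' * `maintenance` — weekly maintenance-therapy cost scaled linearly by the
#'   adherence rate (possession-ratio consumption), over alive
#'   non-exacerbation occupancy;
#' * `outpatient` — expected routine visits per cycle
#'   (`1 / outpatient_interval_weeks`, intervals 26 / 13 / 13÷3 weeks by
#'   control state) times the unit attendance cost — independent of
#'   adherence;
#' * `rescue` — state-specific weekly reliever cost — independent of
#'   adherence;
#' * `exacerbation_nonadmitted` / `exacerbation_admitted` — incident
#'   exacerbations costed per episode, split 39%/61% admitted/non-admitted.
#'
#' @param t A `cohort_trace`.
#' @param p The `asthma_parameters` used to generate it.
#' @param a Adherence rate (scales the maintenance stream only).
#' @param rate_annual Discount rate override (default: from `p`).
#' @return Named vector of the five components plus `total`.
#' @export
costs <- function(t, p, a, rate_annual = p$discount_rate_annual) {
  n <- length(t$incident_exacerbations)
  df <- discount_factor(seq_len(n), rate_annual, t$cycles_per_year)
  occ <- t$occupancy[-1, , drop = FALSE]

  ctrl_occ <- occ[, 1:3, drop = FALSE]
  maintenance <- sum(rowSums(ctrl_occ) * df) * a * p$costs$maintenance_weekly
  visit_rate <- 1 / p$outpatient_interval_weeks
  outpatient <- sum((ctrl_occ %*% visit_rate) * df) * p$costs$outpatient_visit
  rescue_w <- p$costs$rescue_weekly[c(CTRL, "Exacerbation")]
  rescue <- sum((occ[, 1:4, drop = FALSE] %*% rescue_w) * df)
  inc_disc <- sum(t$incident_exacerbations * df)
  ex_nonadm <- inc_disc * (1 - p$admitted_fraction) * p$costs$exacerbation_nonadmitted
  ex_adm <- inc_disc * p$admitted_fraction * p$costs$exacerbation_admitted

  out <- c(maintenance = maintenance, outpatient = outpatient, rescue = rescue,
           exacerbation_nonadmitted = ex_nonadm, exacerbation_admitted = ex_adm)
  c(out, total = sum(out))
}

#' Summarize a cohort run
#'
#' @param t A `cohort_trace`.
#' @param p The `asthma_parameters` used to generate it.
#' @param a Adherence rate.
#' @return An `outcome_summary`: list with `adherence`,
#'   `total_exacerbations`, `life_years` (undiscounted), `qalys_discounted`,
#'   and `costs_discounted` (named vector with components and `total`).
#' @export
summarize_outcomes <- function(t, p, a) {
  structure(list(
    adherence = a,
    total_exacerbations = count_exacerbations(t),
    life_years = life_years(t),
    qalys_discounted = qalys(t, p),
    costs_discounted = costs(t, p, a)
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> adherence %.0f%%\n", 100 * x$adherence))
  cat(sprintf("  exacerbations (20y expected): %.3f\n", x$total_exacerbations))
  cat(sprintf("  life years (undiscounted):    %.3f\n", x$life_years))
  cat(sprintf("  QALYs (discounted):           %.3f\n", x$qalys_discounted))
  cat(sprintf("  costs (discounted, GBP 2022): %.0f\n", x$costs_discounted[["total"]]))
  invisible(x)
}

# one row per summary, for tabular export
summary_row <- function(s) {
  cd <- s$costs_discounted
  data.frame(adherence = s$adherence,
             exacerbations = s$total_exacerbations,
             life_years = s$life_years,
             qalys = s$qalys_discounted,
             cost_total = cd[["total"]],
             cost_maintenance = cd[["maintenance"]],
             cost_outpatient = cd[["outpatient"]],
             cost_rescue = cd[["rescue"]],
             cost_exac_nonadmitted = cd[["exacerbation_nonadmitted"]],
             cost_exac_admitted = cd[["exacerbation_admitted"]])
}

#' Export a cohort trace as delimited text
#'
#' One row per cycle: state occupancies, incident exacerbation flow, and
#' the discount factor (audit column).
#'
#' @param t A `cohort_trace`.
#' @param p The `asthma_parameters` used to generate it.
#' @param path Output path (tab-separated, UTF-8, LF).
#' @return `path`, invisibly.
#' @export
write_trace <- function(t, p, path) {
  n <- length(t$incident_exacerbations)
  df <- data.frame(cycle = 0:n,
                   age = c(t$ages[1] - 1 / t$cycles_per_year, t$ages),
                   t$occupancy,
                   incident_exacerbations = c(NA, t$incident_exacerbations),
                   discount_factor = discount_factor(0:n, p$discount_rate_annual,
                                                     t$cycles_per_year))
  write_tsv_with_header(df, path, list(type = "cohort_trace"))
  invisible(path)
}
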