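PARAM_SCHEMA <- "asthmod-parameters/1"

# three control states, in model order
CTRL <- c("Controlled", "PartiallyControlled", "Uncontrolled")

#' Construct a model parameter set
#'
#' Bundles every numeric input of the cohort model. Most users will start
#' from [default_parameters()] and modify fields, or transcribe a published
#' parameter list into the JSON schema read by [load_parameters()].
#'
#' @param initial_distribution Named probability vector over the three
#'   control states (sums to 1).
#' @param full_adherence_transitions 3x4 matrix of weekly transition
#'   probabilities at full adherence; rows `Controlled`,
#'   `PartiallyControlled`, `Uncontrolled`; columns the same three states
#'   plus `Exacerbation`. Diagonal entries are 0: the residual row mass is
#'   the probability of staying put.
#' @param exacerbation_recovery Named probability vector over the control
#'   states: destination on leaving the one-cycle exacerbation state
#'   (sums to 1).
#' @param zero_adherence_odds_ratios Named vector, one odds ratio per origin
#'   control state, applied to the full-adherence exacerbation-entry
#'   probability to obtain the no-treatment probability.
#' @param exacerbation_case_fatality Weekly probability of asthma death while
#'   in the exacerbation state.
#' @param admitted_fraction Fraction of exacerbations admitted to hospital.
#' @param utilities Named list: per-state utilities `Controlled`,
#'   `PartiallyControlled`, `Uncontrolled`, plus `ExacerbationAdmitted` and
#'   `ExacerbationNonAdmitted`.
#' @param utility_adjustment Data frame `age_from`, `male`, `female`:
#'   multiplicative utility decrements by age band and sex.
#' @param costs Named list: `maintenance_weekly`, `outpatient_visit`,
#'   `rescue_weekly` (named vector incl. `Exacerbation`),
#'   `exacerbation_nonadmitted`, `exacerbation_admitted`. 2022 GBP.
#' @param outpatient_interval_weeks Named vector of weeks between routine
#'   outpatient visits per control state.
#' @param discount_rate_annual Annual discount rate (fraction).
#' @param horizon_years Model horizon in years.
#' @param cycles_per_year Cycles per year (weekly model: 52).
#' @param cohort_start_age Cohort age at cycle 0, years.
#' @param sex_mix Fraction female.
#' @param distributions Named list of [dist_spec()] tags keyed by parameter
#'   path (e.g. `"utilities.Controlled"`, `"initial_distribution"`).
#' @return An object of class `asthma_parameters`.
#' @seealso [default_parameters()], [validate_parameters()],
#'   [load_parameters()], [write_parameters()]
#' @export
asthma_parameters <- function(initial_distribution,
                              full_adherence_transitions,
                              exacerbation_recovery,
                              zero_adherence_odds_ratios,
                              exacerbation_case_fatality,
                              admitted_fraction,
                              utilities,
                              costs,
                              outpatient_interval_weeks,
                              utility_adjustment = flat_utility_adjustment(),
                              discount_rate_annual = 0.035,
                              horizon_years = 20,
                              cycles_per_year = 52,
                              cohort_start_age = 40,
                              sex_mix = 0.5,
                              distributions = list()) {
  p <- structure(list(
    schema = PARAM_SCHEMA,
    initial_distribution = initial_distribution,
    full_adherence_transitions = full_adherence_transitions,
    exacerbation_recovery = exacerbation_recovery,
    zero_adherence_odds_ratios = zero_adherence_odds_ratios,
    exacerbation_case_fatality = exacerbation_case_fatality,
    admitted_fraction = admitted_fraction,
    utilities = utilities,
    utility_adjustment = utility_adjustment,
    costs = costs,
    outpatient_interval_weeks = outpatient_interval_weeks,
    discount_rate_annual = discount_rate_annual,
    horizon_years = horizon_years,
    cycles_per_year = cycles_per_year,
    cohort_start_age = cohort_start_age,
    sex_mix = sex_mix,
    distributions = distributions
  ), class = "asthma_parameters")
  viol <- validate_parameters(p)
  if (length(viol))
    stop("invalid parameter set:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  p
}

#' No-op utility adjustment table
#'
#' @return A single-band table with multiplier 1 for both sexes.
#' @export
flat_utility_adjustment <- function() {
  data.frame(age_from = 0, male = 1, female = 1)
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameterization and reports *all*
#' violations rather than stopping at the first. Never raises.
#'
#' @param p An `asthma_parameters` object (or plain list with its fields).
#' @return Character vector of violation descriptions; empty when valid.
#' @examples
#' validate_parameters(default_parameters())  # character(0)
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  add <- function(field, value, rule)
    v <<- c(v, sprintf("%s = %s: %s", field, paste(signif(unlist(value), 6), collapse = ","), rule))

  prob01 <- function(x, field) {
    bad <- !is.finite(x) | x < 0 | x > 1
    if (any(bad)) add(field, x[bad], "probability outside [0,1]")
  }

  id <- p$initial_distribution
  if (length(id) != 3) add("initial_distribution", id, "must have 3 components (control states)")
  prob01(id, "initial_distribution")
  if (length(id) == 3 && abs(sum(id) - 1) > 1e-9)
    add("initial_distribution", sum(id), "must sum to 1 within 1e-9")

  tr <- p$full_adherence_transitions
  if (!is.matrix(tr) || !all(dim(tr) == c(3, 4))) {
    add("full_adherence_transitions", dim(tr), "must be a 3x4 matrix (origins x destinations)")
  } else {
    prob01(as.vector(tr), "full_adherence_transitions")
    for (i in 1:3) {
      if (is.finite(tr[i, i]) && tr[i, i] != 0)
        add(sprintf("full_adherence_transitions[%s,%s]", CTRL[i], CTRL[i]), tr[i, i],
            "diagonal must be 0 (stay probability is the residual)")
      rs <- sum(tr[i, ])
      if (is.finite(rs) && rs > 1 + 1e-12)
        add(sprintf("full_adherence_transitions[%s,]", CTRL[i]), rs,
            "row sum must be <= 1 (residual mass = stay)")
    }
  }

  er <- p$exacerbation_recovery
  if (length(er) != 3) add("exacerbation_recovery", er, "must have 3 components")
  prob01(er, "exacerbation_recovery")
  if (length(er) == 3 && abs(sum(er) - 1) > 1e-9)
    add("exacerbation_recovery", sum(er), "must sum to 1 within 1e-9")

  ors <- p$zero_adherence_odds_ratios
  if (length(ors) != 3) add("zero_adherence_odds_ratios", ors, "must have 3 components")
  if (any(!is.finite(ors) | ors <= 0))
    add("zero_adherence_odds_ratios", ors, "odds ratios must be > 0")

  prob01(p$exacerbation_case_fatality, "exacerbation_case_fatality")
  prob01(p$admitted_fraction, "admitted_fraction")

  un <- c("Controlled", "PartiallyControlled", "Uncontrolled",
          "ExacerbationAdmitted", "ExacerbationNonAdmitted")
  for (nm in un) {
    u <- p$utilities[[nm]]
    if (is.null(u)) add(paste0("utilities.", nm), NA, "missing utility")
    else if (!is.finite(u) || u < -1 || u > 1)
      add(paste0("utilities.", nm), u, "utility outside [-1,1]")
  }

  ua <- p$utility_adjustment
  if (!is.data.frame(ua) || !all(c("age_from", "male", "female") %in% names(ua))) {
    add("utility_adjustment", NA, "needs columns age_from, male, female")
  } else {
    if (is.unsorted(ua$age_from, strictly = TRUE))
      add("utility_adjustment.age_from", ua$age_from, "age bands must be strictly increasing")
    if (any(ua$male < 0 | ua$male > 1) || any(ua$female < 0 | ua$female > 1))
      add("utility_adjustment", NA, "multipliers must lie in [0,1]")
  }

  cn <- c("maintenance_weekly", "outpatient_visit", "exacerbation_nonadmitted",
          "exacerbation_admitted")
  for (nm in cn) {
    x <- p$costs[[nm]]
    if (is.null(x)) add(paste0("costs.", nm), NA, "missing cost")
    else if (!is.finite(x) || x < 0) add(paste0("costs.", nm), x, "cost must be >= 0")
  }
  rw <- p$costs$rescue_weekly
  if (length(rw) < 3 || any(!is.finite(rw) | rw < 0))
    add("costs.rescue_weekly", rw, "weekly rescue costs must be >= 0 for every state")

  oi <- p$outpatient_interval_weeks
  if (length(oi) != 3 || any(!is.finite(oi) | oi <= 0))
    add("outpatient_interval_weeks", oi, "must be 3 positive interval lengths")

  if (!is.finite(p$discount_rate_annual) || p$discount_rate_annual < 0)
    add("discount_rate_annual", p$discount_rate_annual, "must be >= 0")
  if (!is.finite(p$horizon_years) || p$horizon_years <= 0)
    add("horizon_years", p$horizon_years, "must be > 0")
  if (!is.finite(p$cycles_per_year) || p$cycles_per_year < 1)
    add("cycles_per_year", p$cycles_per_year, "must be >= 1")
  if (!is.finite(p$cohort_start_age) || p$cohort_start_age < 0)
    add("cohort_start_age", p$cohort_start_age, "must be >= 0")
  prob01(p$sex_mix, "sex_mix")

  for (nm in names(p$distributions)) {
    derr <- validate_dist_spec(p$distributions[[nm]])
    if (length(derr))
      add(paste0("distributions.", nm), NA, paste(derr, collapse = "; "))
  }

  v
}

#' Default parameter fixture
#'
#' The parameterization shipped with the package. Values printed in the
#' source publication record are used verbatim: the initial control-state
#' distribution (20.5% / 39.4% / 40.1%), the 39%/61% admitted/non-admitted
#' exacerbation split, the 3.5% annual discount rate, the 20-year horizon
#' and the weekly cycle. Every other number — transition probabilities,
#' odds ratios, utilities, unit costs, case fatality, distribution
#' hyperparameters — is a documented plausible stand-in for the deposited
#' supplementary parameter list, replaceable via [load_parameters()]. The
#' methods vignette records the provenance and rationale of each stand-in.
#'
#' @return A valid `asthma_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$initial_distribution
#' @export
default_parameters <- function() {
  tr <- matrix(0, 3, 4, dimnames = list(CTRL, c(CTRL, "Exacerbation")))
  # weekly full-adherence transitions (stand-ins; residual = stay):
  tr["Controlled", ] <- c(0, 0.150, 0.020, 0.002)
  tr["PartiallyControlled", ] <- c(0.100, 0, 0.070, 0.006)
  tr["Uncontrolled", ] <- c(0.020, 0.100, 0, 0.015)

  utilities <- list(
    Controlled = 0.89, PartiallyControlled = 0.83, Uncontrolled = 0.74,
    ExacerbationAdmitted = 0.33, ExacerbationNonAdmitted = 0.57
  )
  costs <- list(
    maintenance_weekly = 8.00,          # step-weighted maintenance therapy / week
    outpatient_visit = 163.00,          # respiratory outpatient attendance
    rescue_weekly = c(Controlled = 0.30, PartiallyControlled = 0.75,
                      Uncontrolled = 1.50, Exacerbation = 0),
    exacerbation_nonadmitted = 150.00,  # primary/urgent care episode
    exacerbation_admitted = 2987.00     # admission incl. hospitalization + ambulance
  )
  id <- c(Controlled = 0.205, PartiallyControlled = 0.394, Uncontrolled = 0.401)
  er <- c(Controlled = 0.20, PartiallyControlled = 0.40, Uncontrolled = 0.40)
  ors <- c(Controlled = 3, PartiallyControlled = 3, Uncontrolled = 3)

  # age/sex multiplicative utility decrements (population-norm style stand-in)
  ua <- data.frame(
    age_from = c(16, 25, 35, 45, 55, 65, 75),
    male = c(1.00, 0.99, 0.98, 0.96, 0.93, 0.90, 0.85),
    female = c(0.99, 0.98, 0.97, 0.95, 0.92, 0.88, 0.83)
  )

  dists <- list(
    initial_distribution = dist_spec("dirichlet", setNames(400 * id, names(id)), mean = id),
    exacerbation_recovery = dist_spec("dirichlet", setNames(200 * er, names(er)), mean = er),
    exacerbation_case_fatality = dist_spec("beta", c(20, 1980), mean = 0.01),
    admitted_fraction = dist_spec("beta", c(39, 61), mean = 0.39),
    "utilities.Controlled" = beta_from_mean_se(0.89, 0.03),
    "utilities.PartiallyControlled" = beta_from_mean_se(0.83, 0.03),
    "utilities.Uncontrolled" = beta_from_mean_se(0.74, 0.03),
    "utilities.ExacerbationAdmitted" = beta_from_mean_se(0.33, 0.05),
    "utilities.ExacerbationNonAdmitted" = beta_from_mean_se(0.57, 0.05),
    "costs.maintenance_weekly" = gamma_from_mean_se(8.00, 1.6),
    "costs.outpatient_visit" = gamma_from_mean_se(163, 32.6),
    "costs.exacerbation_nonadmitted" = gamma_from_mean_se(150, 30),
    "costs.exacerbation_admitted" = gamma_from_mean_se(2987, 597.4),
    "zero_adherence_odds_ratios.Controlled" = lognormal_from_mean_se(3, 0.6),
    "zero_adherence_odds_ratios.PartiallyControlled" = lognormal_from_mean_se(3, 0.6),
    "zero_adherence_odds_ratios.Uncontrolled" = lognormal_from_mean_se(3, 0.6)
  )
  # per-origin dirichlet over (destinations..., stay) for the transition rows
  for (i in seq_along(CTRL)) {
    row <- tr[i, ]
    conc <- c(row[-i], stay = 1 - sum(row)) * 600
    conc <- conc[conc > 0]
    dists[[paste0("full_adherence_transitions.", CTRL[i])]] <-
      dist_spec("dirichlet", conc, mean = c(row[-i], stay = 1 - sum(row))[names(conc)])
  }

  asthma_parameters(
    initial_distribution = id,
    full_adherence_transitions = tr,
    exacerbation_recovery = er,
    zero_adherence_odds_ratios = ors,
    exacerbation_case_fatality = 0.01,
    admitted_fraction = 0.39,
    utilities = utilities,
    utility_adjustment = ua,
    costs = costs,
    outpatient_interval_weeks = c(Controlled = 26, PartiallyControlled = 13,
                                  Uncontrolled = 13 / 3),
    discount_rate_annual = 0.035,
    horizon_years = 20,
    cycles_per_year = 52,
    cohort_start_age = 40,
    sex_mix = 0.5,
    distributions = dists
  )
}

#' Draw a random but valid parameter set
#'
#' Generates a parameterization from documented plausible ranges for
#' property-style testing (row-stochasticity, mass conservation,
#' monotonicity). Identical seeds give identical output. Odds ratios are
#' drawn above 1, matching the modelled direction (no treatment raises
#' exacerbation risk).
#'
#' @param seed Integer seed.
#' @return A valid `asthma_parameters` object (all distribution tags fixed).
#' @export
random_plausible_parameters <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  rdirich <- function(conc) { g <- rgamma(length(conc), conc, 1); g / sum(g) }

  id <- setNames(rdirich(c(2, 4, 4)), CTRL)
  tr <- matrix(0, 3, 4, dimnames = list(CTRL, c(CTRL, "Exacerbation")))
  for (i in 1:3) {
    move_total <- runif(1, 0.05, 0.35)
    split <- rdirich(c(1, 1))
    tr[i, setdiff(1:3, i)] <- move_total * split
    tr[i, 4] <- runif(1, 5e-4, 0.02)
  }
  er <- setNames(rdirich(c(2, 4, 4)), CTRL)
  ors <- setNames(exp(runif(3, log(1.2), log(5))), CTRL)

  u3 <- sort(runif(3, 0.55, 0.95), decreasing = TRUE)
  utilities <- list(
    Controlled = u3[1], PartiallyControlled = u3[2], Uncontrolled = u3[3],
    ExacerbationAdmitted = runif(1, 0.1, 0.5),
    ExacerbationNonAdmitted = runif(1, 0.4, 0.7)
  )
  costs <- list(
    maintenance_weekly = runif(1, 2, 20),
    outpatient_visit = runif(1, 80, 300),
    rescue_weekly = c(Controlled = runif(1, 0, 1), PartiallyControlled = runif(1, 0.2, 2),
                      Uncontrolled = runif(1, 0.5, 4), Exacerbation = 0),
    exacerbation_nonadmitted = runif(1, 50, 400),
    exacerbation_admitted = runif(1, 1000, 5000)
  )

  asthma_parameters(
    initial_distribution = id,
    full_adherence_transitions = tr,
    exacerbation_recovery = er,
    zero_adherence_odds_ratios = ors,
    exacerbation_case_fatality = runif(1, 0.001, 0.02),
    admitted_fraction = runif(1, 0.2, 0.6),
    utilities = utilities,
    costs = costs,
    outpatient_interval_weeks = c(Controlled = 26, PartiallyControlled = 13,
                                  Uncontrolled = 13 / 3),
    discount_rate_annual = runif(1, 0, 0.06),
    horizon_years = 20,
    cycles_per_year = 52,
    cohort_start_age = sample(30:60, 1),
    sex_mix = runif(1)
  )
}

# ---- parameter paths ---------------------------------------------------

# get/set a value addressed by a dotted path; matrix rows addressed by rowname
param_get <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- p
  for (k in parts) {
    if (is.matrix(x)) x <- x[k, ]
    else x <- x[[k]]
    if (is.null(x)) stop("unknown parameter path: ", path, call. = FALSE)
  }
  x
}

param_set <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts, value) {
    k <- parts[1]
    if (length(parts) == 1) {
      if (is.matrix(x)) x[k, names(value)] <- value
      else if (is.list(x)) x[[k]] <- value
      else x[k] <- value
      return(x)
    }
    if (is.matrix(x)) {
      x[k, names(value)] <- value  # matrix rows are terminal
      return(x)
    }
    x[[k]] <- rec(x[[k]], parts[-1], value)
    x
  }
  out <- rec(unclass(p), parts, value)
  class(out) <- class(p)
  out
}

# ---- i/o ---------------------------------------------------------------

#' Read a parameter file
#'
#' Reads the versioned JSON parameter schema written by
#' [write_parameters()]. Omitted optional fields take their documented
#' defaults (discount rate 0.035/yr, horizon 20 years, 52 cycles/year,
#' start age 40, sex mix 0.5, flat utility adjustment, no distribution
#' tags). Required fields that are absent raise a schema error naming the
#' field; invariant violations raise a validation error listing every
#' violation.
#'
#' @param path Path to a parameter JSON file.
#' @return A validated `asthma_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema) || !identical(raw$schema, PARAM_SCHEMA))
    stop("unrecognized parameter schema (expected '", PARAM_SCHEMA, "')", call. = FALSE)

  required <- c("initial_distribution", "full_adherence_transitions",
                "exacerbation_recovery", "zero_adherence_odds_ratios",
                "exacerbation_case_fatality", "admitted_fraction",
                "utilities", "costs", "outpatient_interval_weeks")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("parameter file missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  # JSON integers parse as R integers; the model works in doubles throughout
  num <- function(x) { x <- unlist(x); storage.mode(x) <- "double"; x }

  tr <- raw$full_adherence_transitions
  trm <- matrix(0, 3, 4, dimnames = list(CTRL, c(CTRL, "Exacerbation")))
  for (org in CTRL) trm[org, ] <- num(tr[[org]])[colnames(trm)]

  dists <- list()
  for (nm in names(raw$distributions)) {
    d <- raw$distributions[[nm]]
    dists[[nm]] <- structure(list(family = d$family, params = num(d$params),
                                  mean = num(d$mean)), class = "dist_spec")
  }

  ua <- if (!is.null(raw$utility_adjustment)) {
    ua <- as.data.frame(raw$utility_adjustment)
    ua[] <- lapply(ua, function(col) { storage.mode(col) <- "double"; col })
    ua
  } else flat_utility_adjustment()

  costs <- lapply(raw$costs, num)

  asthma_parameters(
    initial_distribution = num(raw$initial_distribution)[CTRL],
    full_adherence_transitions = trm,
    exacerbation_recovery = num(raw$exacerbation_recovery)[CTRL],
    zero_adherence_odds_ratios = num(raw$zero_adherence_odds_ratios)[CTRL],
    exacerbation_case_fatality = num(raw$exacerbation_case_fatality),
    admitted_fraction = num(raw$admitted_fraction),
    utilities = lapply(raw$utilities, num),
    utility_adjustment = ua,
    costs = costs,
    outpatient_interval_weeks = num(raw$outpatient_interval_weeks)[CTRL],
    discount_rate_annual = num(raw$discount_rate_annual %||% 0.035),
    horizon_years = num(raw$horizon_years %||% 20),
    cycles_per_year = num(raw$cycles_per_year %||% 52),
    cohort_start_age = num(raw$cohort_start_age %||% 40),
    sex_mix = num(raw$sex_mix %||% 0.5),
    distributions = dists
  )
}

#' Write a parameter file
#'
#' Serializes an `asthma_parameters` object to the versioned JSON schema at
#' full double precision (UTF-8, LF line endings); [load_parameters()]
#' round-trips every field bit-exactly.
#'
#' @param p An `asthma_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  tr <- p$full_adherence_transitions
  trl <- lapply(setNames(rownames(tr), rownames(tr)),
                function(org) as.list(tr[org, ]))
  out <- list(
    schema = PARAM_SCHEMA,
    initial_distribution = as.list(p$initial_distribution),
    full_adherence_transitions = trl,
    exacerbation_recovery = as.list(p$exacerbation_recovery),
    zero_adherence_odds_ratios = as.list(p$zero_adherence_odds_ratios),
    exacerbation_case_fatality = p$exacerbation_case_fatality,
    admitted_fraction = p$admitted_fraction,
    utilities = p$utilities,
    utility_adjustment = p$utility_adjustment,
    costs = list(
      maintenance_weekly = p$costs$maintenance_weekly,
      outpatient_visit = p$costs$outpatient_visit,
      rescue_weekly = as.list(p$costs$rescue_weekly),
      exacerbation_nonadmitted = p$costs$exacerbation_nonadmitted,
      exacerbation_admitted = p$costs$exacerbation_admitted
    ),
    outpatient_interval_weeks = as.list(p$outpatient_interval_weeks),
    discount_rate_annual = p$discount_rate_annual,
    horizon_years = p$horizon_years,
    cycles_per_year = p$cycles_per_year,
    cohort_start_age = p$cohort_start_age,
    sex_mix = p$sex_mix,
    distributions = lapply(p$distributions, function(d)
      list(family = d$family, params = as.list(d$params), mean = as.list(d$mean)))
  )
  # I(17) significant digits: exact binary64 round-trip through text
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                           dataframe = "columns")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.asthma_parameters <- function(x, ...) {
  cat("<asthma_parameters> (", PARAM_SCHEMA, ")\n", sep = "")
  cat("  initial distribution (C/P/U): ",
      paste(signif(x$initial_distribution, 4), collapse = " / "), "\n", sep = "")
  cat("  horizon: ", x$horizon_years, " years x ", x$cycles_per_year,
      " cycles/yr; discount ", 100 * x$discount_rate_annual, "%/yr\n", sep = "")
  cat("  start age ", x$cohort_start_age, "; ", 100 * x$sex_mix, "% female; ",
      length(x$distributions), " PSA-tagged parameters\n", sep = "")
  invisible(x)
}
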