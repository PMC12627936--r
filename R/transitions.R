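#' No-treatment (zero adherence) transition probabilities
#'
#' Applies the per-origin odds ratios to the full-adherence
#' exacerbation-entry probabilities; all other transitions carry over
#' unchanged and the residual "stay" mass absorbs the change. With every
#' odds ratio equal to 1 the output is identical to the full-adherence
#' matrix.
#'
#' @param p An `asthma_parameters` object.
#' @return A 3x4 matrix in the layout of `p$full_adherence_transitions`.
#' @export
zero_adherence_transitions <- function(p) {
  tr <- p$full_adherence_transitions
  ors <- p$zero_adherence_odds_ratios
  for (org in rownames(tr)) {
    tr[org, "Exacerbation"] <- or_adjust(tr[org, "Exacerbation"], ors[[org]])
    if (sum(tr[org, ]) > 1 + 1e-12)
      stop("zero-adherence row for origin '", org,
           "' exceeds total probability 1 after odds-ratio adjustment", call. = FALSE)
  }
  tr
}

# expand a 3x4 stored row (diagonal 0, stay implicit) to a 5-state alive row
expand_row <- function(row3x4, origin_idx) {
  out <- numeric(5)
  out[1:4] <- row3x4
  out[origin_idx] <- 1 - sum(row3x4)  # stay
  out
}

#' Weekly transition matrix at a given adherence and age
#'
#' Builds the 5x5 row-stochastic weekly matrix used by the cohort engine.
#' For each alive control-state row the full-adherence and zero-adherence
#' (odds-ratio adjusted) rows are blended as the convex combination
#' `E(a) * row_full + (1 - E(a)) * row_zero`, then composed with background
#' weekly mortality for the cohort's current age: death is resolved first
#' and the remaining transitions are scaled by the survival complement.
#' The exacerbation row combines background mortality with the weekly
#' asthma case fatality, and distributes survivors over the recovery
#' vector; asthma-specific death is reachable only from the exacerbation
#' state. `Dead` is absorbing.
#'
#' @param p An `asthma_parameters` object.
#' @param a Adherence rate in \[0, 1\].
#' @param age Cohort age (years) at this cycle.
#' @param lt A `life_table` for background mortality.
#' @return A 5x5 `transition_matrix` with attributes `adherence` and `age`.
#' @export
build_matrix <- function(p, a, age, lt) {
  E <- effectiveness(a)
  tr_full <- p$full_adherence_transitions
  tr_zero <- zero_adherence_transitions(p)
  qw <- weekly_mortality(lt, age, p$cycles_per_year)

  M <- matrix(0, 5, 5, dimnames = list(CONTROL_STATES, CONTROL_STATES))
  for (i in 1:3) {
    row <- E * expand_row(tr_full[i, ], i) + (1 - E) * expand_row(tr_zero[i, ], i)
    M[i, ] <- c(row[1:4] * (1 - qw), qw)
  }
  # exacerbation: one-cycle state; case fatality + background death first
  d <- 1 - (1 - qw) * (1 - p$exacerbation_case_fatality)
  M[4, 1:3] <- p$exacerbation_recovery * (1 - d)
  M[4, 5] <- d
  M[5, 5] <- 1

  if (any(M < -1e-15 | M > 1 + 1e-15) || any(abs(rowSums(M) - 1) > 1e-12))
    stop("internal consistency error: transition matrix not row-stochastic", call. = FALSE)

  structure(M, adherence = a, age = age, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> adherence = ", attr(x, "adherence"),
      ", age = ", attr(x, "age"), "\n", sep = "")
  print(round(unclass(x), 5))
  invisible(x)
}
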