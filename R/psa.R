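#' Draw one parameter set from its distribution tags
#'
#' Every tagged value is replaced by a draw from its [dist_spec()];
#' untagged values carry their deterministic means. Dirichlet-tagged
#' vectors are drawn jointly (normalized by construction); a dirichlet tag
#' on a transition row may include a trailing `"stay"` component, which is
#' dropped after the draw (the row's residual mass is the stay
#' probability). If a draw violates the parameter invariants it is
#' redrawn, up to 100 times.
#'
#' Uses the current R RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param p An `asthma_parameters` object.
#' @param max_redraws Redraw cap on invariant-violating draws.
#' @return A valid `asthma_parameters` object with the same tags.
#' @export
sample_parameters <- function(p, max_redraws = 100) {
  if (!length(p$distributions)) return(p)
  for (attempt in seq_len(max_redraws + 1)) {
    q <- p
    bad <- NULL
    for (path in names(p$distributions)) {
      d <- p$distributions[[path]]
      draw <- sample_dist(d)
      if (d$family == "dirichlet" && "stay" %in% names(draw))
        draw <- draw[setdiff(names(draw), "stay")]
      q <- param_set(q, path, draw)
    }
    viol <- validate_parameters(q)
    if (!length(viol)) return(q)
    bad <- viol
  }
  stop("sample_parameters: redraw cap (", max_redraws, ") exceeded; last violations: ",
       paste(bad, collapse = "; "), call. = FALSE)
}

# prefix-stable per-iteration substream seeds from a master seed
iteration_seeds <- function(seed, n_iter) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  floor(runif(n_iter) * 2147483646) + 1
}

#' Probabilistic sensitivity analysis across an adherence grid
#'
#' For each Monte-Carlo iteration, one parameter draw is taken from the
#' distribution tags and shared across all adherence levels (common random
#' numbers), then the deterministic cohort engine is run at every level.
#' Iteration substreams are derived from the master seed, so increasing
#' `n_iter` extends — rather than reshuffles — the sequence of draws.
#'
#' @param p An `asthma_parameters` object (its tags define the sampled
#'   uncertainty; untagged values stay fixed).
#' @param levels Adherence grid, each value in \[0, 1\]. Default: the ten
#'   levels 0.1, 0.2, ..., 1.0.
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param seed Master seed (required; no silent default).
#' @param lt A `life_table`.
#' @return A `psa_result`: list with `draws` (data frame: iteration, level,
#'   outcomes, cost components), `summary` (see [summarize_psa()]),
#'   `levels`, `n_iterations`, `seed`.
#' @export
run_psa <- function(p, levels = seq(0.1, 1, by = 0.1), n_iter = 1000, seed, lt = default_life_table()) {
  if (missing(seed) || is.null(seed)) stop("run_psa requires an explicit seed", call. = FALSE)
  stopifnot(n_iter >= 1, length(levels) >= 1, all(levels >= 0 & levels <= 1))
  seeds <- iteration_seeds(seed, n_iter)

  rows <- vector("list", n_iter * length(levels))
  k <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(seeds[i])
    pi_ <- tryCatch(sample_parameters(p),
                    error = function(e) stop("PSA iteration ", i, ": ", conditionMessage(e),
                                             call. = FALSE))
    for (j in seq_along(levels)) {
      a <- levels[j]
      s <- tryCatch(summarize_outcomes(run_cohort(pi_, a, lt), pi_, a),
                    error = function(e) stop("PSA iteration ", i, ", level ", a, ": ",
                                             conditionMessage(e), call. = FALSE))
      k <- k + 1L
      rows[[k]] <- cbind(iteration = i, summary_row(s))
    }
  }
  draws <- do.call(rbind, rows)
  res <- structure(list(draws = draws, levels = levels, n_iterations = n_iter,
                        seed = seed), class = "psa_result")
  res$summary <- summarize_psa(res)
  res
}

PSA_OUTCOMES <- c("exacerbations", "life_years", "qalys", "cost_total")

#' Per-level means and percentile 95% intervals
#'
#' Empirical means with 2.5th/97.5th percentile bounds of the Monte-Carlo
#' draws, per adherence level, for the four headline outcomes.
#'
#' @param r A `psa_result`.
#' @return Data frame: `adherence`, `outcome`, `mean`, `lower`, `upper`.
#' @export
summarize_psa <- function(r) {
  out <- expand.grid(adherence = r$levels, outcome = PSA_OUTCOMES,
                     stringsAsFactors = FALSE)
  out$mean <- out$lower <- out$upper <- NA_real_
  for (row in seq_len(nrow(out))) {
    x <- r$draws[r$draws$adherence == out$adherence[row], out$outcome[row]]
    q <- unname(quantile(x, c(0.025, 0.975), type = 7))
    out$mean[row] <- mean(x)
    out$lower[row] <- q[1]
    out$upper[row] <- q[2]
  }
  out[order(match(out$outcome, PSA_OUTCOMES), out$adherence),
      c("adherence", "outcome", "mean", "lower", "upper")]
}

#' Paired comparison of two adherence levels
#'
#' Computes per-iteration differences (`a_to` minus `a_from`) for the four
#' headline outcomes using the shared parameter draws (common random
#' numbers), and summarizes them as means with percentile 95% intervals.
#' A negative `exacerbations` or `cost_total` delta favours the higher
#' adherence level; positive `life_years` and `qalys` deltas do likewise.
#'
#' @param r A `psa_result`.
#' @param a_from,a_to Two levels present in `r$levels`.
#' @return Data frame: `outcome`, `mean`, `lower`, `upper` of the paired
#'   deltas.
#' @export
compare_levels <- function(r, a_from, a_to) {
  for (a in c(a_from, a_to))
    if (!any(abs(r$levels - a) < 1e-12))
      stop("adherence level ", a, " is not on the PSA grid", call. = FALSE)
  d_from <- r$draws[abs(r$draws$adherence - a_from) < 1e-12, ]
  d_to <- r$draws[abs(r$draws$adherence - a_to) < 1e-12, ]
  d_from <- d_from[order(d_from$iteration), ]
  d_to <- d_to[order(d_to$iteration), ]
  out <- data.frame(outcome = PSA_OUTCOMES, mean = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (row in seq_len(nrow(out))) {
    delta <- d_to[[out$outcome[row]]] - d_from[[out$outcome[row]]]
    q <- unname(quantile(delta, c(0.025, 0.975), type = 7))
    out$mean[row] <- mean(delta)
    out$lower[row] <- q[1]
    out$upper[row] <- q[2]
  }
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_iterations, " iterations x ", length(x$levels),
      " adherence levels (seed ", x$seed, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}
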