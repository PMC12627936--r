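#' Treatment effectiveness from medication adherence
#'
#' Piecewise mapping from an adherence rate (possession-ratio style,
#' fraction of prescribed maintenance medication taken) to treatment
#' effectiveness, the scalar that interpolates between no-treatment and
#' full-treatment transition behaviour:
#'
#' * `a <= 0.30`: effectiveness equals the adherence rate;
#' * `0.30 < a < 1`: `1 - exp(-5 * (a - 0.2287))`;
#' * `a = 1`: effectiveness is exactly 1.
#'
#' The two branches nearly meet at the 30% breakpoint
#' (`1 - exp(-5 * 0.0713) ≈ 0.2999`), but the mapping jumps at `a = 1`
#' (the exponential branch approaches ~0.9789); the boundary statements are
#' implemented literally.
#'
#' @param a Adherence rate(s) in \[0, 1\] (vectorized).
#' @return Effectiveness in \[0, 1\].
#' @examples
#' effectiveness(c(0, 0.15, 0.5, 1))
#' @export
effectiveness <- function(a) {
  if (any(!is.finite(a) | a < 0 | a > 1))
    stop("adherence must lie in [0,1]", call. = FALSE)
  e <- ifelse(a <= 0.30, a, 1 - exp(-5 * (a - 0.2287)))
  e[a == 1] <- 1
  e
}

#' Apply an odds ratio to a probability
#'
#' Converts `p` to odds, multiplies by `or_value`, and converts back:
#' `or_adjust(p, r) = r*p/(1-p) / (1 + r*p/(1-p))`. Used to derive
#' no-treatment transition probabilities from full-treatment ones.
#'
#' @param p Probability in \[0, 1); `p = 1` has undefined odds and errors.
#' @param or_value Odds ratio (> 0). Vectorized over both arguments.
#' @return Adjusted probability.
#' @examples
#' or_adjust(0.2, 2)   # 1/3
#' @export
or_adjust <- function(p, or_value) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probability must lie in [0,1]", call. = FALSE)
  if (any(p == 1))
    stop("p = 1 has undefined odds; cannot apply a finite odds ratio", call. = FALSE)
  if (any(!is.finite(or_value) | or_value <= 0))
    stop("odds ratio must be > 0", call. = FALSE)
  odds <- or_value * p / (1 - p)
  odds / (1 + odds)
}
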