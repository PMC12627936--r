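#' Distribution tag for probabilistic sensitivity analysis
#'
#' A `dist_spec` attaches a sampling distribution to a model parameter. The
#' deterministic model always uses `mean`; the PSA replaces the value by one
#' draw from `family`.
#'
#' Supported families and their `params`:
#' * `fixed` — no params; sampling returns `mean` exactly.
#' * `beta` — `c(shape1, shape2)`, both > 0; support \[0, 1\].
#' * `gamma` — `c(shape, scale)`, both > 0; support >= 0.
#' * `lognormal` — `c(meanlog, sdlog)`, `sdlog` > 0; support > 0.
#' * `dirichlet` — named concentration vector, all > 0, attached to a
#'   probability vector; component names must match the target vector
#'   (a trailing `"stay"` component is allowed for transition rows, see
#'   [sample_parameters()]).
#'
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet"`.
#' @param params Numeric parameter vector, family-specific (see above).
#' @param mean The deterministic point value (scalar, or vector for
#'   `dirichlet`).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", c(39, 61), mean = 0.39)
#' dist_spec("fixed", mean = 0.035)
#' @export
dist_spec <- function(family, params = numeric(0), mean) {
  family <- match.arg(family, c("fixed", "beta", "gamma", "lognormal", "dirichlet"))
  out <- structure(list(family = family, params = params, mean = mean),
                   class = "dist_spec")
  err <- validate_dist_spec(out)
  if (length(err)) stop("invalid dist_spec: ", paste(err, collapse = "; "), call. = FALSE)
  out
}

#' Validate a distribution tag
#'
#' @param d A `dist_spec`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_dist_spec <- function(d) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.list(d) || is.null(d$family)) return("not a dist_spec")
  p <- d$params
  m <- d$mean
  switch(d$family,
    fixed = {
      if (!length(m) || any(!is.finite(m))) add("fixed: mean must be finite")
    },
    beta = {
      if (length(p) != 2 || any(p <= 0)) add("beta: needs two shape parameters > 0")
      if (length(m) != 1 || m < 0 || m > 1) add("beta: mean outside [0,1]")
    },
    gamma = {
      if (length(p) != 2 || any(p <= 0)) add("gamma: needs shape > 0 and scale > 0")
      if (length(m) != 1 || m < 0) add("gamma: mean outside support [0,Inf)")
    },
    lognormal = {
      if (length(p) != 2 || !is.finite(p[1]) || p[2] <= 0)
        add("lognormal: needs finite meanlog and sdlog > 0")
      if (length(m) != 1 || m <= 0) add("lognormal: mean outside support (0,Inf)")
    },
    dirichlet = {
      if (!length(p) || any(p <= 0)) add("dirichlet: all concentrations must be > 0")
      if (is.null(names(p))) add("dirichlet: concentrations must be named")
      if (any(m < 0) || any(m > 1)) add("dirichlet: mean components outside [0,1]")
    },
    add(paste0("unknown family '", d$family, "'"))
  )
  v
}

# one draw from a dist_spec; dirichlet returns a named probability vector
sample_dist <- function(d) {
  switch(d$family,
    fixed = d$mean,
    beta = rbeta(1, d$params[1], d$params[2]),
    gamma = rgamma(1, shape = d$params[1], scale = d$params[2]),
    lognormal = rlnorm(1, meanlog = d$params[1], sdlog = d$params[2]),
    dirichlet = {
      g <- rgamma(length(d$params), shape = d$params, scale = 1)
      setNames(g / sum(g), names(d$params))
    },
    stop("unknown family '", d$family, "'")
  )
}

#' Moment-matching constructors for distribution tags
#'
#' Convenience builders mapping a mean and standard error onto the
#' conventional PSA families: beta for probabilities and utilities, gamma for
#' costs, lognormal for odds ratios.
#'
#' @param mean Target mean.
#' @param se Target standard error (> 0).
#' @return A [dist_spec()].
#' @examples
#' beta_from_mean_se(0.39, 0.05)
#' gamma_from_mean_se(163, 32.6)
#' @name moment_match
NULL

#' @rdname moment_match
#' @export
beta_from_mean_se <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se > 0, se^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", c(mean * nu, (1 - mean) * nu), mean = mean)
}

#' @rdname moment_match
#' @export
gamma_from_mean_se <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  shape <- (mean / se)^2
  dist_spec("gamma", c(shape, mean / shape), mean = mean)
}

#' @rdname moment_match
#' @export
lognormal_from_mean_se <- function(mean, se) {
  stopifnot(mean > 0, se > 0)
  sdlog <- sqrt(log(1 + (se / mean)^2))
  dist_spec("lognormal", c(log(mean) - sdlog^2 / 2, sdlog), mean = mean)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec ", x$family, "> mean = ", paste(signif(x$mean, 6), collapse = ", "),
      if (length(x$params)) paste0("; params = ", paste(signif(x$params, 6), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
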