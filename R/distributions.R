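# Closed-form parametric survival families used for extrapolating trial
# PFS/OS curves beyond follow-up.  Time unit is months throughout
# (1 month = 30.4375 days).
#
# Parameterization convention (shape a, scale b unless noted):
#   exponential  S(t) = exp(-rate * t)
#   weibull      S(t) = exp(-(t/b)^a)
#   gompertz     S(t) = exp(-(b/a) * (exp(a*t) - 1)), shape a > 0, rate b > 0
#   loglogistic  S(t) = 1 / (1 + (t/b)^a)            (median = b)
#   lognormal    S(t) = 1 - Phi((log t - meanlog)/sdlog)
# The Gompertz shape is constrained positive so that S(t) -> 0; under this
# convention every family is a proper survival distribution.

#' Supported parametric survival families
#'
#' Family order is also the tie-break order used by [select_best()].
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal")
}

param_names_for <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    loglogistic = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog")
  )
}

#' Construct a parametric survival distribution
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param params Numeric parameter vector in the family's canonical order:
#'   `rate`; `(shape, scale)`; `(shape, rate)`; `(shape, scale)`;
#'   `(meanlog, sdlog)`.  All parameters must be positive except the
#'   lognormal `meanlog`, which may be any real number.
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("loglogistic", c(shape = 2.63812, scale = 13.97048))
#' surv_prob(d, c(0, 13.97048))   # 1 and exactly 0.5
#' @export
surv_dist <- function(family, params) {
  family <- match.arg(family, surv_families())
  params <- as.numeric(params)
  nm <- param_names_for(family)
  if (length(params) != length(nm))
    stop_input(sprintf("family '%s' takes %d parameter(s) (%s), got %d",
                       family, length(nm), paste(nm, collapse = ", "), length(params)))
  if (any(!is.finite(params)))
    stop_input("survival parameters must be finite")
  positive <- if (family == "lognormal") c(FALSE, TRUE) else rep(TRUE, length(nm))
  if (any(params[positive] <= 0))
    stop_input(sprintf("family '%s': parameter(s) %s must be > 0",
                       family, paste(nm[positive], collapse = ", ")))
  names(params) <- nm
  structure(list(family = family, params = params), class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop_input("times must be finite and non-negative")
  t
}

#' Survival probability S(t)
#'
#' @param dist A [surv_dist()].
#' @param t Vector of non-negative times (months).
#' @return `S(t)`, vectorized over `t`.
#' @export
surv_prob <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  t <- check_times(t)
  p <- dist$params
  switch(dist$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-(t / p[["scale"]])^p[["shape"]]),
    gompertz    = exp(-(p[["rate"]] / p[["shape"]]) * expm1(p[["shape"]] * t)),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal   = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE)
  )
}

#' Event-time density f(t)
#'
#' @inheritParams surv_prob
#' @return `f(t) = -dS/dt`, vectorized over `t`.
#' @export
surv_density <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  t <- check_times(t)
  p <- dist$params
  switch(dist$family,
    exponential = stats::dexp(t, p[["rate"]]),
    weibull     = stats::dweibull(t, p[["shape"]], p[["scale"]]),
    gompertz    = p[["rate"]] * exp(p[["shape"]] * t) *
                    exp(-(p[["rate"]] / p[["shape"]]) * expm1(p[["shape"]] * t)),
    loglogistic = {
      a <- p[["shape"]]; b <- p[["scale"]]
      z <- (t / b)^a
      ifelse(t == 0 & a > 1, 0, (a / b) * (t / b)^(a - 1) / (1 + z)^2)
    },
    lognormal   = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]])
  )
}

#' Quantile of the event-time distribution
#'
#' Returns `t` such that `1 - S(t) = p` (closed form for every family).
#'
#' @inheritParams surv_prob
#' @param p Vector of probabilities in `[0, 1)`.
#' @export
surv_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop_input("quantile probabilities must lie in [0, 1)")
  pa <- dist$params
  switch(dist$family,
    exponential = -log1p(-p) / pa[["rate"]],
    weibull     = pa[["scale"]] * (-log1p(-p))^(1 / pa[["shape"]]),
    gompertz    = log1p(-(pa[["shape"]] / pa[["rate"]]) * log1p(-p)) / pa[["shape"]],
    loglogistic = pa[["scale"]] * (p / (1 - p))^(1 / pa[["shape"]]),
    lognormal   = stats::qlnorm(p, pa[["meanlog"]], pa[["sdlog"]])
  )
}

#' Median survival time
#'
#' @inheritParams surv_prob
#' @export
surv_median <- function(dist) surv_quantile(dist, 0.5)

#' Restricted mean survival time
#'
#' Computes the restricted mean survival time
#' \eqn{\int_0^{\tau} S(t)\,dt} by adaptive quadrature.
#'
#' @inheritParams surv_prob
#' @param horizon Upper limit \eqn{\tau} in months (> 0, or 0 for a
#'   degenerate zero-length horizon).
#' @return Restricted mean in months.
#' @export
restricted_mean <- function(dist, horizon) {
  stopifnot(inherits(dist, "surv_dist"))
  if (!is_scalar_number(horizon) || horizon < 0)
    stop_input("horizon must be a non-negative number")
  if (horizon == 0) return(0)
  out <- stats::integrate(function(t) surv_prob(dist, t), 0, horizon,
                          rel.tol = 1e-8, subdivisions = 1000L)
  if (out$message != "OK")
    stop(sprintf("quadrature failed: %s", out$message))
  out$value
}
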