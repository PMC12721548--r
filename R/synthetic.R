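# Generators for every input the pipeline needs without external data:
# censored IPD from any parametric family, digitized KM point sets with
# jitter, and the full base/min/max/distribution parameter table.

#' Simulate censored individual-patient data
#'
#' Event times are drawn by inverse-CDF sampling from the family's
#' closed-form quantile function; censoring is applied per the chosen
#' mechanism.
#'
#' @param dist A [surv_dist()].
#' @param n Number of records (>= 1).
#' @param censoring `"none"`, `"administrative"` (cut at `t_max`), or
#'   `"random_exponential"` (independent exponential censoring with rate
#'   `rate`).
#' @param t_max Administrative censoring time (months, >= 0).
#' @param rate Exponential censoring rate (per month, > 0).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return data.frame with columns `time`, `event`.
#' @export
simulate_ipd <- function(dist, n,
                         censoring = c("none", "administrative", "random_exponential"),
                         t_max = NULL, rate = NULL, seed = NULL) {
  stopifnot(inherits(dist, "surv_dist"))
  censoring <- match.arg(censoring)
  if (!is_scalar_number(n) || n < 1 || n != round(n))
    stop_input("n must be a positive integer")
  with_seed(seed, {
    t_event <- surv_quantile(dist, stats::runif(n))
    out <- switch(censoring,
      none = data.frame(time = t_event, event = 1L),
      administrative = {
        if (!is_scalar_number(t_max) || t_max < 0)
          stop_input("administrative censoring needs t_max >= 0")
        data.frame(time = pmin(t_event, t_max),
                   event = as.integer(t_event < t_max | t_max == Inf))
      },
      random_exponential = {
        if (!is_scalar_number(rate) || rate <= 0)
          stop_input("random_exponential censoring needs rate > 0")
        t_cens <- stats::rexp(n, rate)
        data.frame(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
      })
    out
  })
}

#' Digitize a survival curve onto a time grid
#'
#' Emulates reading coordinates off a published figure: survival values at
#' the grid times plus truncated Gaussian jitter (values are clamped to
#' `[0, 1]` and re-monotonized by a running minimum).  `jitter_sd = 0`
#' returns the exact values.
#'
#' @param x A [surv_dist()] or [kaplan_meier()] curve.
#' @param times Non-empty grid of increasing times.
#' @param n_total Arm sample size recorded on the digitized curve.
#' @param jitter_sd Standard deviation of the digitization noise (>= 0).
#' @param seed Optional integer seed.
#' @return A [digitized_curve()].
#' @export
digitize_curve <- function(x, times, n_total, jitter_sd = 0, seed = NULL) {
  if (length(times) == 0) stop_input("times grid is empty")
  if (!is_scalar_number(jitter_sd) || jitter_sd < 0)
    stop_input("jitter_sd must be >= 0")
  s <- if (inherits(x, "surv_dist")) surv_prob(x, times)
       else if (inherits(x, "km_curve")) km_eval(x, times)
       else stop_input("x must be a surv_dist or km_curve")
  if (jitter_sd > 0) {
    s <- with_seed(seed, s + stats::rnorm(length(s), 0, jitter_sd))
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)
  }
  digitized_curve(times, s, n_total)
}

#' Load a model parameter table from a YAML file
#'
#' Reads and validates a structured parameter file: the sensitivity table
#' (base/min/max/distribution per parameter), log-logistic survival
#' parameters per arm and endpoint, model settings, the willingness-to-pay
#' context, and the published reference results used for calibration.
#' Every row must satisfy `min <= base <= max`.
#'
#' @param path Path to the YAML file.
#' @return Object of class `cea_parameters`: list with elements
#'   `parameters` (data.frame), `survival` (nested [surv_dist()] objects),
#'   `settings`, `wtp`, `reference` and `path`.
#' @export
load_parameter_table <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_input(sprintf("parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  need <- c("parameters", "survival_parameters", "settings", "wtp")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop_input("parameter file missing sections: ", paste(missing, collapse = ", "))

  rows <- raw$parameters
  tab <- data.frame(
    name = vapply(rows, `[[`, character(1), "name"),
    base = vapply(rows, `[[`, numeric(1), "base"),
    min = vapply(rows, `[[`, numeric(1), "min"),
    max = vapply(rows, `[[`, numeric(1), "max"),
    dist = vapply(rows, `[[`, character(1), "dist"),
    group = vapply(rows, `[[`, character(1), "group"),
    repaired = vapply(rows, function(r) isTRUE(r$repaired), logical(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tab$name))
    stop_input("duplicated parameter names in table")
  bad <- tab$name[tab$min > tab$base | tab$base > tab$max]
  if (length(bad))
    stop_input("rows violating min <= base <= max: ", paste(bad, collapse = ", "))
  if (!all(tab$dist %in% c("gamma", "beta", "normal", "fixed")))
    stop_input("unknown distribution tag in parameter table")

  sv <- lapply(raw$survival_parameters, function(arm)
    lapply(arm, function(cv) surv_dist(cv$family, c(cv$shape, cv$scale))))

  ref <- raw$reference_results
  if (!is.null(ref$price_rows))
    ref$price_rows <- do.call(rbind, lapply(ref$price_rows, as.data.frame))

  structure(list(
    parameters = tab,
    survival = sv,
    settings = model_settings(
      cycle_days = raw$settings$cycle_days,
      horizon_years = raw$settings$horizon_years,
      annual_discount = raw$settings$annual_discount
    ),
    wtp = wtp_context(raw$wtp$gdp_per_capita, raw$wtp$multiplier),
    reference = ref,
    path = path
  ), class = "cea_parameters")
}

#' The packaged ES-SCLC parameter table
#'
#' Returns the full base/min/max/distribution fixture for the socazolimab
#' evaluation: unit prices, monitoring and best-supportive-care costs,
#' grade >= 3 adverse-event incidences per arm, state utilities, discount
#' rate, patient profile, the fitted log-logistic survival parameters, and
#' the published reference results used for calibration.  The control-arm
#' thrombocytopenia bounds are repaired to +/-20% of base (the printed
#' bounds are inconsistent with the base value); the affected row carries
#' `repaired = TRUE`.
#'
#' @return A `cea_parameters` object (see [load_parameter_table()]).
#' @examples
#' fx <- fixture_parameter_table()
#' subset(fx$parameters, name == "cost_socazolimab_mg")
#' @export
fixture_parameter_table <- function() {
  load_parameter_table(
    system.file("extdata", "es_sclc_model.yaml", package = "psmcea", mustWork = TRUE))
}

#' Extract base parameter values as a named list
#'
#' @param params A `cea_parameters` object.
#' @return Named list of base values, ready for [build_cost_schedule()]
#'   and [evaluate_cea()].
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  stats::setNames(as.list(params$parameters$base), params$parameters$name)
}
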