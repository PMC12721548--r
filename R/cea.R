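# Base-case cost-utility analysis: discounted totals per arm, increments,
# ICER, willingness-to-pay context, price-discount and threshold analyses.

#' Willingness-to-pay context
#'
#' @param gdp_per_capita Per-capita GDP in CNY (2024 base: 95,797).
#' @param multiplier GDP multiplier defining the threshold (default 3,
#'   giving 287,391 CNY/QALY).
#' @export
wtp_context <- function(gdp_per_capita = 95797, multiplier = 3) {
  if (!is_scalar_number(gdp_per_capita) || gdp_per_capita <= 0 ||
      !is_scalar_number(multiplier) || multiplier <= 0)
    stop_input("gdp_per_capita and multiplier must be > 0")
  structure(list(gdp_per_capita = gdp_per_capita, multiplier = multiplier,
                 wtp = gdp_per_capita * multiplier), class = "wtp_context")
}

#' Cost-effectiveness result
#'
#' Holds discounted totals per arm, unrounded increments, the ICER
#' (computed from the unrounded increments) and a dominance flag:
#' `"dominant"` when the treatment is cheaper and more effective,
#' `"dominated"` when costlier and less effective, `"undefined"` when the
#' effect increment is zero, `"none"` otherwise.
#'
#' @param cost_treatment,cost_control Discounted total costs (CNY).
#' @param qaly_treatment,qaly_control Discounted total effects (QALYs).
#' @return Object of class `ce_result`.
#' @export
ce_result <- function(cost_treatment, cost_control, qaly_treatment, qaly_control) {
  vals <- c(cost_treatment, cost_control, qaly_treatment, qaly_control)
  if (any(!is.finite(vals))) stop_input("all inputs must be finite")
  delta_cost <- cost_treatment - cost_control
  delta_qaly <- qaly_treatment - qaly_control
  dominance <- if (delta_qaly == 0) {
    "undefined"
  } else if (delta_cost <= 0 && delta_qaly > 0) {
    "dominant"
  } else if (delta_cost >= 0 && delta_qaly < 0) {
    "dominated"
  } else "none"
  structure(list(
    cost_treatment = cost_treatment, cost_control = cost_control,
    qaly_treatment = qaly_treatment, qaly_control = qaly_control,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer = if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly,
    dominance = dominance
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  cost:  treatment %12.2f  control %12.2f  (delta %10.2f CNY)\n",
              x$cost_treatment, x$cost_control, x$delta_cost))
  cat(sprintf("  QALYs: treatment %12.4f  control %12.4f  (delta %10.4f)\n",
              x$qaly_treatment, x$qaly_control, x$delta_qaly))
  if (is.na(x$icer)) cat("  ICER: undefined (zero effect increment)\n")
  else cat(sprintf("  ICER: %.2f CNY/QALY%s\n", x$icer,
                   if (x$dominance %in% c("dominant", "dominated"))
                     paste0(" [", x$dominance, "]") else ""))
  invisible(x)
}

#' Evaluate the full cost-effectiveness pipeline for one parameter set
#'
#' Builds both arms' partitioned-survival traces and cost schedules and
#' returns the incremental result.  This is the single entry point used by
#' the base case, the tornado analysis and the probabilistic sensitivity
#' analysis; `values` carries every sampled/varied quantity (including the
#' discount rate, which re-enters [model_settings()]).
#'
#' @param values Named list of parameter values (see [param_values()]).
#' @param survival Nested list of [surv_dist()] objects:
#'   `survival$treatment$pfs`, `$os`, `survival$control$pfs`, `$os`.
#' @param settings A [model_settings()] supplying cycle length, horizon
#'   and half-cycle convention; its discount rate is overridden by
#'   `values$discount_rate`.
#' @param soca_mode,soca_calibration See [build_cost_schedule()].
#' @return A [ce_result()].
#' @export
evaluate_cea <- function(values, survival, settings = model_settings(),
                         soca_mode = c("calibrated", "protocol"),
                         soca_calibration = NULL) {
  soca_mode <- match.arg(soca_mode)
  st <- model_settings(
    cycle_days = settings$cycle_days,
    horizon_years = settings$horizon_years,
    annual_discount = values$discount_rate %||% settings$annual_discount,
    half_cycle_correction = settings$half_cycle_correction
  )
  utilities <- list(u_pfs = values$u_pfs, u_pd = values$u_pd)
  arms <- lapply(c(treatment = "treatment", control = "control"), function(arm) {
    tr <- build_trace(survival[[arm]]$pfs, survival[[arm]]$os, st)
    sch <- build_cost_schedule(arm, values, st, soca_mode, soca_calibration)
    list(cost = accumulate_costs(tr, sch, st),
         qaly = accumulate_qalys(tr, utilities, st))
  })
  ce_result(arms$treatment$cost, arms$control$cost,
            arms$treatment$qaly, arms$control$qaly)
}

#' Base-case analysis from a parameter table
#'
#' Runs [evaluate_cea()] at the table's base values.  In the default
#' calibrated mode the total socazolimab expenditure is derived from the
#' published price-simulation rows via [calibrate_socazolimab()].
#'
#' @param params A `cea_parameters` object (default: the packaged
#'   ES-SCLC table, [fixture_parameter_table()]).
#' @param soca_mode See [build_cost_schedule()].
#' @param half_cycle_correction Enable the half-cycle correction.
#' @return A [ce_result()].
#' @export
base_case <- function(params = fixture_parameter_table(),
                      soca_mode = c("calibrated", "protocol"),
                      half_cycle_correction = FALSE) {
  soca_mode <- match.arg(soca_mode)
  st <- params$settings
  st$half_cycle_correction <- isTRUE(half_cycle_correction)
  evaluate_cea(param_values(params), params$survival, st, soca_mode,
               soca_calibration = soca_calibration_from(params))
}

# calibration reference (total at base price/weight) from a parameter table
soca_calibration_from <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  if (is.null(params$reference$price_rows)) return(NULL)
  v <- param_values(params)
  list(total = calibrate_socazolimab(params$reference$price_rows),
       ref_price = v$cost_socazolimab_mg, ref_weight = v$weight_kg)
}

#' Price-discount analysis
#'
#' Re-prices socazolimab at a set of retained price fractions `f`: the
#' incremental cost becomes `delta_cost - (1 - f) * soca_total` while the
#' effect increment is unchanged, and the ICER is recomputed.
#'
#' @param base A [ce_result()] for the base case.
#' @param soca_total Total discounted socazolimab expenditure at full
#'   price (CNY, >= 0).
#' @param fractions Retained price fractions in `(0, 1]`.
#' @return data.frame with columns `fraction`, `cost_treatment`,
#'   `delta_cost`, `icer`.
#' @export
price_discount_analysis <- function(base, soca_total,
                                    fractions = c(0.9, 0.8, 0.7, 0.68, 0.67, 0.6)) {
  stopifnot(inherits(base, "ce_result"))
  if (!is_scalar_number(soca_total) || soca_total < 0)
    stop_input("soca_total must be >= 0")
  if (any(fractions <= 0) || any(fractions > 1))
    stop_input("fractions must lie in (0, 1]")
  dc <- base$delta_cost - (1 - fractions) * soca_total
  data.frame(
    fraction = fractions,
    cost_treatment = base$cost_treatment - (1 - fractions) * soca_total,
    delta_cost = dc,
    icer = dc / base$delta_qaly
  )
}

#' Socazolimab price at which the ICER meets the WTP threshold
#'
#' Solves the affine relation
#' `delta_cost - (1 - f) * soca_total = wtp * delta_qaly` for the retained
#' fraction `f` and converts it to a unit price.  A solution outside
#' `(0, 1]` is reported as infeasible (`NA` with attribute
#' `feasible = FALSE`): the regimen is either already cost-effective at
#' full price (`f > 1`) or cannot reach the threshold through the drug
#' price alone (`f <= 0`).
#'
#' @param base A [ce_result()].
#' @param soca_total Total discounted socazolimab expenditure (> 0).
#' @param unit_price Current unit price (CNY/mg, base 115).
#' @param wtp A [wtp_context()] or a numeric threshold (CNY/QALY).
#' @return Threshold unit price (CNY/mg), with attributes `fraction` and
#'   `feasible`.
#' @export
threshold_price <- function(base, soca_total, unit_price = 115,
                            wtp = wtp_context()) {
  stopifnot(inherits(base, "ce_result"))
  if (!is_scalar_number(soca_total) || soca_total <= 0)
    stop_input("soca_total must be > 0")
  lambda <- if (inherits(wtp, "wtp_context")) wtp$wtp else wtp
  if (!is_scalar_number(lambda) || lambda < 0)
    stop_input("wtp must be a non-negative number")
  f <- 1 - (base$delta_cost - lambda * base$delta_qaly) / soca_total
  feasible <- f > 0 && f <= 1
  out <- if (feasible) f * unit_price else NA_real_
  structure(out, fraction = f, feasible = feasible)
}
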