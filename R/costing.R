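# Turns the trial's dosing rules and the unit-price table into per-cycle,
# per-state cost schedules for both arms.
#
# Regimen (every 3 weeks): socazolimab 5 mg/kg on day 1 (treatment arm,
# capped at 2 years); carboplatin AUC 5 on day 1 (Calvert formula);
# etoposide 100 mg/m2 on days 1-3; four chemotherapy cycles.
#
# Accrual conventions (documented in the methods vignette):
#   - laboratory + radiology monitoring every alive cycle (PFS and PD);
#   - best supportive care per PD cycle;
#   - chemotherapy drug cost in the first four cycles, borne only by
#     patients still progression-free (the engine weights PFS-state costs
#     by PFS occupancy);
#   - adverse-event management cost as a single up-front expenditure
#     (incidences are whole-course probabilities);
#   - socazolimab either per protocol (per-cycle cost while
#     progression-free, up to floor(730.5/21) = 34 cycles) or calibrated
#     (a one-off expenditure anchored to the published price-simulation
#     arithmetic, scaled with unit price and patient weight).

#' Patient profile used for dose calculations
#'
#' @param weight Body weight in kg (base 59).
#' @param bsa Body surface area in m^2 (base 1.72).
#' @param ccr Creatinine clearance in mL/min (base 90).
#' @export
patient_profile <- function(weight = 59, bsa = 1.72, ccr = 90) {
  vals <- c(weight = weight, bsa = bsa, ccr = ccr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_input("weight, bsa and ccr must all be > 0")
  structure(as.list(vals), class = "patient_profile")
}

#' Compute a drug dose from its dosing rule
#'
#' @param rule `"per_kg"` (mg/kg), `"per_m2"` (mg/m^2 per administration
#'   day), or `"calvert"` (carboplatin: dose mg = AUC x (GFR + 25), with
#'   creatinine clearance standing in for GFR).
#' @param amount The rule-specific dose parameter (mg/kg, mg/m^2, or
#'   target AUC in mg.min/mL).
#' @param profile A [patient_profile()].
#' @return Dose in mg (per administration day for `"per_m2"`).
#' @examples
#' compute_dose("per_kg", 5, patient_profile())    # 295 mg socazolimab
#' compute_dose("calvert", 5, patient_profile())   # 575 mg carboplatin
#' @export
compute_dose <- function(rule = c("per_kg", "per_m2", "calvert"), amount,
                         profile = patient_profile()) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "patient_profile"))
  if (!is_scalar_number(amount) || amount <= 0)
    stop_input("amount must be a positive number")
  switch(rule,
    per_kg = amount * profile$weight,
    per_m2 = amount * profile$bsa,
    calvert = amount * (profile$ccr + 25)
  )
}

#' One-off adverse-event management cost
#'
#' Expected cost of treating grade >= 3 adverse events, computed as
#' `sum(incidence * unit cost)` and applied once at model entry.
#'
#' @param incidences Numeric vector of whole-course event probabilities in
#'   `[0, 1]`.
#' @param unit_costs Matching vector of per-event management costs (CNY).
#' @export
adverse_event_cost <- function(incidences, unit_costs) {
  if (length(incidences) != length(unit_costs))
    stop_input("incidences and unit_costs must have equal length")
  if (any(incidences < 0) || any(incidences > 1))
    stop_input("incidences must lie in [0, 1]")
  if (any(unit_costs < 0)) stop_input("unit costs must be >= 0")
  sum(incidences * unit_costs)
}

ae_names <- c("neutropenia", "leukocytopenia", "anemia", "thrombocytopenia")

arm_ae_cost <- function(values, arm) {
  adverse_event_cost(
    unlist(values[paste0("inc_", ae_names, "_", arm)]),
    unlist(values[paste0("cost_", ae_names)])
  )
}

#' Per-cycle cost schedule container
#'
#' @param pfs_cost Per-cycle cost while progression-free (scalar or vector).
#' @param pd_cost Per-cycle cost while progressed (scalar or vector).
#' @param one_off One-off cost at model entry (CNY, >= 0).
#' @export
cost_schedule <- function(pfs_cost = 0, pd_cost = 0, one_off = 0) {
  if (any(pfs_cost < 0) || any(pd_cost < 0) || any(one_off < 0))
    stop_input("all schedule entries must be >= 0")
  structure(list(pfs_cost = pfs_cost, pd_cost = pd_cost, one_off = one_off),
            class = "cost_schedule")
}

#' Build the cost schedule for one arm
#'
#' @param arm `"treatment"` (socazolimab + carboplatin/etoposide) or
#'   `"control"` (placebo + carboplatin/etoposide).
#' @param values Named list of parameter values as produced by
#'   [param_values()] (unit prices, AE incidences, patient profile).
#' @param settings A [model_settings()].
#' @param soca_mode `"calibrated"` (default): socazolimab enters as a
#'   one-off expenditure equal to the calibrated total, scaled
#'   proportionally with its unit price and the patient weight;
#'   `"protocol"`: per-cycle drug cost while progression-free up to the
#'   2-year cap.
#' @param soca_calibration For `"calibrated"` mode, a list with `total`
#'   (CNY), `ref_price` (CNY/mg) and `ref_weight` (kg): the expenditure
#'   total and the price/weight it was calibrated at.  See
#'   [calibrate_socazolimab()].
#' @return A [cost_schedule()] spanning `settings$n_cycles + 1` cycles.
#' @export
build_cost_schedule <- function(arm = c("treatment", "control"), values,
                                settings = model_settings(),
                                soca_mode = c("calibrated", "protocol"),
                                soca_calibration = NULL) {
  arm <- match.arg(arm)
  soca_mode <- match.arg(soca_mode)
  stopifnot(inherits(settings, "model_settings"))
  v <- values
  profile <- patient_profile(v$weight_kg, v$bsa_m2, v$ccr_ml_min)
  n <- settings$n_cycles + 1

  monitoring <- v$cost_laboratory + v$cost_radiology
  pfs <- rep(monitoring, n)
  pd <- rep(monitoring + v$cost_bsc_cycle, n)

  chemo <- 3 * compute_dose("per_m2", 100, profile) * v$cost_etoposide_mg +
           compute_dose("calvert", 5, profile) * v$cost_carboplatin_mg
  idx <- seq_len(min(4, n))
  pfs[idx] <- pfs[idx] + chemo

  one_off <- arm_ae_cost(v, arm)

  if (arm == "treatment") {
    if (soca_mode == "protocol") {
      cap <- floor(2 * 365.25 / settings$cycle_days)
      idx <- seq_len(min(cap, n))
      pfs[idx] <- pfs[idx] + compute_dose("per_kg", 5, profile) * v$cost_socazolimab_mg
    } else {
      if (is.null(soca_calibration) || !is_scalar_number(soca_calibration$total))
        stop_input("calibrated soca_mode requires soca_calibration$total")
      ref_price <- soca_calibration$ref_price %||% v$cost_socazolimab_mg
      ref_weight <- soca_calibration$ref_weight %||% v$weight_kg
      one_off <- one_off + soca_calibration$total *
        (v$cost_socazolimab_mg / ref_price) * (v$weight_kg / ref_weight)
    }
  }
  cost_schedule(pfs_cost = pfs, pd_cost = pd, one_off = one_off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the total discounted socazolimab expenditure
#'
#' The published price simulation reports incremental cost at several
#' retained-price fractions; because total cost is affine in the
#' socazolimab unit price, the least-squares slope of incremental cost on
#' retained fraction recovers the total discounted socazolimab expenditure
#' implied by the original analysis.  For exactly collinear input the
#' slope is exact (two rows `(1, IC1)`, `(0.7, IC0.7)` give
#' `(IC1 - IC0.7) / 0.3`).
#'
#' @param price_rows data.frame with columns `fraction` (retained price
#'   fraction, in `(0, 1]`) and `incremental_cost` (CNY); at least two
#'   distinct fractions.
#' @return Total socazolimab expenditure (CNY, discounted).
#' @export
calibrate_socazolimab <- function(price_rows) {
  if (!is.data.frame(price_rows) ||
      !all(c("fraction", "incremental_cost") %in% names(price_rows)))
    stop_input("price_rows must have columns 'fraction' and 'incremental_cost'")
  if (length(unique(price_rows$fraction)) < 2)
    stop_input("calibration needs at least two distinct price fractions")
  unname(stats::coef(stats::lm(incremental_cost ~ fraction, data = price_rows))[2])
}
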