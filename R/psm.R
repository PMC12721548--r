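# Partitioned-survival cohort engine: per-cycle occupancy of the three
# health states (progression-free, progressed, dead) derived directly from
# the PFS and OS curves, with discounting and QALY/cost accrual.

#' Model settings
#'
#' @param cycle_days Cycle length in days (default 21: one 3-week
#'   treatment cycle).
#' @param horizon_years Simulation horizon in years (default 10).
#' @param annual_discount Annual discount rate for costs and effects,
#'   in `[0, 0.08]` (default 0.05).
#' @param half_cycle_correction Average adjacent cycle occupancies when
#'   accruing rewards (default `FALSE`: cycle-start evaluation).
#' @return List of class `model_settings` with derived fields
#'   `cycle_months = cycle_days / 30.4375` and
#'   `n_cycles = floor(horizon_years * 365.25 / cycle_days)` (the trace has
#'   `n_cycles + 1` rows, cycle 0 included as a full cycle at discount 1).
#' @export
model_settings <- function(cycle_days = 21, horizon_years = 10,
                           annual_discount = 0.05,
                           half_cycle_correction = FALSE) {
  if (!is_scalar_number(cycle_days) || cycle_days <= 0)
    stop_input("cycle_days must be > 0")
  if (!is_scalar_number(horizon_years) || horizon_years <= 0)
    stop_input("horizon_years must be > 0")
  if (!is_scalar_number(annual_discount) || annual_discount < 0 || annual_discount > 0.08)
    stop_input("annual_discount must lie in [0, 0.08]")
  structure(list(
    cycle_days = cycle_days,
    horizon_years = horizon_years,
    annual_discount = annual_discount,
    half_cycle_correction = isTRUE(half_cycle_correction),
    cycle_months = cycle_days / 30.4375,
    n_cycles = floor(horizon_years * 365.25 / cycle_days)
  ), class = "model_settings")
}

#' State utilities
#'
#' Annual utility weights for the progression-free and progressed states.
#' Defaults are the base-case values for first-line ES-SCLC therapy.
#'
#' @param u_pfs Utility per year in the progression-free state (base 0.673).
#' @param u_pd Utility per year in the progressed state (base 0.473);
#'   must satisfy `0 <= u_pd <= u_pfs <= 1`.
#' @export
utility_set <- function(u_pfs = 0.673, u_pd = 0.473) {
  if (!is_scalar_number(u_pfs) || !is_scalar_number(u_pd))
    stop_input("utilities must be numbers")
  if (u_pd < 0 || u_pfs > 1 || u_pd > u_pfs)
    stop_input("utilities must satisfy 0 <= u_pd <= u_pfs <= 1")
  structure(list(u_pfs = u_pfs, u_pd = u_pd), class = "utility_set")
}

#' Build the partitioned-survival cohort trace
#'
#' At cycle `k` (time `t_k = k * cycle_months`):
#' \itemize{
#'   \item PFS occupancy `= min(S_pfs(t_k), S_os(t_k))`
#'   \item death occupancy `= 1 - S_os(t_k)`
#'   \item PD occupancy `= S_os(t_k) - min(S_pfs(t_k), S_os(t_k))`
#' }
#' Crossings of independently fitted curves (`S_pfs > S_os`) are clipped so
#' PD occupancy stays non-negative; the number of clipped cycles is
#' recorded in the `"n_clipped"` attribute.  The discount factor is
#' anchored in continuous time at cycle start,
#' `(1 + annual_discount)^(-t_k / 12)`.
#'
#' @param pfs,os [surv_dist()] objects for progression-free and overall
#'   survival.
#' @param settings A [model_settings()].
#' @return data.frame of class `cohort_trace` with columns `cycle`,
#'   `time_months`, `pfs`, `pd`, `death`, `discount`; attributes
#'   `settings` and `n_clipped`.
#' @export
build_trace <- function(pfs, os, settings = model_settings()) {
  stopifnot(inherits(pfs, "surv_dist"), inherits(os, "surv_dist"),
            inherits(settings, "model_settings"))
  k <- 0:settings$n_cycles
  t_k <- k * settings$cycle_months
  s_pfs <- surv_prob(pfs, t_k)
  s_os <- surv_prob(os, t_k)
  occ_pfs <- pmin(s_pfs, s_os)
  n_clipped <- sum(s_pfs > s_os)
  tr <- data.frame(
    cycle = k,
    time_months = t_k,
    pfs = occ_pfs,
    pd = s_os - occ_pfs,
    death = 1 - s_os,
    discount = (1 + settings$annual_discount)^(-t_k / 12)
  )
  class(tr) <- c("cohort_trace", "data.frame")
  attr(tr, "settings") <- settings
  attr(tr, "n_clipped") <- n_clipped
  tr
}

trace_settings <- function(trace, settings) {
  if (is.null(settings)) settings <- attr(trace, "settings")
  stopifnot(inherits(settings, "model_settings"))
  settings
}

# occupancy columns adjusted for the half-cycle convention: averages of
# adjacent cycles (one fewer accrual interval than trace rows)
occupancy_for_accrual <- function(occ, half_cycle) {
  if (!half_cycle) return(occ)
  (occ[-length(occ)] + occ[-1]) / 2
}

discount_for_accrual <- function(disc, half_cycle) {
  if (!half_cycle) return(disc)
  disc[-length(disc)]
}

#' Accumulate discounted QALYs from a cohort trace
#'
#' Sums `discount_k * (u_pfs * pfs_k + u_pd * pd_k) * cycle_years` over the
#' trace.  Under the half-cycle correction, adjacent occupancies are
#' averaged (trapezoidal accrual over `n_cycles` intervals, discounted at
#' interval start).
#'
#' @param trace A [build_trace()] result.
#' @param utilities A [utility_set()], or any list/vector with elements
#'   `u_pfs` and `u_pd` (the lenient form is used by the probabilistic
#'   sensitivity analysis, where independently sampled utilities may
#'   transiently violate the ordering constraint).
#' @param settings Optional [model_settings()]; defaults to the trace's own.
#' @return Discounted QALYs per patient.
#' @export
accumulate_qalys <- function(trace, utilities = utility_set(), settings = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  settings <- trace_settings(trace, settings)
  u_pfs <- utilities[["u_pfs"]]; u_pd <- utilities[["u_pd"]]
  if (!is_scalar_number(u_pfs) || !is_scalar_number(u_pd) || u_pfs < 0 || u_pd < 0)
    stop_input("utilities must be non-negative numbers named u_pfs and u_pd")
  hc <- settings$half_cycle_correction
  occ <- u_pfs * occupancy_for_accrual(trace$pfs, hc) +
         u_pd * occupancy_for_accrual(trace$pd, hc)
  sum(discount_for_accrual(trace$discount, hc) * occ) * settings$cycle_months / 12
}

#' Accumulate discounted life years from a cohort trace
#'
#' Equivalent to [accumulate_qalys()] with both utilities equal to 1.
#' @inheritParams accumulate_qalys
#' @export
accumulate_life_years <- function(trace, settings = NULL) {
  accumulate_qalys(trace, list(u_pfs = 1, u_pd = 1), settings)
}

#' Accumulate discounted costs from a cohort trace and cost schedule
#'
#' Sums `discount_k * (pfs_cost_k * pfs_k + pd_cost_k * pd_k)` over the
#' trace, plus one-off costs (applied undiscounted at model entry).
#' Per-state cost entries may be a constant or a vector of length
#' `nrow(trace)`.
#'
#' @param trace A [build_trace()] result.
#' @param schedule A [cost_schedule()] (or list with `pfs_cost`, `pd_cost`,
#'   `one_off`).
#' @param settings Optional [model_settings()].
#' @return Discounted cost per patient (CNY).
#' @export
accumulate_costs <- function(trace, schedule, settings = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  settings <- trace_settings(trace, settings)
  n <- nrow(trace)
  expand <- function(x, what) {
    if (length(x) == 1) rep(x, n)
    else if (length(x) == n) x
    else stop_input(sprintf("%s has length %d; expected 1 or %d", what, length(x), n))
  }
  pfs_cost <- expand(schedule$pfs_cost, "pfs_cost")
  pd_cost <- expand(schedule$pd_cost, "pd_cost")
  one_off <- if (is.null(schedule$one_off)) 0 else schedule$one_off
  if (any(pfs_cost < 0) || any(pd_cost < 0) || one_off < 0)
    stop_input("costs must be non-negative")
  hc <- settings$half_cycle_correction
  per_cycle <- occupancy_for_accrual(trace$pfs, hc) *
                 (if (hc) pfs_cost[-n] else pfs_cost) +
               occupancy_for_accrual(trace$pd, hc) *
                 (if (hc) pd_cost[-n] else pd_cost)
  sum(discount_for_accrual(trace$discount, hc) * per_cycle) + one_off
}
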