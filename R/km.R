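# Kaplan-Meier estimation and reconstruction of pseudo individual-patient
# data from digitized survival-curve coordinates (the published-curve ->
# IPD step that precedes parametric fitting when trial data are not
# deposited).

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step curve in the
#' package's container.
#'
#' @param data data.frame with columns `time` and `event` (1 = event,
#'   0 = censored); at least one record.
#' @return An object of class `km_curve`: list with `time`, `surv`
#'   (including the `(0, 1)` origin), and per-step `n_risk`, `n_event`,
#'   `n_censor`.
#' @export
kaplan_meier <- function(data) {
  data <- check_ipd(data)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "none")
  structure(list(
    time = c(0, sf$time), surv = c(1, sf$surv),
    n_risk = sf$n.risk, n_event = sf$n.event, n_censor = sf$n.censor,
    step_time = sf$time, n = nrow(data)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d step times, final S = %.4f\n",
              x$n, length(x$step_time), min(x$surv)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step interpolation of the product-limit estimate.
#' @param curve A [kaplan_meier()] result.
#' @param t Times (>= 0).
#' @export
km_eval <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  check_times(t)
  stats::stepfun(curve$time[-1], curve$surv, right = FALSE)(t)
}

#' Construct a digitized survival curve
#'
#' Represents point coordinates read off a published Kaplan-Meier figure.
#' Digitization jitter can leave the survival values locally increasing;
#' increases of at most `snap_tol` are snapped back to the running minimum,
#' larger violations are rejected as input errors.
#'
#' @param t Strictly increasing times (months).
#' @param s Survival probabilities in `[0, 1]` at `t`.
#' @param n_total Arm sample size (>= 2); required because at-risk counts
#'   are usually not printed with the curve.
#' @param risk_table Optional data.frame with columns `time` and `n_risk`
#'   (numbers at risk at those times, non-increasing).
#' @param snap_tol Largest monotonicity violation treated as digitizer
#'   noise (default 0.005).
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(t, s, n_total, risk_table = NULL, snap_tol = 0.005) {
  if (length(t) != length(s) || length(t) == 0)
    stop_input("t and s must be non-empty vectors of equal length")
  if (any(!is.finite(t)) || any(diff(t) <= 0) || any(t < 0))
    stop_input("digitized times must be non-negative and strictly increasing")
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop_input("digitized survival values must lie in [0, 1]")
  if (!is_scalar_number(n_total) || n_total < 2 || n_total != round(n_total))
    stop_input("n_total must be an integer >= 2")
  for (i in seq_along(s)[-1]) {
    if (s[i] > s[i - 1]) {
      if (s[i] - s[i - 1] <= snap_tol) s[i] <- s[i - 1]
      else stop_input(sprintf(
        "survival increases by %.4f at t = %g (> snap tolerance %.4f)",
        s[i] - s[i - 1], t[i], snap_tol))
    }
  }
  if (!is.null(risk_table)) {
    if (!is.data.frame(risk_table) || !all(c("time", "n_risk") %in% names(risk_table)))
      stop_input("risk_table must have columns 'time' and 'n_risk'")
    if (is.unsorted(risk_table$time, strictly = TRUE))
      stop_input("risk_table times must be strictly increasing")
    if (any(diff(risk_table$n_risk) > 0))
      stop_input("numbers at risk must be non-increasing")
    if (risk_table$n_risk[1] > n_total)
      stop_input("first n_risk exceeds n_total")
  }
  structure(list(t = t, s = s, n_total = as.integer(n_total),
                 risk_table = risk_table),
            class = "digitized_curve")
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts the product-limit estimator.  Without a risk table, censoring is
#' assumed to occur only after the last digitized point, so the curve is an
#' empirical survival function and cumulative event counts are recovered by
#' rounding `n_total * (1 - s)`; survivors are censored at the last
#' digitized time.  With a risk table, an iterative interval-matching
#' scheme in the style of the standard KM-reconstruction algorithm spreads
#' censoring uniformly within each risk-table interval and adjusts the
#' per-interval censor count until the computed number at risk matches the
#' published one.
#'
#' The reconstructed data always contain exactly `n_total` records with
#' times inside `[0, max(t)]`.
#'
#' @param curve A [digitized_curve()].
#' @return data.frame with columns `time` and `event`.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (is.null(curve$risk_table)) reconstruct_no_risk(curve)
  else reconstruct_with_risk(curve)
}

reconstruct_no_risk <- function(curve) {
  n <- curve$n_total
  cum_events <- cummax(pmin(round(n * (1 - curve$s)), n))
  d <- diff(c(0, cum_events))
  times <- rep(curve$t, d)
  n_cens <- n - sum(d)
  out <- data.frame(
    time = c(times, rep(max(curve$t), n_cens)),
    event = c(rep(1L, length(times)), rep(0L, n_cens))
  )
  out[order(out$time, -out$event), , drop = FALSE]
}

reconstruct_with_risk <- function(curve) {
  t <- curve$t; s <- curve$s; rt <- curve$risk_table
  N <- length(t)
  J <- nrow(rt)
  # first digitized point at or after each risk-table time
  lower <- vapply(rt$time, function(T0) {
    w <- which(t >= T0)
    if (length(w)) min(w) else N + 1L
  }, integer(1))
  keep <- lower <= N
  lower <- lower[keep]; n_pub <- rt$n_risk[keep]; J <- length(lower)
  upper <- c(lower[-1] - 1L, N)

  d <- integer(N)                      # events at each point
  cens_times <- numeric(0)
  n_cur <- n_pub[1]
  s_prev <- 1
  for (j in seq_len(J)) {
    idx <- lower[j]:upper[j]
    if (length(idx) == 0 || idx[1] > idx[length(idx)]) next
    target <- if (j < J) n_pub[j + 1] else NA_integer_
    cj <- 0L
    for (iter in 1:60) {
      cvec <- diff(round(seq(0, cj, length.out = length(idx) + 1)))
      n_i <- n_cur; S <- s_prev
      dvec <- integer(length(idx))
      for (k in seq_along(idx)) {
        i <- idx[k]
        di <- if (S > 0 && n_i > 0) round(n_i * (1 - s[i] / S)) else 0
        di <- max(0L, min(di, n_i))
        dvec[k] <- di
        if (n_i > 0 && di > 0) S <- S * (1 - di / n_i)
        n_i <- max(0L, n_i - di - cvec[k])
      }
      if (is.na(target) || n_i == target) break
      cj <- max(0L, cj + (n_i - target))
    }
    d[idx] <- dvec
    # censor times spread uniformly between consecutive digitized points
    for (k in seq_along(idx)) {
      ck <- cvec[k]
      if (ck > 0) {
        i <- idx[k]
        t_hi <- if (i < N) t[i + 1] else t[i]
        cens_times <- c(cens_times, t[i] + (t_hi - t[i]) * seq_len(ck) / (ck + 1))
      }
    }
    n_cur <- n_i; s_prev <- S
  }
  times <- rep(t, d)
  extra <- curve$n_total - length(times) - length(cens_times)
  # anyone unaccounted for is censored at the end of follow-up
  out <- data.frame(
    time = c(times, cens_times, rep(max(t), max(0L, extra))),
    event = c(rep(1L, length(times)), rep(0L, length(cens_times) + max(0L, extra)))
  )
  out[order(out$time, -out$event), , drop = FALSE]
}
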