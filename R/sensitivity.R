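# Deterministic (one-way / tornado) and probabilistic (Monte Carlo, CEAC,
# cost-effectiveness plane) sensitivity analyses over the parameter table.

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the ICER with each parameter set to its lower and upper
#' bound in turn, all other parameters at base.  Entries are returned
#' sorted by descending span `|icer_high - icer_low|`.
#'
#' @param params A `cea_parameters` object.
#' @param soca_mode,half_cycle_correction See [base_case()].
#' @param parameters Optional character vector restricting which table
#'   rows are varied (default: all).
#' @return data.frame of class `tornado` with columns `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `span`, plus attribute `base_icer`.
#' @export
owsa <- function(params = fixture_parameter_table(),
                 soca_mode = c("calibrated", "protocol"),
                 half_cycle_correction = FALSE, parameters = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  soca_mode <- match.arg(soca_mode)
  tab <- params$parameters
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, tab$name)
    if (length(missing))
      stop_input("unknown parameter(s): ", paste(missing, collapse = ", "))
    tab <- tab[tab$name %in% parameters, , drop = FALSE]
  }
  if (any(tab$min > tab$max)) stop_input("parameter bounds with min > max")
  st <- params$settings
  st$half_cycle_correction <- isTRUE(half_cycle_correction)
  base_values <- param_values(params)
  cal <- soca_calibration_from(params)
  base <- evaluate_cea(base_values, params$survival, st, soca_mode, cal)

  eval_at <- function(name, value) {
    v <- base_values
    v[[name]] <- value
    evaluate_cea(v, params$survival, st, soca_mode, cal)$icer
  }
  icer_low <- unname(mapply(eval_at, tab$name, tab$min))
  icer_high <- unname(mapply(eval_at, tab$name, tab$max))
  out <- data.frame(
    parameter = tab$name, low = tab$min, high = tab$max,
    icer_low = icer_low, icer_high = icer_high,
    span = abs(icer_high - icer_low), row.names = NULL
  )
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  attr(out, "base_icer") <- base$icer
  out
}

#' Method-of-moments sampling distribution for one parameter
#'
#' The min/max bounds are read as a central 95% interval, so
#' `sd = (max - min) / 3.92`.  Gamma: `shape = (mean/sd)^2`,
#' `rate = mean/sd^2`.  Beta: matched on the natural `[0, 1]` scale.
#' A zero-width interval degenerates to a point mass.
#'
#' @param base,min,max Base value and bounds.
#' @param dist `"gamma"`, `"beta"`, `"normal"` or `"fixed"`.
#' @param name Parameter name, used in error messages.
#' @return List with elements `dist` and the distribution's parameters.
#' @export
moment_match <- function(base, min, max, dist, name = "parameter") {
  sd <- (max - min) / 3.92
  if (dist == "fixed" || sd == 0) return(list(dist = "fixed", value = base))
  switch(dist,
    gamma = {
      if (base <= 0)
        stop_input(sprintf("%s: gamma requires a positive mean", name))
      list(dist = "gamma", shape = (base / sd)^2, rate = base / sd^2)
    },
    beta = {
      if (base <= 0 || base >= 1)
        stop_input(sprintf("%s: beta requires a mean in (0, 1)", name))
      nu <- base * (1 - base) / sd^2 - 1
      if (nu <= 0)
        stop_input(sprintf("%s: bounds too wide for a beta distribution", name))
      list(dist = "beta", shape1 = base * nu, shape2 = (1 - base) * nu)
    },
    normal = list(dist = "normal", mean = base, sd = sd),
    stop_input(sprintf("%s: unknown distribution '%s'", name, dist))
  )
}

#' Build the PSA sampling specification from a parameter table
#'
#' One sampling distribution per table row via [moment_match()].  The
#' discount rate is held fixed at base by default (standard practice for a
#' structural/model parameter); `sample_discount = TRUE` samples it as a
#' Beta on `[0, max]` rescaled from the bounds.
#'
#' @param params A `cea_parameters` object.
#' @param sample_discount Sample the discount rate too (default `FALSE`).
#' @return Named list of moment-matched distributions (class `psa_spec`).
#' @export
psa_spec <- function(params, sample_discount = FALSE) {
  stopifnot(inherits(params, "cea_parameters"))
  tab <- params$parameters
  spec <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (row$name == "discount_rate") {
      if (!sample_discount) return(list(dist = "fixed", value = row$base))
      # Beta on [0, max], moment-matched on the rescaled mean
      m <- row$base / row$max
      s <- (row$max - row$min) / 3.92 / row$max
      nu <- m * (1 - m) / s^2 - 1
      return(list(dist = "scaled_beta", shape1 = m * nu, shape2 = (1 - m) * nu,
                  scale = row$max))
    }
    moment_match(row$base, row$min, row$max, row$dist, row$name)
  })
  names(spec) <- tab$name
  structure(spec, class = "psa_spec")
}

sample_psa_params <- function(spec, n) {
  draws <- lapply(spec, function(d) {
    switch(d$dist,
      fixed = rep(d$value, n),
      gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
      beta = stats::rbeta(n, d$shape1, d$shape2),
      scaled_beta = d$scale * stats::rbeta(n, d$shape1, d$shape2),
      normal = stats::rnorm(n, d$mean, d$sd)
    )
  })
  as.data.frame(draws)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the [psa_spec()] distributions (utilities
#' and unit costs shared between arms, adverse-event incidences sampled
#' per arm) and evaluates both arms through the full pipeline for each
#' draw.  Seeded and reproducible; the caller's RNG state is untouched.
#'
#' @param params A `cea_parameters` object.
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed (default 1).
#' @param soca_mode,half_cycle_correction See [base_case()].
#' @param sample_discount See [psa_spec()].
#' @return data.frame of class `psa_draws` with columns `cost_treatment`,
#'   `cost_control`, `qaly_treatment`, `qaly_control`, `delta_cost`,
#'   `delta_qaly`; attributes `seed`, `n`, `spec`.
#' @export
psa <- function(params = fixture_parameter_table(), n = 1000, seed = 1,
                soca_mode = c("calibrated", "protocol"),
                half_cycle_correction = FALSE, sample_discount = FALSE) {
  stopifnot(inherits(params, "cea_parameters"))
  soca_mode <- match.arg(soca_mode)
  if (!is_scalar_number(n) || n < 1) stop_input("n must be >= 1")
  spec <- psa_spec(params, sample_discount)
  st <- params$settings
  st$half_cycle_correction <- isTRUE(half_cycle_correction)
  cal <- soca_calibration_from(params)
  mat <- with_seed(seed, sample_psa_params(spec, n))
  # profile quantities must stay positive; the normal tails are reflected
  for (nm in c("weight_kg", "bsa_m2", "ccr_ml_min"))
    if (nm %in% names(mat)) mat[[nm]] <- abs(mat[[nm]])

  m <- as.matrix(mat)
  res <- vapply(seq_len(n), function(i) {
    ce <- evaluate_cea(as.list(m[i, ]), params$survival, st, soca_mode, cal)
    c(ce$cost_treatment, ce$cost_control, ce$qaly_treatment, ce$qaly_control)
  }, numeric(4))
  out <- data.frame(
    cost_treatment = res[1, ], cost_control = res[2, ],
    qaly_treatment = res[3, ], qaly_control = res[4, ]
  )
  out$delta_cost <- out$cost_treatment - out$cost_control
  out$delta_qaly <- out$qaly_treatment - out$qaly_control
  class(out) <- c("psa_draws", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  out
}

#' Acceptance probability of the treatment arm at one WTP value
#'
#' Fraction of draws in which the treatment arm has the strictly higher
#' net monetary benefit `lambda * E - C`; ties are awarded to control.
#'
#' @param draws A [psa()] result.
#' @param wtp WTP value(s), CNY/QALY.
#' @export
acceptance_probability <- function(draws, wtp) {
  stopifnot(inherits(draws, "psa_draws"))
  vapply(wtp, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
}

#' Cost-effectiveness acceptability curves
#'
#' @param draws A [psa()] result.
#' @param wtp_grid WTP grid (default 0 to 600,000 CNY in 2,500-CNY steps).
#' @return data.frame of class `ceac` with columns `wtp`, `p_treatment`,
#'   `p_control` (the two curves sum to 1 at every WTP).
#' @export
ceac <- function(draws, wtp_grid = seq(0, 600000, by = 2500)) {
  if (length(wtp_grid) == 0) stop_input("wtp_grid is empty")
  p <- acceptance_probability(draws, wtp_grid)
  structure(data.frame(wtp = wtp_grid, p_treatment = p, p_control = 1 - p),
            class = c("ceac", "data.frame"))
}

#' WTP at which the acceptability curves cross
#'
#' Linear interpolation of the treatment curve through probability 0.5
#' (the point where both strategies are equally likely to be
#' cost-effective).  If the curve never reaches 0.5 on the grid the
#' result is `NA` with attribute `crossed = FALSE`.
#'
#' @param curves A [ceac()] result.
#' @return WTP in CNY/QALY (scalar, possibly `NA`), attribute `crossed`.
#' @export
ceac_crossing <- function(curves) {
  stopifnot(inherits(curves, "ceac"))
  p <- curves$p_treatment; w <- curves$wtp
  at <- which(p >= 0.5)
  if (length(at) == 0) return(structure(NA_real_, crossed = FALSE))
  i <- at[1]
  if (i == 1 || p[i] == 0.5)
    return(structure(w[i], crossed = TRUE))
  w_cross <- w[i - 1] + (0.5 - p[i - 1]) / (p[i] - p[i - 1]) * (w[i] - w[i - 1])
  structure(w_cross, crossed = TRUE)
}
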