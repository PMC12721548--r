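# shared fixtures; everything is generated in code

# the packaged parameter table, read once per test run
fx <- fixture_parameter_table()

table2_dists <- function() fx$survival

# a copy of the table with selected rows (default: all) collapsed to
# zero-width bounds, for degenerate-sensitivity checks
degenerate_params <- function(params = fx, names = NULL) {
  tab <- params$parameters
  i <- if (is.null(names)) seq_len(nrow(tab)) else match(names, tab$name)
  tab$min[i] <- tab$base[i]
  tab$max[i] <- tab$base[i]
  params$parameters <- tab
  params
}

# continuous-time discounted-QALY integral, the quadrature oracle for the
# cycle-sum accrual
qaly_integral <- function(pfs, os, settings, u_pfs = 0.673, u_pd = 0.473,
                          upper = NULL) {
  if (is.null(upper))
    upper <- (settings$n_cycles + 1) * settings$cycle_months
  f <- function(t) {
    sp <- surv_prob(pfs, t); so <- surv_prob(os, t)
    occ_p <- pmin(sp, so)
    (1 + settings$annual_discount)^(-t / 12) *
      (u_pfs * occ_p + u_pd * (so - occ_p))
  }
  stats::integrate(f, 0, upper, rel.tol = 1e-10, subdivisions = 2000L)$value / 12
}
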