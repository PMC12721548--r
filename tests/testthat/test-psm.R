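# partitioned-survival trace and reward accrual

test_that("trace occupancies are conserved and monotone for both fitted arms", {
  st <- model_settings()
  expect_equal(st$n_cycles, 173)
  for (arm in c("treatment", "control")) {
    sv <- table2_dists()[[arm]]
    tr <- build_trace(sv$pfs, sv$os, st)
    expect_equal(nrow(tr), 174)
    expect_true(all(abs(tr$pfs + tr$pd + tr$death - 1) <= 1e-12))
    expect_true(all(diff(tr$pfs) <= 0))
    expect_true(all(diff(tr$pfs + tr$pd) <= 0))
    expect_true(all(diff(tr$death) >= 0))
    expect_true(all(tr$pfs >= 0 & tr$pd >= 0 & tr$death >= 0))
    expect_equal(unlist(tr[1, c("pfs", "pd", "death", "discount")]),
                 c(pfs = 1, pd = 0, death = 0, discount = 1))
  }
})

test_that("death occupancy is 0.5 at the OS median", {
  sv <- table2_dists()$treatment
  st <- model_settings()
  tr <- build_trace(sv$pfs, sv$os, st)
  # the OS median (= log-logistic scale) is not on the cycle grid; check
  # the continuous definition directly and the grid bracketing
  expect_equal(1 - surv_prob(sv$os, 13.97048), 0.5, tolerance = 1e-9)
  below <- max(which(tr$time_months <= 13.97048))
  expect_lt(tr$death[below], 0.5)
  expect_gt(tr$death[below + 1], 0.5)
})

test_that("PFS/OS crossings are clipped so PD occupancy stays non-negative", {
  pfs <- surv_dist("exponential", 0.05)   # slower than OS: guaranteed crossing
  os <- surv_dist("exponential", 0.10)
  tr <- build_trace(pfs, os, model_settings())
  expect_true(all(tr$pd >= 0))
  expect_gt(attr(tr, "n_clipped"), 0)
  expect_true(all(abs(tr$pfs + tr$pd + tr$death - 1) <= 1e-12))
})

test_that("discounted QALY accrual agrees with the continuous-time integral", {
  st <- model_settings()
  for (arm in c("treatment", "control")) {
    sv <- table2_dists()[[arm]]
    tr <- build_trace(sv$pfs, sv$os, st)
    q_sum <- accumulate_qalys(tr, utility_set())
    q_int <- qaly_integral(sv$pfs, sv$os, st)
    # cycle-start evaluation of a decreasing integrand overestimates the
    # integral by at most one cycle's contribution
    expect_gte(q_sum, q_int)
    expect_lte(q_sum - q_int, 0.673 * st$cycle_months / 12)
  }
})

test_that("QALYs reduce to the restricted mean for unit utilities, no discounting", {
  os <- surv_dist("exponential", 0.08)
  st <- model_settings(annual_discount = 0)
  tr <- build_trace(os, os, st)   # PFS = OS: everyone alive is progression-free
  ly <- accumulate_qalys(tr, list(u_pfs = 1, u_pd = 1))
  rm_years <- restricted_mean(os, (st$n_cycles + 1) * st$cycle_months) / 12
  expect_lte(abs(ly - rm_years), st$cycle_months / 12)
  expect_equal(ly, accumulate_life_years(tr))
  expect_equal(accumulate_qalys(tr, list(u_pfs = 0, u_pd = 0)), 0)
})

test_that("refining the cycle length converges to the integral", {
  sv <- table2_dists()$treatment
  err <- sapply(c(21, 7, 1), function(cd) {
    st <- model_settings(cycle_days = cd)
    q <- accumulate_qalys(build_trace(sv$pfs, sv$os, st), utility_set())
    abs(q - qaly_integral(sv$pfs, sv$os, st))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("removing discounting strictly increases QALYs and costs", {
  sv <- table2_dists()$treatment
  sch <- cost_schedule(pfs_cost = 500, pd_cost = 3115, one_off = 0)
  res <- lapply(c(0.05, 0), function(r) {
    st <- model_settings(annual_discount = r)
    tr <- build_trace(sv$pfs, sv$os, st)
    c(q = accumulate_qalys(tr, utility_set()), c = accumulate_costs(tr, sch))
  })
  expect_gt(res[[2]]["q"], res[[1]]["q"])
  expect_gt(res[[2]]["c"], res[[1]]["c"])
})

test_that("half-cycle correction lowers accrual and is applied consistently", {
  sv <- table2_dists()$treatment
  st_on <- model_settings(half_cycle_correction = TRUE)
  tr <- build_trace(sv$pfs, sv$os, model_settings())
  tr_on <- build_trace(sv$pfs, sv$os, st_on)
  q_off <- accumulate_qalys(tr, utility_set())
  q_on <- accumulate_qalys(tr_on, utility_set())
  expect_lt(q_on, q_off)
  expect_lt(abs(q_on - q_off), 0.673 * st_on$cycle_months / 12)
})

test_that("cost accrual is linear in the schedule and honours one-off costs", {
  sv <- table2_dists()$control
  tr <- build_trace(sv$pfs, sv$os, model_settings(annual_discount = 0))
  expect_equal(accumulate_costs(tr, cost_schedule()), 0)
  # constant PD cost: total = unit cost x sum of PD occupancies
  c_pd <- accumulate_costs(tr, cost_schedule(pd_cost = 3115))
  expect_equal(c_pd, 3115 * sum(tr$pd))
  expect_equal(accumulate_costs(tr, cost_schedule(one_off = 100)), 100)
  expect_error(accumulate_costs(tr, list(pfs_cost = c(1, 2, 3), pd_cost = 0,
                                         one_off = 0)), "length")
})

test_that("settings validation rejects out-of-range inputs", {
  expect_error(model_settings(cycle_days = 0), "> 0")
  expect_error(model_settings(annual_discount = 0.2), "\\[0, 0.08\\]")
  expect_error(utility_set(0.4, 0.6), "u_pd <= u_pfs")
  s <- model_settings(cycle_days = 21, horizon_years = 0.5)
  expect_equal(s$n_cycles, 8)
})
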