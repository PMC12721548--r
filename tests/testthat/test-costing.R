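# dosing rules, adverse-event costs, per-arm cost schedules, calibration

test_that("dosing rules reproduce the trial's doses for the base profile", {
  pp <- patient_profile()
  expect_equal(compute_dose("per_kg", 5, pp), 295)        # socazolimab, mg
  expect_equal(compute_dose("calvert", 5, pp), 575)       # carboplatin, mg
  expect_equal(compute_dose("per_m2", 100, pp), 172)      # etoposide, mg/day
  expect_equal(3 * compute_dose("per_m2", 100, pp), 516)  # 3-day cycle total
  expect_error(compute_dose("per_kg", -5, pp), "positive")
  expect_error(patient_profile(weight = 0), "> 0")
})

test_that("adverse-event cost is the incidence-weighted sum of unit costs", {
  expect_equal(adverse_event_cost(c(0, 0, 0), c(100, 200, 300)), 0)
  expect_equal(adverse_event_cost(1, 822.89), 822.89)
  v <- param_values(fx)
  expected <- 0.691 * 2877.40 + 0.442 * 2309.99 + 0.233 * 1235.30 + 0.337 * 822.89
  expect_equal(psmcea:::arm_ae_cost(v, "treatment"), expected)
  expected_c <- 0.668 * 2877.40 + 0.340 * 2309.99 + 0.206 * 1235.30 + 0.279 * 822.89
  expect_equal(psmcea:::arm_ae_cost(v, "control"), expected_c)
  expect_error(adverse_event_cost(c(0.5, 1.2), c(1, 1)), "\\[0, 1\\]")
})

test_that("cost schedules follow the per-state accrual rules", {
  v <- param_values(fx)
  st <- model_settings()
  ctl <- build_cost_schedule("control", v, st)
  # beyond the 4 chemotherapy cycles, PFS cost is monitoring only
  expect_equal(ctl$pfs_cost[7], 166 + 300)
  # PD cost is BSC + monitoring in every cycle
  expect_true(all(ctl$pd_cost == 3115 + 466))
  # chemotherapy in the first four cycles only
  chemo <- 516 * 3.16 + 575 * 0.61
  expect_equal(ctl$pfs_cost[1:4], rep(466 + chemo, 4))
  expect_equal(length(ctl$pfs_cost), st$n_cycles + 1)

  trt <- build_cost_schedule("treatment", v, st, soca_mode = "protocol")
  # protocol mode: socazolimab while progression-free, cycle 2 included
  expect_equal(trt$pfs_cost[2], 295 * 115 + 516 * 3.16 + 575 * 0.61 + 466)
  # the 2-year cap: 34 dosing cycles, none afterwards
  expect_equal(trt$pfs_cost[35], 466)
  expect_equal(trt$pfs_cost[34], 466 + 295 * 115)
  # control arm never carries socazolimab cost
  expect_true(all(ctl$pfs_cost <= max(466 + chemo)))
  expect_equal(sum(trt$pfs_cost) - sum(ctl$pfs_cost), 34 * 295 * 115)
})

test_that("calibrated mode books socazolimab as a scaled one-off", {
  v <- param_values(fx)
  st <- model_settings()
  cal <- list(total = 43232.73, ref_price = 115, ref_weight = 59)
  trt <- build_cost_schedule("treatment", v, st, "calibrated", cal)
  ctl <- build_cost_schedule("control", v, st, "calibrated", cal)
  expect_equal(trt$pfs_cost, ctl$pfs_cost)   # no per-cycle drug difference
  expect_equal(trt$one_off - psmcea:::arm_ae_cost(v, "treatment"), 43232.73)
  # the one-off scales linearly with unit price and weight
  v2 <- v; v2$cost_socazolimab_mg <- 92; v2$weight_kg <- 70.8
  trt2 <- build_cost_schedule("treatment", v2, st, "calibrated", cal)
  expect_equal(trt2$one_off - psmcea:::arm_ae_cost(v2, "treatment"),
               43232.73 * (92 / 115) * (70.8 / 59))
  expect_error(build_cost_schedule("treatment", v, st, "calibrated", NULL),
               "soca_calibration")
})

test_that("total arm cost is homogeneous of degree 1 in unit prices", {
  v <- param_values(fx)
  st <- model_settings()
  sv <- table2_dists()$treatment
  tr <- build_trace(sv$pfs, sv$os, st)
  cal <- list(total = 43232.73, ref_price = 115, ref_weight = 59)
  cost1 <- accumulate_costs(tr, build_cost_schedule("treatment", v, st,
                                                    "calibrated", cal))
  v2 <- v
  price_names <- grep("^cost_", names(v), value = TRUE)
  for (nm in price_names) v2[[nm]] <- 2 * v2[[nm]]
  cal2 <- list(total = 2 * cal$total, ref_price = 2 * 115, ref_weight = 59)
  cost2 <- accumulate_costs(tr, build_cost_schedule("treatment", v2, st,
                                                    "calibrated", cal2))
  expect_equal(cost2, 2 * cost1, tolerance = 1e-12)
})

test_that("socazolimab calibration recovers the slope of incremental cost on price", {
  two <- data.frame(fraction = c(1.0, 0.7),
                    incremental_cost = c(74616.56, 61646.74))
  expect_equal(calibrate_socazolimab(two), (74616.56 - 61646.74) / 0.3,
               tolerance = 1e-12)
  flat <- data.frame(fraction = c(1.0, 0.5), incremental_cost = c(5, 5))
  expect_equal(calibrate_socazolimab(flat), 0)
  # the published price-simulation rows are collinear: least squares over
  # all rows agrees with the two-point slope within 1 CNY
  all_rows <- fx$reference$price_rows
  expect_lt(abs(calibrate_socazolimab(all_rows) - 43232.73), 1)
  same <- data.frame(fraction = c(0.7, 0.7), incremental_cost = c(1, 2))
  expect_error(calibrate_socazolimab(same), "distinct")
})
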