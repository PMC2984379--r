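risks_low <- mortality_risks(1.77, 2.11)
risks_high <- mortality_risks(1.00, 4.08)

test_that("nondiabetic death rate back-calculation matches census deaths", {
  expect_equal(back_calculate_gamma(0.01, 1000, 900, 50, 50,
                                    mortality_risks(1, 1)), 0.01)
  # hand arithmetic: 10 / (900 + 1.77*50 + 2.11*50)
  g <- back_calculate_gamma(0.01, 1000, 900, 50, 50, risks_low)
  expect_equal(g, 10 / (900 + 88.5 + 105.5), tolerance = 1e-12)
  expect_equal(g, 0.0091408, tolerance = 1e-5)
  # all-nondiabetic limit
  expect_equal(back_calculate_gamma(0.02, 500, 500, 0, 0, risks_low), 0.02)
  expect_error(back_calculate_gamma(0.9, 100, 10, 10, 80, risks_high),
               class = "mortality_overflow")
})

test_that("transition rows are probability vectors with no remission", {
  id <- build_transition_row("X", 0, 0, 0.04, 0.08, risks_low)
  expect_equal(id, c(X = 1, Z = 0, Y = 0, dead = 0))
  ry <- build_transition_row("Y", 0.01, 0.1, 0.04, 0.08, risks_low)
  expect_equal(ry, c(X = 0, Z = 0, Y = 1 - 2.11 * 0.01, dead = 2.11 * 0.01))
  rx <- build_transition_row("X", 0.008, 0.09, 0.04, 0.08, risks_low)
  expect_equal(rx[["Z"]], 0.08 * 0.09)
  expect_equal(rx[["Y"]], 0.04 * 0.09)
  expect_equal(sum(rx), 1, tolerance = 1e-15)
  expect_error(build_transition_row("Z", 0.3, 0.9, 0.1, 0.1, risks_high),
               class = "infeasible_rates")
})

test_that("every transition row over a full run is valid", {
  us <- us_fixture()
  tr <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  for (k in 2:nrow(tr)) {
    for (stt in c("X", "Z", "Y")) {
      row <- build_transition_row(stt, tr$gamma[k], tr$beta[k],
                                  us$calib$xi1, us$calib$xi2, risks_low)
      expect_true(all(row >= 0 & row <= 1))
      expect_equal(sum(row), 1, tolerance = 1e-12)
    }
  }
})

test_that("single-year step does the expected arithmetic", {
  cal1 <- us_fixture()$calib
  # closed population, zero rates: state unchanged
  st <- step_three_state(c(X = 800, Z = 100, Y = 100), b = 0, m = 0, d = 0,
                         i_t = 0, calib = cal1, risks = risks_low)
  expect_equal(st$state, c(X = 800, Z = 100, Y = 100))
  expect_equal(unname(st$flows["incident_total"]), 0)

  # all-diagnosed onset (eta = 1): 1% of X moves straight to Y
  cal_eta1 <- cal1
  cal_eta1$xi1 <- 1; cal_eta1$xi2 <- 0; cal_eta1$eta <- 1
  st <- step_three_state(c(X = 1000, Z = 0, Y = 0), b = 0, m = 0, d = 0,
                         i_t = 0.01, calib = cal_eta1, risks = risks_low)
  expect_equal(st$state, c(X = 990, Z = 0, Y = 10))
})

test_that("trajectories conserve population and deaths exactly", {
  us <- us_fixture()
  for (risks in list(risks_low, risks_high)) {
    tr <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks)
    expect_rel_equal(tr$X + tr$Z + tr$Y, us$census$N, 1e-9)
    expect_rel_equal(tr$deaths[-1],
                     us$census$d[-1] * tr$N[-nrow(tr)], 1e-9)
    expect_true(all(tr[, c("X", "Z", "Y")] >= 0))
    expect_equal(tr$theta, tr$theta1 + tr$theta2, tolerance = 1e-12)
  }
})

test_that("diagnosed burden responds monotonically to incidence and mortality", {
  us <- us_fixture()
  lower <- us$scenario; lower$rate <- lower$rate * 0.85
  tr_mid <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  tr_low <- run_three_state(us$state0, us$census, lower, us$calib, risks_low)
  expect_true(all(tr_mid$Y[-1] >= tr_low$Y[-1]))
  expect_true(all(tr_mid$theta2[-1] >= tr_low$theta2[-1]))

  # lower diagnosed mortality (r2 = 2.11 vs 4.08) retains more cases
  tr_hr <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks_high)
  expect_gt(tr_mid$Y[tr_mid$year == 2050], tr_hr$Y[tr_hr$year == 2050])
})

test_that("zero incidence leaves the diagnosed pool decaying in a closed population", {
  us <- us_fixture()
  cen <- generate_census(2007, 2030, 1e6,
                         list(d = 0.01, b = 12000, m = 0))
  st0 <- generate_initial_state(1e6, 0.05, 0.09)
  zero <- data.frame(year = 2008:2030, rate = 0)
  tr <- run_three_state(st0, cen, zero, us$calib, risks_low)
  expect_true(all(diff(tr$Y) < 0))
  expect_true(all(diff(tr$Z) < 0))
})

test_that("four-state marginals reproduce the three-state trajectory", {
  us <- us_fixture()
  tr3 <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  tr4 <- run_four_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  expect_rel_equal(tr4$X, tr3$X, 1e-9)
  expect_rel_equal(tr4$Z, tr3$Z, 1e-9)
  expect_rel_equal(tr4$Y, tr3$Y, 1e-9)
  # high-risk share pinned every year
  expect_equal(tr4$p_t, rep(us$calib$p28, nrow(tr4)), tolerance = 1e-12)
  # all strata nonnegative, total matches census
  expect_true(all(tr4[, c("IX", "LX", "LXI", "Z", "Y")] >= 0))
  expect_rel_equal(tr4$N, us$census$N, 1e-9)
})

test_that("four-state run reproduces the published base-year stratum rates", {
  us <- us_fixture()
  # scenario whose 2008 diagnosed incidence equals the calibration value
  scen <- us$scenario
  scen$rate[1] <- us$calib$i29
  tr4 <- run_four_state(us$state0, us$census, scen, us$calib, risks_low)
  expect_equal(round_half_up(tr4$lambda_high[2], 4), 0.0287)
  # high-risk retention probability alpha1(2008) near the published 0.89
  expect_equal(round_half_up(tr4$alpha1[2], 2), 0.90, tolerance = 0.011)
})

test_that("homogeneous-risk split leaves no net inter-strata correction", {
  us <- us_fixture()
  t_a <- run_four_state(us$state0, us$census, us$scenario, us$calib, risks_low,
                        strata = list(p = 0.257, c = 1, q = 1))
  t_b <- run_four_state(us$state0, us$census, us$scenario, us$calib, risks_low,
                        strata = list(p = 0.257, c = 1, q = 0.93))
  # with equal stratum incidences the q-retention flows net out exactly
  expect_equal(t_a$IX, t_b$IX, tolerance = 1e-12)
  expect_equal(t_a$IX / t_a$X, rep(0.257, nrow(t_a)), tolerance = 1e-12)
})

test_that("null intervention reproduces the four-state model exactly", {
  us <- us_fixture()
  tr4 <- run_four_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  tr5 <- run_five_state(us$state0, us$census, us$scenario, us$calib, risks_low,
                        intervention = list(nu = 0, regression_rate = 0))
  for (cl in c("IX", "LX", "LXI", "Z", "Y", "incident_total")) {
    expect_equal(tr5[[cl]], tr4[[cl]], tolerance = 1e-12)
  }
})

test_that("intervention reduces incident cases by the analytic first-year share", {
  us <- us_fixture()
  tr3 <- run_three_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  tr5 <- run_five_state(us$state0, us$census, us$scenario, us$calib, risks_low)
  dd <- incident_case_difference(tr3, tr5)
  expect_true(all(dd$difference[-1] > 0))

  # first projected year: prevented share is exactly nu * p * c/(p c + 1 - p)
  cal <- us$calib
  share <- cal$nu * cal$p28 * cal$c / (cal$p28 * cal$c + 1 - cal$p28)
  expect_equal(dd$difference[2] / dd$base[2], share, tolerance = 1e-9)
  # a few years in, the prevented fraction stays in the expected band
  frac10 <- dd$difference[dd$year == 2010] / dd$base[dd$year == 2010]
  expect_gt(frac10, 0.15); expect_lt(frac10, 0.19)

  expect_equal(incident_case_difference(tr3, tr3)$difference,
               rep(c(NA, 0), c(1, nrow(tr3) - 1)))
  expect_error(incident_case_difference(tr3, tr5[-2, ]),
               class = "invalid_argument")
})

test_that("risk regression routes intervention participants to LXI", {
  us <- us_fixture()
  tr5 <- run_five_state(us$state0, us$census, us$scenario, us$calib, risks_low,
                        intervention = list(nu = 0.25, regression_rate = 0.02))
  expect_equal(tr5$LXI[1], 0) # starts empty
  expect_true(all(tr5$LXI[-1] > 0))
  expect_rel_equal(tr5$N, us$census$N, 1e-9)
  base <- run_five_state(us$state0, us$census, us$scenario, us$calib, risks_low,
                         intervention = list(nu = 0.25, regression_rate = 0))
  expect_true(all(tr5$LXI[-1] > base$LXI[-1]))
})
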