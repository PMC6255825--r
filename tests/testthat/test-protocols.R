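# In-silico protocols: access-resistance scan, space-clamp bias, network
# event simulation and the charge calibration.

surrogate_model <- function(seed = 1, ...) {
  cable_model(make_surrogate_morphology(seed = seed, ...))
}

test_that("ramp-determined reversal matches the two-branch analytic value", {
  cmod <- surrogate_model(1)
  # synapse at the soma, low access resistance: the determined reversal is
  # the conductance-weighted mean of the branch Nernst potentials
  r <- run_rs_experiment(cmod, rs_list = 5, site = 0L, cl_i = 30,
                         hco3_i = 14.4)
  analytic <- (nernst(30, 133.5) + 0.44 * nernst(14.4, 24)) / 1.44
  expect_identical(nrow(r), 1L)
  expect_lt(abs(r$egaba - analytic), 0.5)
})

test_that("the reversal determination is insensitive to access resistance", {
  cmod <- surrogate_model(1)
  r <- run_rs_experiment(cmod)
  expect_identical(nrow(r), 5L)
  expect_lt(max(r$egaba) - min(r$egaba), 0.5)
  # proximal-site determination stays within 1 mV of the analytic
  # conductance-weighted reversal
  analytic <- (nernst(30, 133.5) + 0.44 * nernst(14.4, 24)) / 1.44
  expect_lt(max(abs(r$egaba - analytic)), 1)
})

test_that("space-clamp bias has the observed structure at both chloride levels", {
  cmod <- surrogate_model(1)
  hi <- run_spaceclamp_experiment(cmod, cl_i = 50)
  lo <- run_spaceclamp_experiment(cmod, cl_i = 10)
  expect_true(all(diff(hi$cl_apparent) > 0)) # overestimation grows distally
  expect_true(all(diff(lo$cl_apparent) < 0)) # underestimation grows distally
  # the proximal site is the least biased in the high-chloride case, and its
  # residual offset is the structural one: the ramp measures the
  # conductance-weighted reversal while the inversion assumes the GHK form
  e_star <- function(cl) (nernst(cl, 133.5) + 0.44 * nernst(14.4, 24)) / 1.44
  struct_hi <- cl_from_egaba(e_star(50), hco3_i = 14.4)
  struct_lo <- cl_from_egaba(e_star(10), hco3_i = 14.4)
  expect_equal(hi$cl_apparent[1], struct_hi, tolerance = 0.03)
  expect_equal(lo$cl_apparent[1], struct_lo, tolerance = 0.03)
  expect_true(which.min(abs(hi$cl_apparent - 50)) == 1L)
})

test_that("zero synapses leave the concentrations flat", {
  cmod <- surrogate_model(1)
  g <- run_gdp_simulation(cmod, gdp_stimulus(n_gaba = 0, n_ampa = 0),
                          cl_init = 30, post = 500)
  expect_lt(abs(g$delta_cl), 1e-9)
  expect_lt(abs(g$delta_hco3), 1e-9)
})

test_that("the event stimulus drives chloride toward its reversal", {
  cmod <- surrogate_model(1)
  g10 <- run_gdp_simulation(cmod, gdp_stimulus(seed = 7), cl_init = 10,
                            post = 2500)
  g50 <- run_gdp_simulation(cmod, gdp_stimulus(seed = 7), cl_init = 50,
                            post = 2500)
  expect_gt(g10$delta_cl, 0) # influx at low internal chloride
  expect_lt(g50$delta_cl, 0) # efflux at high internal chloride
  expect_lt(g10$delta_hco3, 0) # bicarbonate is always lost
  expect_lt(g50$delta_hco3, 0)
  # identical seeds reproduce identically
  g10b <- run_gdp_simulation(cmod, gdp_stimulus(seed = 7), cl_init = 10,
                             post = 2500)
  expect_identical(g10$delta_cl, g10b$delta_cl)
  # tidy/glance interfaces
  expect_identical(nrow(glance(g10)), 1L)
  expect_true(all(c("time_ms", "variable", "value") %in% names(tidy(g10))))
})

test_that("charge calibration scales the synapse count to target", {
  cmod <- surrogate_model(1)
  stim <- gdp_stimulus(n_gaba = 60, seed = 3)
  # trivial target
  z <- calibrate_gdp_charge(cmod, stim, target_charge = 0)
  expect_identical(z$stim$n_gaba, 0L)
  # a reachable target is met within 5%
  cal <- calibrate_gdp_charge(cmod, stim, target_charge = 30)
  expect_lt(abs(cal$charge - 30) / 30, 0.05)
  # doubling the unitary conductance roughly halves the calibrated count
  stim2 <- stim
  stim2$g_gaba <- 2 * stim$g_gaba
  cal2 <- calibrate_gdp_charge(cmod, stim2, target_charge = 30)
  expect_lt(abs(cal2$stim$n_gaba - cal$stim$n_gaba / 2),
            max(2, 0.2 * cal$stim$n_gaba / 2))
})
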