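# Cable discretization, the split GABA current, and the coupled
# voltage/ion solver checked against conservation and closed-form oracles.

test_that("discretization preserves area and volume partitions", {
  # single cylinder 100 um x 2 um: lateral area 2 pi r L
  cyl <- morphology(tibble::tibble(
    id = 1:2, parent_id = c(NA, 1L), parent_pos = c(NA, 1),
    length = c(15, 100), diam_prox = c(15, 2), diam_dist = c(15, 2),
    region = c("soma", "dendrite")
  ))
  cm1 <- cable_model(cyl, nseg = 1)
  dend <- cm1$segments$region == "dendrite"
  expect_equal(sum(cm1$segments$area[dend]), 2 * pi * 1 * 100, tolerance = 1e-12)
  # shell volumes partition the cytoplasm exactly
  expect_equal(sum(cm1$shell_vol), sum(pi * (cm1$segments$diam / 2)^2 *
                                         cm1$segments$length), tolerance = 1e-12)
  # d_lambda refinement: more segments, same area
  m <- make_surrogate_morphology(seed = 2)
  c_a <- cable_model(m, d_lambda = 0.1)
  c_b <- cable_model(m, d_lambda = 0.05)
  expect_gt(nrow(c_b$segments), nrow(c_a$segments))
  expect_equal(sum(c_b$segments$area), sum(c_a$segments$area), tolerance = 1e-9)
  # volumes agree up to the O(1/nseg^2) center-diameter quadrature of tapers
  expect_equal(sum(c_b$shell_vol), sum(c_a$shell_vol), tolerance = 1e-3)
  # segment counts are odd per section
  expect_true(all(table(c_a$segments$section_id) %% 2 == 1))
})

test_that("the split GABA current matches its defining equation", {
  expect_identical(gaba_current(-40, 1, -40, -40, 0.44)$i_total, 0)
  z <- gaba_current(-40, 2, -55, -10, p = 0)
  expect_identical(z$i_hco3, 0)
  expect_equal(z$i_cl, 2 * (-40 + 55))
  g <- gaba_current(0, 1, -57.3, -13.9, 0.44)
  expect_equal(g$i_cl, 57.3 / 1.44, tolerance = 1e-12)
  expect_equal(g$i_hco3, 0.44 * 13.9 / 1.44, tolerance = 1e-12)
  expect_equal(g$i_total, g$i_cl + g$i_hco3)
})

test_that("a quiescent model is an exact fixed point", {
  cmod <- cable_model(ball_stick_morphology())
  sim <- simulate_cable(cmod, duration = 1000,
                        ions = ion_dynamics(cl_init = 30))
  expect_lt(max(abs(sim$v_soma - (-53))), 1e-9)
  expect_lt(max(abs(sim$cl_dend - 30)), 1e-9)
  expect_lt(max(abs(sim$hco3_dend - 14.1)), 1e-9)
})

test_that("chloride mass balances the integrated synaptic current", {
  # sealed single compartment, transport off, one GABA pulse under a
  # near-ideal somatic clamp: delta(moles) must equal int i_cl dt / F
  cmod <- cable_model(soma_only_morphology())
  ions <- ion_dynamics(cl_init = 10, transport = FALSE)
  syn <- synapse(0, "gaba", g_peak = 2, onset = 50)
  sim <- simulate_cable(cmod, duration = 600, dt = 0.025, synapses = syn,
                        clamp = sevc_clamp(0.5, 0), ions = ions,
                        record_dt = 0.1)
  st0 <- matrix(10, 1, 5)
  d_moles <- total_moles(cmod, attr(sim, "state"), "cl") -
    sum(cmod$shell_vol * st0) # mM um^3
  q_pAms <- sum(diff(sim$time_ms) * (head(sim$i_cl_total, -1) +
                                       tail(sim$i_cl_total, -1)) / 2)
  expect_equal(d_moles, q_pAms * 1000 / 96485, tolerance = 0.005)
  expect_gt(d_moles, 0) # influx at 0 mV with low internal chloride
})

test_that("transport relaxes concentrations with the bimodal time constants", {
  cmod <- cable_model(ball_stick_morphology())
  # uptake: start 10 mM below rest, tau 174 s
  ions <- ion_dynamics(cl_init = 20, cl_rest = 30, hco3_init = 14.1,
                       longitudinal = FALSE)
  sim <- simulate_cable(cmod, duration = 60e3, dt = 10, ions = ions,
                        record_dt = 1000)
  dev <- 30 - sim$cl_dend
  tau_up <- -(sim$time_ms[31] - sim$time_ms[1]) /
    log(dev[31] / dev[1]) / 1000
  expect_equal(tau_up, 174, tolerance = 0.02)
  # extrusion: start above rest, tau 321 s
  ions2 <- ion_dynamics(cl_init = 40, cl_rest = 30, longitudinal = FALSE)
  sim2 <- simulate_cable(cmod, duration = 60e3, dt = 10, ions = ions2,
                         record_dt = 1000)
  dev2 <- sim2$cl_dend - 30
  tau_ex <- -(sim2$time_ms[31] - sim2$time_ms[1]) /
    log(dev2[31] / dev2[1]) / 1000
  expect_equal(tau_ex, 321, tolerance = 0.02)
})

test_that("diffusion conserves mass and equilibrates gradients", {
  cmod <- cable_model(two_branch_morphology(len = 50))
  nseg <- nrow(cmod$segments)
  set.seed(11)
  cl0 <- runif(nseg, 5, 60)
  ions <- ion_dynamics(cl_init = cl0, hco3_init = 14.1, transport = FALSE)
  sim <- simulate_cable(cmod, duration = 10e3, dt = 0.5, ions = ions,
                        record_dt = 100)
  m0 <- sum(cmod$shell_vol * matrix(cl0, nseg, cmod$n_shells))
  m1 <- total_moles(cmod, attr(sim, "state"), "cl")
  expect_lt(abs(m1 - m0) / m0, 1e-6)
  # profile relaxes toward uniform
  cl_fin <- attr(sim, "state")$cl
  expect_lt(max(cl_fin) - min(cl_fin), 0.1 * (max(cl0) - min(cl0)))
  # and the uniform profile is the conserved mean
  expect_equal(mean(range(cl_fin)), m0 / sum(cmod$shell_vol), tolerance = 0.05)
})

test_that("the single-electrode clamp follows the voltage-divider law", {
  cmod <- cable_model(ball_stick_morphology())
  rin_MOhm <- input_resistance(cmod) * 1000
  step <- 20 # mV above rest
  for (rs in c(0.5, 40)) {
    sim <- simulate_cable(cmod, duration = 400, dt = 0.025,
                          clamp = sevc_clamp(rs, -53 + step),
                          ions = ion_dynamics(cl_init = 30, dynamic = FALSE))
    err <- (-53 + step) - tail(sim$v_soma, 1)
    expect_equal(err, step * rs / (rs + rin_MOhm), tolerance = 0.01)
  }
  # rs 0.5 on this cell: soma within 0.3 mV of command at steady state
  sim <- simulate_cable(cmod, duration = 400,
                        clamp = sevc_clamp(0.5, -33),
                        ions = ion_dynamics(cl_init = 30, dynamic = FALSE))
  expect_lt(abs(tail(sim$v_soma, 1) - (-33)), 0.3)
  # zero command step on a resting cell: no clamp current
  sim0 <- simulate_cable(cmod, duration = 100, clamp = sevc_clamp(1, -53),
                         ions = ion_dynamics(cl_init = 30, dynamic = FALSE))
  expect_lt(max(abs(sim0$i_clamp)), 1e-6)
  expect_error(sevc_clamp(0, -60), class = "chloridyn_config_error")
})

test_that("mean dendritic concentration is the volume-weighted mean", {
  cmod <- cable_model(two_branch_morphology(len = 80, d1 = 1, d2 = 1))
  segs <- cmod$segments
  # equal-volume branches at 10 and 50 average to 30
  cl <- ifelse(segs$section_id == 2, 10, ifelse(segs$section_id == 3, 50, 33))
  state <- matrix(cl, nrow(segs), cmod$n_shells)
  expect_equal(mean_dendritic_concentration(cmod, state, "cl"), 30)
  # uniform field is reproduced exactly
  expect_identical(mean_dendritic_concentration(
    cmod, matrix(30, nrow(segs), cmod$n_shells), "cl"), 30)
  # random state: agrees with a brute-force sum over shells
  set.seed(5)
  rnd <- matrix(runif(nrow(segs) * cmod$n_shells, 5, 50),
                nrow(segs), cmod$n_shells)
  dend <- segs$region == "dendrite"
  brute <- sum(cmod$shell_vol[dend, ] * rnd[dend, ]) / sum(cmod$shell_vol[dend, ])
  expect_equal(mean_dendritic_concentration(cmod, rnd, "cl"), brute,
               tolerance = 1e-12)
})

test_that("passive behaviour matches measured immature-cell ranges", {
  # with a membrane resistivity consistent with the recorded input
  # resistances (R_in ~ Rm / area), the surrogate reproduces the reported
  # R_in and membrane time constant
  m <- make_surrogate_morphology(target_capacitance = 65, seed = 2)
  cmod <- cable_model(m, passive_params(rm = 100, e_leak = -53))
  rin <- input_resistance(cmod)
  expect_gt(rin, 0.9)
  expect_lt(rin, 1.75)
  # time constant from the voltage decay after a current step
  inj <- function(t) ifelse(t < 1000, 10, 0)
  sim <- simulate_cable(cmod, duration = 1600, clamp = current_clamp(inj),
                        ions = ion_dynamics(cl_init = 30, dynamic = FALSE))
  dec <- sim[sim$time_ms > 1050 & sim$time_ms < 1350, ]
  tau <- -1 / coef(lm(log(dec$v_soma + 53) ~ dec$time_ms))[2]
  expect_gt(tau, 86)
  expect_lt(tau, 106)
})

test_that("grid refinement leaves the event-driven chloride shift stable", {
  m <- ball_stick_morphology(len = 150, diam = 0.8)
  base <- cable_model(m, n_shells = 5)
  fine <- cable_model(m, n_shells = 10)
  syn <- dplyr::bind_rows(purrr::map(
    seq(0, 0.9, length.out = 10),
    function(p) synapse(seg_at(base, section = 2, pos = p), "gaba",
                        g_peak = 0.789, onset = 100 + 400 * p)
  ))
  syn_f <- syn
  syn_f$seg <- vapply(seq_len(nrow(syn)), function(i)
    seg_at(fine, section = 2, pos = (i - 1) / 9 * 0.9), integer(1))
  ions <- ion_dynamics(cl_init = 10, cl_rest = 10)
  run <- function(cmod, s, dt) {
    sim <- simulate_cable(cmod, duration = 1500, dt = dt, synapses = s,
                          ions = ions)
    max(sim$cl_dend) - 10
  }
  d_base <- run(base, syn, 0.025)
  d_dt <- run(base, syn, 0.0125)
  d_sh <- run(fine, syn_f, 0.025)
  expect_lt(abs(d_dt - d_base) / d_base, 0.02)
  expect_lt(abs(d_sh - d_base) / d_base, 0.02)
})

test_that("input validation rejects malformed simulations", {
  cmod <- cable_model(soma_only_morphology())
  expect_error(simulate_cable(cmod, 10, synapses = synapse(99L, "gaba", 1)),
               class = "chloridyn_invalid_parameter")
  expect_error(simulate_cable(cmod, 10, ions = ion_dynamics(cl_init = -5)),
               class = "chloridyn_invalid_parameter")
  expect_error(ion_dynamics(tau_uptake = -1),
               class = "chloridyn_invalid_parameter")
})
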