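# Trace container, file round-trip, event detection and charge integration.

test_that("trace files round-trip bit-exactly on values", {
  tr <- new_trace(rnorm(500, -55), dt = 0.1, mode = "current_clamp",
                  meta = list(holding = -60, seed = 7))
  f <- tempfile(fileext = ".trace")
  on.exit(unlink(f))
  write_trace(tr, f)
  back <- read_trace(f)
  expect_identical(back$value, tr$value)
  expect_identical(attr(back, "dt"), attr(tr, "dt"))
  expect_identical(attr(back, "mode"), "current_clamp")
  expect_equal(attr(back, "meta")$holding, -60)
  expect_error(new_trace(c(1, NA), dt = 0.1), class = "chloridyn_invalid_parameter")
  expect_error(new_trace(1:5, dt = 0.1, mode = "current_clamp", units = "pA"),
               class = "chloridyn_invalid_parameter")
})

test_that("the floating-average detector finds constructed events", {
  cfg <- detector_config(threshold = -45, window_n = 50, latency = 1)

  # never crosses
  flat <- new_trace(rep(-55, 20000), dt = 0.1, mode = "current_clamp")
  expect_identical(nrow(detect_gdps(flat, cfg)), 0L)

  # one 1 s square depolarization at 10 kHz; causal averaging lags by at
  # most window_n * dt = 5 ms
  tr <- square_pulse_trace(dt = 0.1, total_ms = 6000, t0 = 2000, t1 = 3000)
  ev <- detect_gdps(tr, cfg)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset - 2000), 5 + 0.1)
  expect_lt(abs(ev$end - 3000), 5 + 0.1)
  expect_equal(ev$duration, (ev$end - ev$onset) / 1000)
  expect_equal(ev$trigger_time, ev$end + 1000)
  expect_equal(ev$peak_amplitude, 25, tolerance = 0.01)

  expect_error(detect_gdps(new_trace(rep(-55, 10), dt = 0.1, mode = "current_clamp"),
                           detector_config(-45, window_n = 50)),
               class = "chloridyn_config_error")
})

test_that("event recovery matches injected Poisson ground truth", {
  spec <- recording_spec(duration = 300, dt = 0.2, noise_sd = 1, seed = 5)
  tr <- generate_recording(spec)
  truth <- attr(tr, "truth")$gdps
  ev <- detect_gdps(tr, detector_config(threshold = -45, window_n = 50))
  expect_identical(nrow(ev), nrow(truth))
  # every detected onset near an injected one
  expect_true(all(vapply(ev$onset, function(o) min(abs(truth$onset - o)) < 200,
                         logical(1))))
  # rate consistent with the generating 1.3 / min within Poisson error
  rate <- nrow(ev) / (spec$duration / 60)
  expect_lt(abs(rate - 1.3), 3 * sqrt(1.3 / (spec$duration / 60)))
})

test_that("action potentials are counted with a refractory lockout", {
  dt <- 0.1
  t <- seq(0, 1000, by = dt)
  x <- rep(-55, length(t))
  spike_times <- c(300, 350, 400, 450, 500, 550)
  for (a in spike_times) x <- x + 55 * pmax(0, 1 - abs(t - a) / 1)
  tr <- new_trace(x, dt = dt, mode = "current_clamp")
  expect_identical(count_action_potentials(tr, 250, 650), 6L)
  # subthreshold window
  expect_identical(count_action_potentials(tr, 0, 200), 0L)
  # two spikes 1 ms apart collapse under a 2 ms lockout
  y <- rep(-55, length(t)) + 55 * pmax(0, 1 - abs(t - 300) / 0.4) +
    55 * pmax(0, 1 - abs(t - 301) / 0.4)
  tr2 <- new_trace(y, dt = dt, mode = "current_clamp")
  expect_identical(count_action_potentials(tr2, 280, 320), 1L)
})

test_that("charge integration reproduces analytic waveforms", {
  dt <- 0.05
  t <- seq(0, 2000, by = dt)
  # rectangle: 100 pA for 880 ms -> 88 pC
  x <- ifelse(t >= 500 & t < 1380, 100, 0)
  tr <- new_trace(x, dt = dt, mode = "voltage_clamp")
  expect_equal(integrate_charge(tr, 480, 1400, baseline = 0), 88,
               tolerance = 0.002)
  # zero deflection
  expect_identical(integrate_charge(tr, 0, 400, baseline = 0), 0)
  # single exponential: peak 309.5 pA, tau 284 ms -> 309.5 * 0.284 pC
  y <- ifelse(t >= 100, 309.5 * exp(-(t - 100) / 284), 0)
  tr2 <- new_trace(y, dt = dt, mode = "voltage_clamp")
  expect_equal(integrate_charge(tr2, 100, 2000, baseline = 0),
               309.5 * 0.284, tolerance = 0.002)
  expect_error(integrate_charge(tr, 100, 99), class = "chloridyn_range_error")
  expect_error(integrate_charge(tr, 0, 1e6), class = "chloridyn_range_error")
})
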