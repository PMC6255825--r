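# Post-synaptic current detection, derivative-based onset separation and
# onset-timing distributions.

make_psc_train <- function(onsets, amp = 46.9, rise = 0.5, decay = 37,
                           dt = 0.1, total = NULL, noise_sd = 0, sign = 1,
                           seed = 1) {
  set.seed(seed)
  if (is.null(total)) total <- max(onsets) + 500
  t <- seq(0, total, by = dt)
  x <- numeric(length(t))
  for (o in onsets) {
    idx <- which(t >= o & t <= o + 10 * decay)
    tp <- rise * decay / (decay - rise) * log(decay / rise)
    f <- 1 / (exp(-tp / decay) - exp(-tp / rise))
    x[idx] <- x[idx] + sign * amp * f * (exp(-(t[idx] - o) / decay) -
                                           exp(-(t[idx] - o) / rise))
  }
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  new_trace(x, dt = dt, mode = "voltage_clamp")
}

test_that("unitary event features are recovered from a constructed train", {
  onsets <- seq(200, 9800, by = 400)
  tr <- make_psc_train(onsets, amp = 46.9, rise = 0.5, decay = 37, noise_sd = 0.5)
  ev <- detect_pscs(tr, "outward", amp_threshold = 10)
  expect_identical(nrow(ev), length(onsets))
  expect_equal(mean(ev$amplitude), 46.9, tolerance = 0.02)
  expect_equal(median(ev$decay_tau), 37, tolerance = 0.15)
  # onsets within 2 ms of construction
  expect_true(all(abs(sort(ev$onset) - onsets) < 2))
  # charge close to the analytic integral of the waveform at 60 mV driving:
  # amp * norm * (decay - rise) in pA*ms = fC
  tp <- 0.5 * 37 / 36.5 * log(74)
  analytic <- 46.9 / (exp(-tp / 37) - exp(-tp / 0.5)) * (37 - 0.5)
  expect_equal(mean(ev$charge), analytic, tolerance = 0.1)
})

test_that("thresholding and flat traces give empty tables", {
  flat <- new_trace(rnorm(5000, 0, 0.2), dt = 0.1, mode = "voltage_clamp")
  expect_identical(nrow(detect_pscs(flat, "outward", amp_threshold = 10)), 0L)
  small <- make_psc_train(500, amp = 5)
  expect_identical(nrow(detect_pscs(small, "outward", amp_threshold = 10)), 0L)
})

test_that("event frequency is recovered at spontaneous rates", {
  # Poisson train at 7.8 Hz for 60 s
  set.seed(3)
  onsets <- sort(runif(round(7.8 * 60), 0, 60000 - 400))
  onsets <- onsets[c(TRUE, diff(onsets) > 8)] # detector resolution floor
  tr <- make_psc_train(onsets, dt = 0.2, total = 60000, noise_sd = 1, seed = 3)
  ev <- detect_pscs(tr, "outward", amp_threshold = 15)
  freq <- nrow(ev) / 60
  expect_lt(abs(freq - length(onsets) / 60), 0.5)
  expect_equal(mean(ev$amplitude), 46.9, tolerance = 0.05)
})

test_that("derivative detection separates outward and inward onsets", {
  tr_out <- make_psc_train(500, amp = 30, sign = 1, total = 2000)
  tr_in <- make_psc_train(1200, amp = 30, sign = -1, total = 2000)
  mixed <- new_trace(tr_out$value + tr_in$value + rnorm(nrow(tr_out), 0, 0.5),
                     dt = 0.1, mode = "voltage_clamp", meta = list(holding = -30))
  on <- detect_events_by_derivative(mixed)
  expect_identical(length(on$outward), 1L)
  expect_identical(length(on$inward), 1L)
  expect_lt(abs(on$outward - 500), 2)
  expect_lt(abs(on$inward - 1200), 2)
  # amplitude rescaling leaves onsets unchanged (threshold scales with MAD)
  scaled <- new_trace(5 * mixed$value, dt = 0.1, mode = "voltage_clamp")
  on2 <- detect_events_by_derivative(scaled)
  expect_identical(on2$outward, on$outward)
  expect_identical(on2$inward, on$inward)
})

test_that("derivative detection has a low false-positive rate on noise", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    noise <- new_trace(rnorm(1e5, 0, 2), dt = 0.1, mode = "voltage_clamp")
    on <- detect_events_by_derivative(noise, k = 6)
    length(on$outward) + length(on$inward)
  }, numeric(1))
  # < 1 false onset per 10 s on average
  expect_lt(mean(hits), 1)
})

test_that("onset distributions normalize into event windows", {
  wins <- tibble::tibble(onset = c(1000, 5000), end = c(2000, 6500))
  # uniform onsets stay near the diagonal
  set.seed(9)
  u <- runif(400)
  onsets <- c(1000 + 1000 * u[1:200], 5000 + 1500 * u[201:400])
  cdf <- cumulative_onset_distribution(onsets, wins)
  ks <- max(abs(cdf$cdf - cdf$u))
  expect_lt(ks, 1.63 / sqrt(400)) # 1% Kolmogorov band
  # delayed class sits right of the early class at every quantile
  early <- 1000 + 800 * u[1:100]
  late <- early + 100
  c_e <- cumulative_onset_distribution(early, wins)
  c_l <- cumulative_onset_distribution(late, wins)
  q <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(stats::quantile(c_l$u, q) > stats::quantile(c_e$u, q)))
  # single onset is a one-step CDF; orphans are dropped with a warning
  one <- cumulative_onset_distribution(1500, wins)
  expect_identical(one$cdf, 1)
  expect_warning(cumulative_onset_distribution(c(1500, 99000), wins), "excluded")
})
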