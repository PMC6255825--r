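#' Online detector configuration for giant depolarizing potentials
#'
#' Mirrors the microcontroller algorithm used for triggered reversal-potential
#' measurements: a strictly causal floating average of `window_n` membrane
#' potential samples is compared against a preset threshold; the event ends
#' when the average falls back below the threshold, and the voltage-clamp
#' ramp is triggered `latency` seconds after the event end.
#'
#' @param threshold Detection threshold, mV.
#' @param window_n Number of samples in the floating average.
#' @param latency Trigger latency after event end, s (0.1-20).
#' @param min_event_duration Events shorter than this are discarded, ms.
#'
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(threshold, window_n = 50, latency = 1,
                            min_event_duration = 50) {
  if (window_n < 1) abort("`window_n` must be >= 1", class = "chloridyn_config_error")
  if (latency < 0.1 || latency > 20) {
    abort("`latency` must lie in [0.1, 20] s", class = "chloridyn_config_error")
  }
  structure(list(threshold = threshold, window_n = as.integer(window_n),
                 latency = latency, min_event_duration = min_event_duration),
            class = "detector_config")
}

#' Detect giant depolarizing potentials in a current-clamp trace
#'
#' Causal floating average threshold crossing: an event opens when the
#' average crosses `threshold` upward and closes at the first sample where it
#' falls back below. Because the average is causal, the reported onset lags
#' the physical onset by at most `window_n * dt` ms. Action potentials riding
#' the event are counted with [count_action_potentials()].
#'
#' @param trace Current-clamp `ephys_trace` (mV).
#' @param cfg A [detector_config()].
#' @param dvdt_threshold Spike-detection slope threshold passed on to
#'   [count_action_potentials()], mV/ms.
#'
#' @return A tibble with one row per event: `onset`, `end`, `trigger_time`
#'   (ms), `duration` (s), `peak_amplitude` (mV above the pre-event
#'   baseline), `ap_count`.
#' @export
detect_gdps <- function(trace, cfg, dvdt_threshold = 10) {
  assert_trace(trace, "current_clamp")
  dt <- trace_dt(trace)
  x <- trace$value
  m <- causal_moving_average(x, cfg$window_n)
  above <- m >= cfg$threshold
  d <- diff(above)
  onsets <- which(d == 1L) + 1L
  ends <- which(d == -1L) + 1L
  if (length(above) && above[1]) onsets <- c(1L, onsets)
  # open event at trace end: close it at the last sample
  if (length(onsets) > length(ends)) ends <- c(ends, length(x))
  if (length(onsets) == 0L) {
    return(tibble(onset = double(), end = double(), trigger_time = double(),
                  duration = double(), peak_amplitude = double(),
                  ap_count = integer()))
  }
  ev <- tibble(onset_i = onsets, end_i = ends)
  ev <- dplyr::filter(ev, (.data$end_i - .data$onset_i) * dt >= cfg$min_event_duration)
  base_n <- max(1L, round(200 / dt))
  rows <- purrr::pmap(ev, function(onset_i, end_i) {
    b0 <- max(1L, onset_i - base_n)
    baseline <- median(x[b0:max(b0, onset_i - 1L)])
    onset_ms <- (onset_i - 1) * dt
    end_ms <- (end_i - 1) * dt
    tibble(
      onset = onset_ms, end = end_ms,
      trigger_time = end_ms + cfg$latency * 1000,
      duration = (end_ms - onset_ms) / 1000,
      peak_amplitude = max(x[onset_i:end_i]) - baseline,
      ap_count = count_action_potentials(trace, onset_ms, end_ms,
                                         dvdt_threshold = dvdt_threshold)
    )
  })
  dplyr::bind_rows(rows)
}

#' Count action potentials inside an event window
#'
#' Counts upward crossings of a dV/dt threshold between `onset` and `end`,
#' with a refractory lockout so multi-sample rising edges and fast doublets
#' closer than the lockout are counted once.
#'
#' @param trace Current-clamp `ephys_trace`.
#' @param onset,end Window boundaries, ms.
#' @param dvdt_threshold Slope threshold, mV/ms.
#' @param lockout_ms Refractory lockout, ms.
#'
#' @return Integer spike count.
#' @export
count_action_potentials <- function(trace, onset, end, dvdt_threshold = 10,
                                    lockout_ms = 2) {
  assert_trace(trace, "current_clamp")
  dt <- trace_dt(trace)
  i0 <- max(1L, floor(onset / dt) + 1L)
  i1 <- min(nrow(trace), ceiling(end / dt) + 1L)
  if (i1 <= i0) return(0L)
  dvdt <- diff(trace$value[i0:i1]) / dt
  hot <- dvdt >= dvdt_threshold
  crossings <- which(diff(c(FALSE, hot)) == 1L)
  if (length(crossings) == 0L) return(0L)
  lock <- lockout_ms / dt
  count <- 1L
  last <- crossings[1]
  for (k in crossings[-1]) {
    if (k - last >= lock) {
      count <- count + 1L
      last <- k
    }
  }
  count
}

#' Integrate the charge of a current deflection
#'
#' Trapezoidal integral of the absolute current deflection from a baseline
#' over a window, as used for the charge transfer of network events:
#' \eqn{Q = \int_{t_0}^{t_1} |I(t) - I_{base}|\,dt}, returned in pC
#' (pA x ms / 1000).
#'
#' @param trace Voltage-clamp `ephys_trace` (pA).
#' @param t0,t1 Integration window, ms.
#' @param baseline Holding-current baseline, pA. Default: median of the
#'   200 ms preceding `t0`.
#'
#' @return Charge, pC.
#' @export
integrate_charge <- function(trace, t0, t1, baseline = NULL) {
  assert_trace(trace, "voltage_clamp")
  dt <- trace_dt(trace)
  n <- nrow(trace)
  if (t1 <= t0 || t0 < 0 || t1 > (n - 1) * dt) {
    abort("integration window outside the trace", class = "chloridyn_range_error")
  }
  i0 <- floor(t0 / dt) + 1L
  i1 <- floor(t1 / dt) + 1L
  if (is.null(baseline)) {
    b0 <- max(1L, i0 - round(200 / dt))
    baseline <- median(trace$value[b0:max(b0, i0 - 1L)])
  }
  y <- abs(trace$value[i0:i1] - baseline)
  trapz_ms(y, dt) / 1000
}

# trapezoid rule on a uniform grid, result in y-units * ms
trapz_ms <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}
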