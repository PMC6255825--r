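#' Detect post-synaptic currents in a voltage-clamp trace
#'
#' Template-free detection of unitary synaptic currents. Event onsets are
#' found on the rising phase: the lightly smoothed first derivative of the
#' rectified trace must exceed a noise-scaled threshold (synaptic rise
#' slopes are far steeper than decay or noise slopes), which separates
#' events that overlap within one decay constant. For each event the
#' amplitude is the peak above the local pre-onset baseline, the 10-90%
#' rise time is interpolated on the rising phase, the decay constant comes
#' from a log-linear least-squares fit from 90% of the peak down to 10% (or
#' the next event), and the charge is the trapezoidal integral from onset
#' to the return to baseline (or the next event).
#'
#' @param trace Voltage-clamp `ephys_trace` (pA).
#' @param polarity `"outward"` (positive deflections) or `"inward"`.
#' @param amp_threshold Minimum peak amplitude above the local baseline, pA.
#' @param k_slope Rise-detection threshold in derivative-noise MADs.
#' @param refractory_ms Minimum onset separation, ms.
#'
#' @return A tibble with one row per event: `onset` (ms), `amplitude` (pA,
#'   positive), `rise_time` (ms), `decay_tau` (ms), `charge` (fC),
#'   `polarity`.
#' @export
detect_pscs <- function(trace, polarity = c("outward", "inward"),
                        amp_threshold, k_slope = 4, refractory_ms = 3) {
  polarity <- match.arg(polarity)
  assert_trace(trace, "voltage_clamp")
  dt <- trace_dt(trace)
  sgn <- if (polarity == "outward") 1 else -1
  dev <- sgn * (trace$value - median(trace$value))
  n <- length(dev)

  empty <- tibble(onset = double(), amplitude = double(), rise_time = double(),
                  decay_tau = double(), charge = double(), polarity = character())
  if (n < 5L) return(empty)

  # rise-phase onsets from the smoothed derivative
  d <- diff(dev) / dt
  w <- max(1L, round(0.5 / dt))
  if (w > 1L) d <- causal_moving_average(d, w)
  noise <- mad(d)
  if (noise == 0) noise <- stats::sd(d)
  if (!is.finite(noise) || noise == 0) return(empty)
  hits <- which(d > k_slope * noise)
  if (!length(hits)) return(empty)
  starts <- hits[c(TRUE, diff(hits) > refractory_ms / dt)]

  base_n <- max(1L, round(5 / dt))
  rows <- purrr::map(seq_along(starts), function(k) {
    o <- starts[k]
    lim <- if (k < length(starts)) starts[k + 1] - 1L else n
    b0 <- max(1L, o - base_n)
    baseline <- median(dev[b0:o])
    p <- o + which.max(dev[o:min(lim, o + round(50 / dt))]) - 1L
    amp <- dev[p] - baseline
    if (amp < amp_threshold) return(NULL)

    t10 <- interp_crossing_time(dev, o, p, baseline + 0.1 * amp, dt)
    t90 <- interp_crossing_time(dev, o, p, baseline + 0.9 * amp, dt)
    rise <- max(t90 - t10, dt / 2)

    # decay fit from 90% of peak down to 10% (or the next event)
    post <- dev[p:lim] - baseline
    i_start <- which(post <= 0.9 * amp)
    i_stop <- which(post <= 0.1 * amp)
    d0 <- if (length(i_start)) i_start[1] else 2L
    d1 <- if (length(i_stop)) i_stop[1] else length(post)
    decay_tau <- NA_real_
    if (d1 - d0 >= 2L) {
      yy <- post[d0:d1]
      pos <- yy > 0
      if (sum(pos) >= 3L) {
        tt <- (seq_along(yy) - 1)[pos] * dt
        fit <- lm(log(yy[pos]) ~ tt)
        slope <- coef(fit)[2]
        if (is.finite(slope) && slope < 0) decay_tau <- unname(-1 / slope)
      }
    }

    # charge: integral from onset to return to baseline (or the next event)
    rel <- dev[o:lim] - baseline
    ret <- which(rel[-seq_len(p - o + 1L)] <= 0)
    end_rel <- if (length(ret)) p - o + 1L + ret[1] else length(rel)
    charge <- trapz_ms(pmax(rel[seq_len(end_rel)], 0), dt) # pA*ms = fC

    tibble(onset = (o - 1) * dt, amplitude = amp, rise_time = rise,
           decay_tau = decay_tau, charge = charge, polarity = polarity)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) empty else out
}

# time (ms) at which `dev` crosses `level` upward between indices i0..i1
interp_crossing_time <- function(dev, i0, i1, level, dt) {
  seg <- dev[i0:i1]
  above <- which(seg >= level)
  if (!length(above)) return((i1 - 1) * dt)
  j <- above[1]
  if (j == 1L) return((i0 - 1) * dt)
  w <- (level - seg[j - 1]) / (seg[j] - seg[j - 1])
  (i0 + j - 2 + w) * dt
}

#' Separate outward and inward synaptic events by the derivative method
#'
#' At intermediate holding potentials GABAergic outward and glutamatergic
#' inward currents superimpose and cannot be separated by amplitude; their
#' onsets are instead identified from the smoothed first derivative of the
#' current trace. Onsets are reported where the derivative exceeds
#' `k` times the median absolute deviation of the derivative noise, split by
#' sign. Pure amplitude rescaling of the trace leaves the onset times
#' unchanged because the threshold scales with the noise estimate.
#'
#' @param trace Voltage-clamp `ephys_trace`.
#' @param k Threshold in derivative-noise MADs.
#' @param smooth_ms Moving-average smoothing applied to the derivative, ms.
#' @param refractory_ms Runs of threshold samples closer than this merge
#'   into a single onset.
#'
#' @return A list with numeric vectors `outward` and `inward` (onset times,
#'   ms).
#' @export
detect_events_by_derivative <- function(trace, k = 6, smooth_ms = 1,
                                        refractory_ms = 5) {
  assert_trace(trace, "voltage_clamp")
  dt <- trace_dt(trace)
  if (nrow(trace) < 3L) return(list(outward = numeric(), inward = numeric()))
  d <- diff(trace$value) / dt
  w <- max(1L, round(smooth_ms / dt))
  if (w > 1L && w <= length(d)) d <- causal_moving_average(d, w)
  noise <- mad(d)
  if (noise == 0) return(list(outward = numeric(), inward = numeric()))
  thr <- k * noise
  onset_times <- function(hits) {
    if (!length(hits)) return(numeric())
    starts <- hits[c(TRUE, diff(hits) > refractory_ms / dt)]
    (starts - 1) * dt
  }
  list(outward = onset_times(which(d > thr)),
       inward = onset_times(which(d < -thr)))
}

#' Cumulative distribution of synaptic-event onsets within network events
#'
#' Maps each onset to its position in the enclosing event window, normalized
#' to \[0, 1\], and returns the empirical cumulative distribution — the
#' standard way to compare the timing of GABAergic and glutamatergic inputs
#' across events of different duration.
#'
#' @param onsets Numeric vector of event onset times, ms.
#' @param gdp_windows Tibble or data frame with columns `onset` and `end`
#'   (ms), one row per network event.
#'
#' @return A tibble with columns `u` (normalized time, sorted) and `cdf`.
#'   Onsets falling outside every window are excluded with a warning.
#' @export
cumulative_onset_distribution <- function(onsets, gdp_windows) {
  gdp_windows <- as_tibble(gdp_windows)
  u <- purrr::map_dbl(onsets, function(t) {
    hit <- which(t >= gdp_windows$onset & t <= gdp_windows$end)
    if (!length(hit)) return(NA_real_)
    w <- gdp_windows[hit[1], ]
    (t - w$onset) / (w$end - w$onset)
  })
  if (anyNA(u)) {
    warn(sprintf("%d onset(s) outside all event windows were excluded", sum(is.na(u))))
    u <- u[!is.na(u)]
  }
  u <- sort(u)
  tibble(u = u, cdf = seq_along(u) / length(u))
}
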