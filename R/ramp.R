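#' Voltage-ramp protocol specification
#'
#' The reversal-potential ramp: a depolarized pre-step (to inactivate fast
#' sodium currents) followed by a linear voltage ramp from `v_start` down to
#' `v_end`.
#'
#' @param v_start Pre-step / ramp start potential, mV.
#' @param v_end Ramp end potential, mV (must be below `v_start`).
#' @param pre_step_duration Duration of the depolarizing pre-step, ms.
#' @param ramp_duration Duration of the ramp, ms. The default (60 mV in
#'   50 ms, about 1 mV/ms) lies within the experimentally plausible range;
#'   see the vignette for the rate-dependent biases of the protocol.
#'
#' @return A list of class `ramp_spec`.
#' @export
ramp_spec <- function(v_start = -3, v_end = -63, pre_step_duration = 100,
                      ramp_duration = 50) {
  if (v_start <= v_end) {
    abort("`v_start` must be above `v_end`", class = "chloridyn_invalid_parameter")
  }
  if (ramp_duration <= 0 || pre_step_duration < 0) {
    abort("durations must be positive", class = "chloridyn_invalid_parameter")
  }
  structure(list(v_start = v_start, v_end = v_end,
                 pre_step_duration = pre_step_duration,
                 ramp_duration = ramp_duration),
            class = "ramp_spec")
}

#' Command voltage of a ramp protocol
#'
#' @param spec A [ramp_spec()].
#' @param time_ms Times at which to evaluate the command, ms (0 = start of
#'   the pre-step).
#'
#' @return Command potential, mV (held at `v_end` after the ramp).
#' @export
ramp_command_voltage <- function(spec, time_ms) {
  t1 <- spec$pre_step_duration
  t2 <- t1 + spec$ramp_duration
  v <- ifelse(time_ms < t1, spec$v_start,
              ifelse(time_ms <= t2,
                     spec$v_start + (spec$v_end - spec$v_start) * (time_ms - t1) / spec$ramp_duration,
                     spec$v_end))
  v
}

#' Extract the GABA-A reversal potential from a ramp pair
#'
#' Subtracts the current of a control voltage ramp from the ramp delivered
#' during the GABA response; the command potential at which the difference
#' current reverses is taken as \eqn{E_{GABA}}. With
#' `method = "interpolation"` the zero crossing is located by linear
#' interpolation between samples; if the noisy difference crosses zero more
#' than once, the crossing closest to the mid-ramp potential is chosen and a
#' warning is emitted. With `method = "fit"` a least-squares line of the
#' difference current against the command voltage is solved for zero, which
#' is robust to additive current noise.
#'
#' @param control,gaba Voltage-clamp `ephys_trace`s with identical timing
#'   (time 0 = start of the pre-step).
#' @param spec A [ramp_spec()] describing the shared command.
#' @param method Crossing locator, `"interpolation"` (default) or `"fit"`.
#' @param v_measured Optional recorded membrane-potential samples aligned
#'   with the traces (numeric vector or an object with a `value` column).
#'   Under an ideal clamp the membrane follows the command and this can be
#'   omitted; with a non-negligible access resistance the membrane
#'   potential deviates from the command by `rs` times the clamp current,
#'   and the reversal must be read off the measured voltage (the
#'   experimental convention) to stay unbiased.
#'
#' @return \eqn{E_{GABA}} in mV, with attribute `n_crossings`.
#' @export
extract_egaba_from_ramp <- function(control, gaba, spec = ramp_spec(),
                                    method = c("interpolation", "fit"),
                                    v_measured = NULL) {
  method <- match.arg(method)
  assert_trace(control, "voltage_clamp")
  assert_trace(gaba, "voltage_clamp")
  dt <- trace_dt(control)
  if (!isTRUE(all.equal(dt, trace_dt(gaba))) || nrow(control) != nrow(gaba)) {
    abort("control and GABA traces must share timing", class = "chloridyn_invalid_parameter")
  }
  t1 <- spec$pre_step_duration
  t2 <- t1 + spec$ramp_duration
  sel <- control$time_ms >= t1 & control$time_ms <= t2
  if (!any(sel)) abort("traces do not cover the ramp segment", class = "chloridyn_range_error")
  di <- gaba$value[sel] - control$value[sel]
  if (max(abs(di)) <= 1e-9 * max(abs(control$value[sel]), 1)) {
    abort("control and GABA currents are indistinguishable (no reversal)",
          class = "chloridyn_no_reversal")
  }
  if (is.null(v_measured)) {
    v <- ramp_command_voltage(spec, control$time_ms[sel])
  } else {
    if (!is.numeric(v_measured)) v_measured <- v_measured$value
    if (length(v_measured) != nrow(control)) {
      abort("`v_measured` must align sample-wise with the traces",
            class = "chloridyn_invalid_parameter")
    }
    v <- v_measured[sel]
  }

  if (method == "fit") {
    fit <- lm(di ~ v)
    b <- coef(fit)
    if (abs(b[2]) < .Machine$double.eps) {
      abort("difference current does not depend on voltage (no reversal)",
            class = "chloridyn_no_reversal")
    }
    e <- unname(-b[1] / b[2])
    if (e > max(v) || e < min(v)) {
      abort("fitted reversal lies outside the ramp (no reversal)",
            class = "chloridyn_no_reversal")
    }
    return(structure(e, n_crossings = 1L))
  }

  s <- sign(di)
  cross <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(s == 0)
  if (length(cross) == 0L && length(exact) == 0L) {
    abort("difference current does not change sign over the ramp (no reversal)",
          class = "chloridyn_no_reversal")
  }
  e_cross <- c(
    # linear interpolation between bracketing samples, against command voltage
    vapply(cross, function(i) {
      w <- di[i] / (di[i] - di[i + 1])
      v[i] + w * (v[i + 1] - v[i])
    }, numeric(1)),
    v[exact]
  )
  if (length(e_cross) > 1L) {
    mid <- (max(v) + min(v)) / 2
    warn(sprintf("%d zero crossings in the ramp difference current; using the one nearest mid-ramp",
                 length(e_cross)))
    e_cross <- e_cross[which.min(abs(e_cross - mid))]
  }
  structure(e_cross, n_crossings = length(cross) + length(exact))
}
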