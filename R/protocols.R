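#' Stimulus specification for a simulated network event
#'
#' The GABAergic/glutamatergic synaptic barrage used to emulate a giant
#' depolarizing potential: 534 GABA-A synapses (0.789 nS, 0.5/80 ms) and
#' 107 AMPA synapses (0.509 nS, 0.1/11 ms, E_rev 0 mV) placed randomly over
#' the dendritic membrane and activated at normally distributed times. The
#' timing defaults (GABA N(500, 250) ms, AMPA N(550, 180) ms, truncated to
#' the stimulus window) make GABAergic inputs lead and glutamatergic
#' activity terminate earlier, matching the onset statistics of identified
#' synaptic events within recorded network bursts.
#'
#' @param n_gaba,n_ampa Synapse counts.
#' @param g_gaba,g_ampa Unitary peak conductances, nS.
#' @param gaba_rise,gaba_decay,ampa_rise,ampa_decay Kinetics, ms.
#' @param gaba_timing,ampa_timing `c(mean, sd)` of the activation-time
#'   distribution, ms.
#' @param window Truncation window for activation times, ms.
#' @param p_split Fractional bicarbonate conductance of the GABA synapses.
#' @param e_rev_ampa AMPA reversal, mV.
#' @param seed Integer seed for placement and timing.
#'
#' @return A list of class `gdp_stimulus`.
#' @export
gdp_stimulus <- function(n_gaba = 534, g_gaba = 0.789,
                         gaba_rise = 0.5, gaba_decay = 80,
                         n_ampa = 107, g_ampa = 0.509,
                         ampa_rise = 0.1, ampa_decay = 11,
                         gaba_timing = c(500, 250), ampa_timing = c(550, 180),
                         window = 1500, p_split = 0.44, e_rev_ampa = 0,
                         seed = 1) {
  if (n_gaba < 0 || n_ampa < 0) abort("counts must be >= 0", class = "chloridyn_invalid_parameter")
  if (gaba_timing[2] <= 0 || ampa_timing[2] <= 0) {
    abort("timing sd must be > 0", class = "chloridyn_invalid_parameter")
  }
  structure(list(n_gaba = as.integer(n_gaba), g_gaba = g_gaba,
                 gaba_rise = gaba_rise, gaba_decay = gaba_decay,
                 n_ampa = as.integer(n_ampa), g_ampa = g_ampa,
                 ampa_rise = ampa_rise, ampa_decay = ampa_decay,
                 gaba_timing = gaba_timing, ampa_timing = ampa_timing,
                 window = window, p_split = p_split,
                 e_rev_ampa = e_rev_ampa, seed = seed),
            class = "gdp_stimulus")
}

rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# sample synapse placement (area-weighted over dendrites) and timing
place_gdp_synapses <- function(model, stim, t_offset = 0, gaba_only = FALSE) {
  withr_seed(stim$seed)
  dend <- model$segments[model$segments$region == "dendrite", ]
  if (!nrow(dend)) abort("model has no dendritic segments", class = "chloridyn_build_error")
  draw <- function(n) sample(dend$seg, n, replace = TRUE, prob = dend$area)
  syn <- NULL
  if (stim$n_gaba > 0) {
    syn <- synapse(draw(stim$n_gaba), "gaba", stim$g_gaba,
                   stim$gaba_rise, stim$gaba_decay,
                   onset = t_offset + rtnorm(stim$n_gaba, stim$gaba_timing[1],
                                             stim$gaba_timing[2], 0, stim$window),
                   p_split = stim$p_split)
  }
  if (!gaba_only && stim$n_ampa > 0) {
    ampa <- synapse(draw(stim$n_ampa), "ampa", stim$g_ampa,
                    stim$ampa_rise, stim$ampa_decay,
                    onset = t_offset + rtnorm(stim$n_ampa, stim$ampa_timing[1],
                                              stim$ampa_timing[2], 0, stim$window),
                    e_rev = stim$e_rev_ampa)
    syn <- dplyr::bind_rows(syn, ampa)
  }
  syn
}

# shared ramp-through-clamp run; returns the re-timed clamp-current trace
# together with the recorded somatic membrane potential
run_clamped_ramp <- function(model, rs, spec, settle, synapse_tbl, ions,
                             dt, record_dt) {
  v_hold <- model$passive$e_leak
  cmd <- function(t) ifelse(t < settle, v_hold,
                            ramp_command_voltage(spec, t - settle))
  total <- settle + spec$pre_step_duration + spec$ramp_duration + 20
  sim <- simulate_cable(model, duration = total, dt = dt,
                        synapses = synapse_tbl,
                        clamp = sevc_clamp(rs, cmd), ions = ions,
                        record_dt = record_dt)
  sel <- sim$time_ms >= settle
  list(i = new_trace(sim$i_clamp[sel], dt = record_dt, mode = "voltage_clamp",
                     meta = list(rs = rs)),
       v = sim$v_soma[sel])
}

#' Access-resistance sensitivity of ramp-determined E_GABA
#'
#' Runs the reversal-potential ramp protocol through a simulated
#' single-electrode clamp at several access resistances, on a neuron with
#' static intracellular ions, and extracts E_GABA from the control/GABA
#' difference current exactly as in the experimental analysis. A 10 nS /
#' 100 ms decay GABA synapse emulates the focal GABA application.
#'
#' @param model A [cable_model()].
#' @param rs_list Access resistances to test, MOhm.
#' @param cl_i,hco3_i Static intracellular concentrations, mM.
#' @param site Segment of the GABA synapse (default: a proximal dendritic
#'   segment about 20 um from the soma).
#' @param g_puff,puff_rise,puff_decay Puff-synapse conductance (nS) and
#'   kinetics (ms).
#' @param spec A [ramp_spec()].
#' @param settle Settling time at the holding potential before the
#'   protocol, ms.
#' @param dt,record_dt Integration / recording steps, ms.
#'
#' @return A tibble with columns `rs` (MOhm) and `egaba` (mV).
#' @export
run_rs_experiment <- function(model, rs_list = c(0.5, 5, 10, 20, 40),
                              cl_i = 30, hco3_i = 14.4, site = NULL,
                              g_puff = 10, puff_rise = 0.5, puff_decay = 100,
                              spec = ramp_spec(), settle = 100,
                              dt = 0.025, record_dt = 0.1) {
  if (is.null(site)) site <- seg_at(model, distance = 20)
  ions <- ion_dynamics(cl_init = cl_i, hco3_init = hco3_i, dynamic = FALSE)
  onset <- settle + spec$pre_step_duration / 2
  puff <- synapse(site, "gaba", g_puff, puff_rise, puff_decay, onset = onset)
  rows <- purrr::map(rs_list, function(rs) {
    ctrl <- run_clamped_ramp(model, rs, spec, settle, NULL, ions, dt, record_dt)
    gaba <- run_clamped_ramp(model, rs, spec, settle, puff, ions, dt, record_dt)
    tibble(rs = rs,
           egaba = as.numeric(extract_egaba_from_ramp(ctrl$i, gaba$i, spec,
                                                      v_measured = gaba$v)))
  })
  dplyr::bind_rows(rows)
}

#' Space-clamp bias of ramp-determined intracellular chloride
#'
#' Repeats the ramp protocol with the GABA synapse at increasingly distal
#' dendritic sites (static intracellular ions, fixed access resistance) and
#' converts each determined E_GABA to an apparent chloride concentration.
#' Dendritic filtering attenuates the command ramp at distal sites, so the
#' apparent concentration diverges from the imposed one with distance.
#'
#' @inheritParams run_rs_experiment
#' @param cl_i The imposed (true) chloride concentration, mM.
#' @param distances Path distances of the synapse sites, um (default: five
#'   sites from proximal to about two thirds of the longest dendritic path;
#'   at very distal sites on strongly filtered trees the difference current
#'   may never reverse within the ramp).
#' @param rs Access resistance, MOhm.
#'
#' @return A tibble with `distance` (um), `seg`, `egaba` (mV),
#'   `cl_apparent` (mM). Sites without a reversal give `NA` with a warning.
#' @export
run_spaceclamp_experiment <- function(model, cl_i, distances = NULL, rs = 5,
                                      hco3_i = 14.4,
                                      g_puff = 10, puff_rise = 0.5,
                                      puff_decay = 100, spec = ramp_spec(),
                                      settle = 100, dt = 0.025,
                                      record_dt = 0.1) {
  dend <- model$segments[model$segments$region == "dendrite", ]
  if (is.null(distances)) {
    distances <- c(0.05, 0.2, 0.35, 0.5, 0.65) * max(dend$dist)
  }
  ions <- ion_dynamics(cl_init = cl_i, hco3_init = hco3_i, dynamic = FALSE)
  onset <- settle + spec$pre_step_duration / 2
  ctrl <- run_clamped_ramp(model, rs, spec, settle, NULL, ions, dt, record_dt)
  rows <- purrr::map(distances, function(d) {
    seg <- seg_at(model, distance = d)
    puff <- synapse(seg, "gaba", g_puff, puff_rise, puff_decay, onset = onset)
    gaba <- run_clamped_ramp(model, rs, spec, settle, puff, ions, dt, record_dt)
    e <- tryCatch(
      as.numeric(extract_egaba_from_ramp(ctrl$i, gaba$i, spec,
                                         v_measured = gaba$v)),
      chloridyn_no_reversal = function(cnd) {
        warn(sprintf("no reversal at site %.0f um; returning NA", d))
        NA_real_
      }
    )
    tibble(distance = d, seg = seg, egaba = e,
           cl_apparent = if (is.na(e)) NA_real_ else cl_from_egaba(e, hco3_i = hco3_i))
  })
  dplyr::bind_rows(rows)
}

#' Simulate the ionic consequences of a network event
#'
#' Runs the full synaptic barrage of [gdp_stimulus()] on a free-running
#' (current-clamp) neuron with dynamic intracellular Cl-/HCO3-, transport
#' set points equal to the initial concentrations, and returns the time
#' courses of the volume-weighted mean dendritic concentrations together
#' with the somatic potential.
#'
#' @param model A [cable_model()].
#' @param stim A [gdp_stimulus()].
#' @param cl_init Initial (and resting) intracellular chloride, mM.
#' @param hco3_init Initial (and resting) bicarbonate, mM.
#' @param post Simulated time after the stimulus window, ms.
#' @param lead Quiet lead-in before the first possible onset, ms.
#' @param dt,record_dt Integration / recording steps, ms.
#'
#' @return An object of class `gdp_simulation`: a list with `timeseries`
#'   (tibble: `time_ms`, `v_soma`, `cl_dend`, `hco3_dend`), the peak signed
#'   change `delta_cl` and `delta_hco3` (mM, relative to baseline), the
#'   minimum `hco3_min` (mM), and the run parameters. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
run_gdp_simulation <- function(model, stim = gdp_stimulus(), cl_init = 30,
                               hco3_init = 14.1, post = 5000, lead = 200,
                               dt = 0.025, record_dt = 2) {
  syn <- place_gdp_synapses(model, stim, t_offset = lead)
  duration <- lead + stim$window + post
  ions <- ion_dynamics(cl_init = cl_init, hco3_init = hco3_init,
                       cl_rest = cl_init, hco3_rest = hco3_init)
  sim <- simulate_cable(model, duration = duration, dt = dt, synapses = syn,
                        ions = ions, record_dt = record_dt)
  d_cl <- sim$cl_dend - cl_init
  d_h <- sim$hco3_dend - hco3_init
  structure(list(
    timeseries = tibble(time_ms = sim$time_ms, v_soma = sim$v_soma,
                        cl_dend = sim$cl_dend, hco3_dend = sim$hco3_dend),
    cl_init = cl_init, hco3_init = hco3_init,
    delta_cl = d_cl[which.max(abs(d_cl))],
    delta_hco3 = d_h[which.max(abs(d_h))],
    hco3_min = min(sim$hco3_dend),
    v_peak = max(sim$v_soma),
    stim = stim, n_seg = nrow(model$segments)
  ), class = "gdp_simulation")
}

#' @export
print.gdp_simulation <- function(x, ...) {
  cat("<gdp_simulation>\n")
  cat(sprintf("  initial [Cl-]i %.1f mM, [HCO3-]i %.1f mM; %d GABA + %d AMPA synapses\n",
              x$cl_init, x$hco3_init, x$stim$n_gaba, x$stim$n_ampa))
  cat(sprintf("  peak dendritic d[Cl-]i %+.2f mM, d[HCO3-]i %+.2f mM (min %.2f mM), V peak %.1f mV\n",
              x$delta_cl, x$delta_hco3, x$hco3_min, x$v_peak))
  invisible(x)
}

#' Calibrate the GABAergic synapse count to a target clamp charge
#'
#' Scales the number of GABA synapses in a stimulus (keeping the unitary
#' conductance fixed) so that the integrated GABA-evoked somatic clamp
#' charge — measured under voltage clamp at `v_cmd` with static
#' intracellular ions — matches a target within `tol`. The iteration
#' exploits the near-linearity of the collected charge in the synapse
#' count.
#'
#' @param model A [cable_model()].
#' @param stim A [gdp_stimulus()].
#' @param target_charge Target charge, pC.
#' @param cl_i,hco3_i Static intracellular concentrations, mM.
#' @param v_cmd Command potential, mV.
#' @param rs Access resistance of the clamp, MOhm (small = near-ideal).
#' @param tol Relative tolerance on the achieved charge.
#' @param max_iter Maximum refinement iterations.
#' @param dt Integration step, ms.
#'
#' @return A list with the scaled stimulus (`stim`), the achieved charge
#'   (`charge`, pC) and the trajectory of trials (`trace`, tibble).
#' @export
calibrate_gdp_charge <- function(model, stim = gdp_stimulus(),
                                 target_charge = 88, cl_i = 10,
                                 hco3_i = 14.1, v_cmd = 0, rs = 0.5,
                                 tol = 0.05, max_iter = 8, dt = 0.025) {
  if (target_charge <= 0) {
    stim$n_gaba <- 0L
    return(list(stim = stim, charge = 0, trace = tibble(n_gaba = 0L, charge = 0)))
  }
  settle <- 300
  ions <- ion_dynamics(cl_init = cl_i, hco3_init = hco3_i, dynamic = FALSE)
  duration <- settle + stim$window + 600
  measure <- function(n) {
    s <- stim
    s$n_gaba <- as.integer(n)
    syn <- place_gdp_synapses(model, s, t_offset = settle, gaba_only = TRUE)
    sim <- simulate_cable(model, duration = duration, dt = dt, synapses = syn,
                          clamp = sevc_clamp(rs, v_cmd), ions = ions,
                          record_dt = 0.5)
    tr <- new_trace(sim$i_clamp, dt = 0.5, mode = "voltage_clamp")
    t0 <- min(syn$onset)
    integrate_charge(tr, t0, duration - 1)
  }
  n <- stim$n_gaba
  trace <- tibble(n_gaba = integer(), charge = double())
  for (it in seq_len(max_iter)) {
    q <- measure(n)
    trace <- dplyr::add_row(trace, n_gaba = as.integer(n), charge = q)
    if (abs(q - target_charge) / target_charge <= tol) {
      stim$n_gaba <- as.integer(n)
      return(list(stim = stim, charge = q, trace = trace))
    }
    n_new <- max(1L, as.integer(round(n * target_charge / q)))
    if (n_new == n) {
      if (abs(q - target_charge) / target_charge <= tol) break
      if (n == 1L && q > target_charge * (1 + tol)) {
        abort("target charge unreachable with at least one synapse",
              class = "chloridyn_calibration_error")
      }
      stim$n_gaba <- as.integer(n)
      return(list(stim = stim, charge = q, trace = trace))
    }
    n <- n_new
  }
  abort("charge calibration did not converge", class = "chloridyn_calibration_error")
}
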