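#' Surrogate immature pyramidal-cell morphology
#'
#' Random branched dendritic tree, scaled so that total membrane area times
#' the specific capacitance matches a target whole-cell capacitance. The
#' defaults emulate an immature CA3 pyramidal neuron: a 15 um soma, five
#' primary dendrites with thin (about 1.2 tapering to 0.4 um) processes and
#' a 65 pF capacitance — the perforated-patch estimate, i.e. the recording
#' configuration that leaves intracellular chloride undisturbed.
#'
#' @param soma_diameter Soma diameter, um.
#' @param n_primary_dendrites Number of primary dendrites.
#' @param mean_path_length Mean soma-to-tip path length, um.
#' @param taper Per-section diameter ratio (child/parent, < 1).
#' @param branch_prob Branching probability per 100 um of neurite.
#' @param target_capacitance Whole-cell capacitance target, pF (30-200).
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param initial_diam Diameter of primary dendrites at the soma, um.
#' @param min_diam Terminal diameter floor, um.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#'
#' @return A [morphology()] with coordinate columns (writable with
#'   [write_swc()]). Total capacitance matches `target_capacitance` within
#'   5 percent or a generation error is raised.
#' @export
make_surrogate_morphology <- function(soma_diameter = 15,
                                      n_primary_dendrites = 5,
                                      mean_path_length = 180,
                                      taper = 0.88,
                                      branch_prob = 0.35,
                                      target_capacitance = 65,
                                      cm = 1,
                                      initial_diam = 1.2,
                                      min_diam = 0.4,
                                      seed = 1) {
  if (target_capacitance < 30 || target_capacitance > 200) {
    abort("`target_capacitance` must lie in [30, 200] pF",
          class = "chloridyn_generation_error")
  }
  stopifnot(soma_diameter > 0, n_primary_dendrites >= 1, mean_path_length > 0)
  withr_seed(seed)

  secs <- new.env()
  secs$rows <- list()
  secs$next_id <- 2L

  grow <- function(parent_id, origin, dir, diam, path_len, max_path) {
    len <- runif(1, 30, 70)
    dd <- max(min_diam, diam * taper)
    id <- secs$next_id
    secs$next_id <- id + 1L
    end <- origin + dir * len
    secs$rows[[length(secs$rows) + 1L]] <- tibble(
      id = id, parent_id = parent_id, parent_pos = 1, length = len,
      diam_prox = diam, diam_dist = dd, region = "dendrite",
      x0 = origin[1], y0 = origin[2], z0 = origin[3],
      x1 = end[1], y1 = end[2], z1 = end[3],
      ux = dir[1], uy = dir[2], uz = dir[3]
    )
    new_path <- path_len + len
    if (new_path >= max_path || dd <= min_diam) return(invisible())
    if (runif(1) < 1 - exp(-branch_prob * len / 100)) {
      for (b in 1:2) grow(id, end, perturb_dir(dir, 40), dd, new_path, max_path)
    } else {
      grow(id, end, perturb_dir(dir, 15), dd, new_path, max_path)
    }
  }

  r_soma <- soma_diameter / 2
  for (p in seq_len(n_primary_dendrites)) {
    dir <- random_unit_vector()
    max_path <- max(60, rnorm(1, mean_path_length, 0.25 * mean_path_length))
    grow(1L, dir * r_soma, dir, initial_diam, 0, max_path)
  }

  soma <- tibble(id = 1L, parent_id = NA_integer_, parent_pos = NA_real_,
                 length = soma_diameter, diam_prox = soma_diameter,
                 diam_dist = soma_diameter, region = "soma",
                 x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = 0,
                 ux = 0, uy = 0, uz = 1)
  m <- dplyr::bind_rows(soma, dplyr::bind_rows(secs$rows))

  # one-shot length rescaling: dendritic area is linear in length, so a
  # single factor puts the capacitance on target exactly
  target_area <- target_capacitance / (0.01 * cm)
  soma_area <- pi * soma_diameter^2
  dend_area <- sum(section_area(m$length[-1], m$diam_prox[-1], m$diam_dist[-1]))
  needed <- target_area - soma_area
  if (needed <= 0) {
    abort("target capacitance smaller than the soma alone", class = "chloridyn_generation_error")
  }
  f <- needed / dend_area
  if (f > 25 || f < 0.04) {
    abort("cannot reach target capacitance by rescaling this tree",
          class = "chloridyn_generation_error")
  }
  m$length[-1] <- m$length[-1] * f
  m <- recompute_coordinates(m, r_soma)

  out <- morphology(dplyr::select(m, -"ux", -"uy", -"uz"))
  achieved <- morphology_capacitance(out, cm)
  if (abs(achieved - target_capacitance) / target_capacitance > 0.05) {
    abort("capacitance calibration failed", class = "chloridyn_generation_error")
  }
  attr(out, "seed") <- seed
  out
}

# rebuild coordinates after length rescaling by walking the tree
recompute_coordinates <- function(m, r_soma) {
  idx <- match(m$parent_id, m$id)
  for (i in order(is.na(m$parent_id), decreasing = TRUE)) NULL
  # process in an order where parents come first (generator appends children
  # after parents, so row order already satisfies this)
  for (i in seq_len(nrow(m))) {
    if (is.na(m$parent_id[i])) next
    p <- idx[i]
    dir <- c(m$ux[i], m$uy[i], m$uz[i])
    origin <- if (m$region[p] == "soma") dir * r_soma else c(m$x1[p], m$y1[p], m$z1[p])
    end <- origin + dir * m$length[i]
    m$x0[i] <- origin[1]; m$y0[i] <- origin[2]; m$z0[i] <- origin[3]
    m$x1[i] <- end[1]; m$y1[i] <- end[2]; m$z1[i] <- end[3]
  }
  m
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate `dir` by a random angle up to `max_deg` around a random axis
perturb_dir <- function(dir, max_deg) {
  repeat {
    v <- random_unit_vector()
    axis <- c(dir[2] * v[3] - dir[3] * v[2],
              dir[3] * v[1] - dir[1] * v[3],
              dir[1] * v[2] - dir[2] * v[1])
    na <- sqrt(sum(axis^2))
    if (na > 1e-6) { axis <- axis / na; break }
  }
  th <- runif(1, 0, max_deg) * pi / 180
  dir * cos(th) + axis * sin(th) # Rodrigues with axis orthogonal to dir
}

withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Specification of a synthetic patch-clamp recording
#'
#' Defaults reproduce the event statistics of spontaneous network activity
#' in immature CA3 slices: giant depolarizing potentials at 1.3 per minute
#' (24.9 mV / 1.24 s in current clamp; 309.5 pA / about 0.9 s envelopes in
#' voltage clamp at 0 mV), GABAergic spontaneous PSCs at 7.8 Hz and
#' glutamatergic ones at 5.8 Hz.
#'
#' @param duration Recording duration, s.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param dt Sampling interval, ms.
#' @param gdp_rate GDP rate, events per minute.
#' @param gdp_amplitude CC depolarization amplitude, mV.
#' @param gdp_amplitude_pA VC envelope peak, pA (holding-dependent; default
#'   the 0 mV GABAergic value).
#' @param spsc_freq_gaba,spsc_freq_glu Spontaneous PSC rates, Hz.
#' @param spsc_gaba,spsc_glu Per-class shape lists
#'   (`amplitude` pA or mV, `rise`, `decay` ms).
#' @param ap_mean Mean number of riding action potentials per
#'   suprathreshold GDP.
#' @param suprathreshold Whether CC events carry action potentials.
#' @param baseline Resting level (mV for CC, pA for VC).
#' @param holding Holding potential for VC metadata, mV.
#' @param noise_sd Gaussian noise SD (trace units).
#' @param min_gap_s Minimum inter-GDP interval, s.
#' @param seed Integer seed.
#'
#' @return A list of class `recording_spec`.
#' @export
recording_spec <- function(duration = 600, mode = c("current_clamp", "voltage_clamp"),
                           dt = 0.1, gdp_rate = 1.3, gdp_amplitude = 24.9,
                           gdp_amplitude_pA = 309.5,
                           spsc_freq_gaba = 7.8, spsc_freq_glu = 5.8,
                           spsc_gaba = list(amplitude = 46.9, rise = 0.5, decay = 37),
                           spsc_glu = list(amplitude = 18.3, rise = 0.5, decay = 10.8),
                           ap_mean = 6.4, suprathreshold = TRUE,
                           baseline = NULL, holding = 0,
                           noise_sd = 1, min_gap_s = 5, seed = 1) {
  mode <- match.arg(mode)
  if (duration <= 0 || gdp_rate < 0 || spsc_freq_gaba < 0 || spsc_freq_glu < 0) {
    abort("rates must be >= 0 and duration > 0", class = "chloridyn_invalid_parameter")
  }
  if (is.null(baseline)) baseline <- if (mode == "current_clamp") -55 else 0
  structure(list(duration = duration, mode = mode, dt = dt, gdp_rate = gdp_rate,
                 gdp_amplitude = gdp_amplitude, gdp_amplitude_pA = gdp_amplitude_pA,
                 spsc_freq_gaba = spsc_freq_gaba, spsc_freq_glu = spsc_freq_glu,
                 spsc_gaba = spsc_gaba, spsc_glu = spsc_glu,
                 ap_mean = ap_mean, suprathreshold = suprathreshold,
                 baseline = baseline, holding = holding,
                 noise_sd = noise_sd, min_gap_s = min_gap_s, seed = seed),
            class = "recording_spec")
}

# normalized two-exponential envelope, unit peak, evaluated at times t >= 0
biexp_envelope <- function(t, tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  f <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  out <- f * (exp(-t / tau_decay) - exp(-t / tau_rise))
  out[t < 0] <- 0
  out
}

#' Generate a synthetic recording with known ground truth
#'
#' Places GDPs by a Poisson process (thinned to a minimum inter-event
#' interval), overlays class-specific spontaneous PSC trains and Gaussian
#' noise, and returns both the trace and the exact injected-event tables so
#' detector performance can be scored against truth. Current-clamp GDPs are
#' smooth two-exponential depolarizations (rise 150 ms, decay 400 ms) with
#' stereotyped riding action potentials (2.7 ms, 55 mV) at the crest;
#' voltage-clamp GDPs are two-exponential current envelopes whose
#' time constants (50/170 ms) give the canonical about 88 pC charge at the
#' 309.5 pA peak.
#'
#' @param spec A [recording_spec()].
#'
#' @return An `ephys_trace`; the ground truth is attached as attribute
#'   `truth`, a list with tibbles `gdps` and `pscs`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  withr_seed(spec$seed)
  dur_ms <- spec$duration * 1000
  n <- floor(dur_ms / spec$dt) + 1L
  t <- (seq_len(n) - 1) * spec$dt
  x <- rep(spec$baseline, n)
  cc <- spec$mode == "current_clamp"

  # --- GDP placement: Poisson, minimum-gap thinned
  onsets <- numeric()
  if (spec$gdp_rate > 0) {
    n_cand <- rpois(1, spec$gdp_rate / 60 * spec$duration * 1.5)
    cand <- sort(runif(n_cand, 0, dur_ms - 2000))
    for (o in cand) {
      if (!length(onsets) || o - tail(onsets, 1) >= spec$min_gap_s * 1000) {
        onsets <- c(onsets, o)
      }
    }
    target_n <- rpois(1, spec$gdp_rate / 60 * spec$duration)
    onsets <- head(onsets, target_n)
  }

  gdps <- tibble(onset = double(), peak_time = double(), amplitude = double(),
                 duration = double(), ap_count = integer())
  for (o in onsets) {
    if (cc) {
      idx <- which(t >= o & t <= o + 3200)
      x[idx] <- x[idx] + biexp_envelope(t[idx] - o, 150, 400) * spec$gdp_amplitude
      ap_n <- if (spec$suprathreshold) max(0L, round(rnorm(1, spec$ap_mean, 0.8))) else 0L
      tp <- o + 235 # envelope peak latency for 150/400 ms
      if (ap_n > 0) {
        ap_t <- sort(runif(ap_n, o + 80, o + 700))
        for (a in ap_t) {
          j <- which(t >= a - 1.35 & t <= a + 1.35)
          x[j] <- x[j] + 55 * pmax(0, 1 - abs(t[j] - a) / 1.35)
        }
      }
      gdps <- dplyr::add_row(gdps, onset = o, peak_time = tp,
                             amplitude = spec$gdp_amplitude, duration = 1.24,
                             ap_count = as.integer(if (spec$suprathreshold) ap_n else 0L))
    } else {
      idx <- which(t >= o & t <= o + 1400)
      x[idx] <- x[idx] + biexp_envelope(t[idx] - o, 50, 170) * spec$gdp_amplitude_pA
      gdps <- dplyr::add_row(gdps, onset = o, peak_time = o + 86.7,
                             amplitude = spec$gdp_amplitude_pA, duration = 0.91,
                             ap_count = 0L)
    }
  }

  # --- spontaneous PSCs
  pscs <- tibble(onset = double(), class = character(), amplitude = double())
  add_train <- function(x, rate_hz, shape, klass, sign) {
    if (rate_hz <= 0) return(x)
    n_ev <- rpois(1, rate_hz * spec$duration)
    ot <- sort(runif(n_ev, 0, dur_ms - 200))
    amp <- if (cc) shape$amplitude / 10 else shape$amplitude # small PSPs in CC
    for (o in ot) {
      idx <- which(t >= o & t <= o + 8 * shape$decay)
      x[idx] <- x[idx] + sign * amp * biexp_envelope(t[idx] - o, shape$rise, shape$decay)
    }
    pscs <<- dplyr::bind_rows(pscs, tibble(onset = ot, class = klass, amplitude = amp))
    x
  }
  if (cc) {
    x <- add_train(x, spec$spsc_freq_gaba, spec$spsc_gaba, "gaba", +1)
  } else {
    # polarity by holding: GABAergic outward at 0 mV, glutamatergic inward at -60
    if (spec$holding > -30) {
      x <- add_train(x, spec$spsc_freq_gaba, spec$spsc_gaba, "gaba", +1)
    }
    if (spec$holding < 0) {
      x <- add_train(x, spec$spsc_freq_glu, spec$spsc_glu, "glu", -1)
    }
    if (spec$holding == -30) {
      x <- add_train(x, spec$spsc_freq_gaba, spec$spsc_gaba, "gaba", +1)
    }
  }

  if (spec$noise_sd > 0) x <- x + rnorm(n, 0, spec$noise_sd)

  tr <- new_trace(x, dt = spec$dt, mode = spec$mode,
                  meta = list(seed = spec$seed, holding = spec$holding,
                              baseline = spec$baseline))
  attr(tr, "truth") <- list(gdps = gdps, pscs = dplyr::arrange(pscs, .data$onset))
  tr
}

#' Generate a matched control / GABA voltage-ramp current pair
#'
#' Ideal-clamp current synthesis for the reversal-potential ramp:
#' the control trace is the leak current \eqn{g_L (V(t) - E_L)}, the second
#' trace adds a GABAergic conductance \eqn{g_{GABA} (V(t) - E_{rev})};
#' Gaussian current noise is added independently to both.
#'
#' @param g_leak,e_leak Leak conductance (nS) and reversal (mV).
#' @param g_gaba,e_rev GABA conductance (nS) and reversal (mV).
#' @param spec A [ramp_spec()].
#' @param dt Sampling interval, ms.
#' @param tail_ms Recording tail after the ramp, ms.
#' @param noise_sd Current noise SD, pA.
#' @param seed Integer seed.
#'
#' @return A list with elements `control` and `gaba` (`ephys_trace`s).
#' @export
generate_ramp_pair <- function(g_leak = 1, e_leak = -55, g_gaba = 2, e_rev = -30,
                               spec = ramp_spec(), dt = 0.1, tail_ms = 20,
                               noise_sd = 0, seed = 1) {
  withr_seed(seed)
  total <- spec$pre_step_duration + spec$ramp_duration + tail_ms
  t <- seq(0, total, by = dt)
  v <- ramp_command_voltage(spec, t)
  i_ctrl <- g_leak * (v - e_leak)
  i_gaba <- i_ctrl + g_gaba * (v - e_rev)
  if (noise_sd > 0) {
    i_ctrl <- i_ctrl + rnorm(length(t), 0, noise_sd)
    i_gaba <- i_gaba + rnorm(length(t), 0, noise_sd)
  }
  list(
    control = new_trace(i_ctrl, dt = dt, mode = "voltage_clamp",
                        meta = list(seed = seed, role = "control")),
    gaba = new_trace(i_gaba, dt = dt, mode = "voltage_clamp",
                     meta = list(seed = seed, role = "gaba"))
  )
}
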