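#' Passive membrane parameters
#'
#' @param ra Specific axial resistance, Ohm cm.
#' @param rm Specific membrane resistance, kOhm cm^2.
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param e_leak Leak reversal potential, mV.
#'
#' @return A list of class `passive_params`.
#' @export
passive_params <- function(ra = 34.5, rm = 2, cm = 1, e_leak = -53) {
  if (ra <= 0 || rm <= 0 || cm <= 0) {
    abort("passive parameters must be positive", class = "chloridyn_invalid_parameter")
  }
  structure(list(ra = ra, rm = rm, cm = cm, e_leak = e_leak),
            class = "passive_params")
}

#' Spatially discretize a morphology into a cable model
#'
#' Splits each section into an odd number of iso-potential segments
#' following the d_lambda rule (segment length at most `d_lambda` times the
#' AC length constant at 100 Hz), computes per-segment membrane area, leak
#' conductance, capacitance and axial coupling, and builds the concentric
#' shell geometry used for radial intracellular diffusion: each segment's
#' radius is divided into `n_shells` equal increments (a cylindrical core
#' plus `n_shells - 1` annular shells); synaptic ion flux enters the
#' outermost shell.
#'
#' @param morph A [morphology()].
#' @param passive A [passive_params()].
#' @param d_lambda Fraction of the 100 Hz length constant per segment.
#' @param nseg Optional fixed segment count per section (scalar, forced odd),
#'   overriding the d_lambda rule.
#' @param n_shells Number of radial compartments (core + shells).
#'
#' @return A list of class `cable_model` with the segment table and shell
#'   geometry.
#' @export
cable_model <- function(morph, passive = passive_params(), d_lambda = 0.1,
                        nseg = NULL, n_shells = 5) {
  stopifnot(inherits(morph, "neuro_morphology"))
  if (any(morph$length <= 0)) abort("zero-length section", class = "chloridyn_build_error")

  # topological order: parents before children
  ord <- integer(0)
  remaining <- morph$id
  placed <- c()
  while (length(remaining)) {
    ready <- remaining[is.na(morph$parent_id[match(remaining, morph$id)]) |
                         morph$parent_id[match(remaining, morph$id)] %in% placed]
    if (!length(ready)) abort("morphology is not a tree", class = "chloridyn_build_error")
    ord <- c(ord, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  morph <- morph[match(ord, morph$id), ]

  segs <- list()
  sec_first_seg <- sec_nseg <- setNames(integer(nrow(morph)), morph$id)
  next_seg <- 0L
  for (r in seq_len(nrow(morph))) {
    sec <- morph[r, ]
    if (is.null(nseg)) {
      dmean <- (sec$diam_prox + sec$diam_dist) / 2
      lambda100 <- 1e5 * sqrt(dmean / (4 * pi * 100 * passive$ra * passive$cm))
      ns <- as.integer((sec$length / (d_lambda * lambda100) + 0.9) %/% 2) * 2L + 1L
    } else {
      ns <- as.integer(nseg) %/% 2L * 2L + 1L
    }
    if (sec$region == "soma") ns <- 1L
    sec_first_seg[as.character(sec$id)] <- next_seg
    sec_nseg[as.character(sec$id)] <- ns
    pos <- (seq_len(ns) - 0.5) / ns
    diam <- sec$diam_prox + (sec$diam_dist - sec$diam_prox) * pos
    len <- sec$length / ns
    if (is.na(sec$parent_id)) {
      par_seg <- c(-1L, next_seg + seq_len(ns - 1L) - 1L)
      same_sec <- rep(TRUE, ns)
    } else {
      pkey <- as.character(sec$parent_id)
      pns <- sec_nseg[pkey]
      attach_seg <- sec_first_seg[pkey] +
        min(pns - 1L, floor(min(max(sec$parent_pos, 0), 0.999999) * pns))
      par_seg <- c(attach_seg, next_seg + seq_len(ns - 1L) - 1L)
      same_sec <- c(FALSE, rep(TRUE, ns - 1L))
    }
    segs[[r]] <- tibble(
      seg = next_seg + seq_len(ns) - 1L,
      section_id = sec$id, region = sec$region,
      parent = as.integer(par_seg), same_section = same_sec,
      pos = pos, length = len, diam = diam,
      area = pi * diam * len,
      cross_area = pi * diam^2 / 4
    )
    next_seg <- next_seg + ns
  }
  segs <- dplyr::bind_rows(segs)

  # membrane properties: pF = 0.01 cm A; nS = 0.01 A / Rm
  segs$cm_pF <- 0.01 * passive$cm * segs$area
  segs$g_leak <- 0.01 * segs$area / passive$rm

  # axial conductance to parent through the two half-segments (nS)
  half_res <- function(i) 0.01 * passive$ra * (segs$length[i] / 2) / segs$cross_area[i] # MOhm
  g_ax <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    p <- segs$parent[i] + 1L
    if (p == 0L) next
    g_ax[i] <- 1000 / (half_res(i) + half_res(p))
  }
  segs$g_ax <- g_ax

  # path distance of each segment center from the soma center
  dist <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    p <- segs$parent[i] + 1L
    dist[i] <- if (p == 0L) 0 else dist[p] + segs$length[p] / 2 + segs$length[i] / 2
  }
  segs$dist <- dist

  # concentric shell geometry
  r <- segs$diam / 2
  dr <- r / n_shells
  k <- seq_len(n_shells) - 1
  shell_vol <- outer(dr^2 * segs$length, (k + 1)^2 - k^2) * pi
  iface_area <- if (n_shells > 1) {
    outer(dr * segs$length, 2 * pi * (k[-1]))
  } else {
    matrix(0, nrow(segs), 0)
  }
  ring_area <- outer(dr^2, (k + 1)^2 - k^2) * pi

  structure(list(segments = segs, passive = passive, n_shells = n_shells,
                 shell_vol = shell_vol, iface_area = iface_area,
                 ring_area = ring_area, dr = dr, morphology = morph),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat(sprintf("<cable_model> %d sections, %d segments, %d radial compartments\n",
              nrow(x$morphology), nrow(x$segments), x$n_shells))
  cat(sprintf("  membrane area %.0f um^2 (capacitance %.1f pF), dendritic volume %.0f um^3\n",
              sum(x$segments$area), sum(x$segments$cm_pF),
              sum(x$shell_vol[x$segments$region == "dendrite", ])))
  invisible(x)
}

#' Split GABA-A current into chloride and bicarbonate branches
#'
#' \deqn{I_{GABA} = \frac{1}{1+P} g (V - E_{Cl}) + \frac{P}{1+P} g (V - E_{HCO3})}
#' with the fractional conductance \eqn{P = P_{HCO3}/P_{Cl}}.
#'
#' @param v Membrane potential, mV.
#' @param g_t Total GABA-A conductance, nS.
#' @param e_cl,e_hco3 Branch reversal potentials, mV.
#' @param p Fractional bicarbonate conductance (dimensionless, >= 0).
#'
#' @return A tibble with `i_cl`, `i_hco3` and `i_total` in pA.
#' @export
gaba_current <- function(v, g_t, e_cl, e_hco3, p = 0.44) {
  if (any(p < 0)) abort("`p` must be >= 0", class = "chloridyn_invalid_parameter")
  i_cl <- g_t / (1 + p) * (v - e_cl)
  i_hco3 <- g_t * p / (1 + p) * (v - e_hco3)
  tibble(i_cl = i_cl, i_hco3 = i_hco3, i_total = i_cl + i_hco3)
}

#' Intracellular ion dynamics settings for a simulation
#'
#' @param cl_init Initial intracellular chloride, mM (scalar or one value
#'   per segment).
#' @param hco3_init Initial intracellular bicarbonate, mM.
#' @param cl_rest,hco3_rest Transport set points, mM (default: the scalar
#'   initial values).
#' @param tau_uptake Relaxation time constant when the concentration is
#'   below rest (uptake, NKCC1-like), s.
#' @param tau_extrusion Time constant above rest (passive efflux), s.
#' @param d_coef Cytoplasmic diffusion coefficient for both anions,
#'   um^2/ms.
#' @param cl_e,hco3_e Static extracellular reservoir concentrations, mM.
#' @param temperature Temperature for the Nernst reversals, degC.
#' @param dynamic If `FALSE`, concentrations are frozen and the branch
#'   reversals stay at their initial values (the static-ion protocols).
#' @param transport,longitudinal Toggle the relaxation transport and the
#'   axial diffusion.
#'
#' @return A list of class `ion_dynamics`.
#' @export
ion_dynamics <- function(cl_init = 30, hco3_init = 14.1,
                         cl_rest = NULL, hco3_rest = 14.1,
                         tau_uptake = 174, tau_extrusion = 321,
                         d_coef = 2, cl_e = 133.5, hco3_e = 24,
                         temperature = 31,
                         dynamic = TRUE, transport = TRUE, longitudinal = TRUE) {
  if (tau_uptake <= 0 || tau_extrusion <= 0) {
    abort("transport time constants must be positive", class = "chloridyn_invalid_parameter")
  }
  if (is.null(cl_rest)) cl_rest <- if (length(cl_init) == 1L) cl_init else 30
  structure(list(cl_init = cl_init, hco3_init = hco3_init,
                 cl_rest = cl_rest, hco3_rest = hco3_rest,
                 tau_uptake = tau_uptake, tau_extrusion = tau_extrusion,
                 d_coef = d_coef, cl_e = cl_e, hco3_e = hco3_e,
                 temperature = temperature, dynamic = dynamic,
                 transport = transport, longitudinal = longitudinal),
            class = "ion_dynamics")
}

#' Single-electrode voltage clamp specification
#'
#' The electrode injects \eqn{i = (V_{cmd} - V_{soma}) / R_s} at the soma
#' and that current is reported as the recorded signal.
#'
#' @param rs Access (series) resistance, MOhm.
#' @param command A function of time (ms) returning the command potential
#'   (mV), or a constant.
#'
#' @return A list of class `clamp_spec`.
#' @export
sevc_clamp <- function(rs, command) {
  if (rs <= 0) abort("`rs` must be > 0", class = "chloridyn_config_error")
  if (!is.function(command)) {
    v <- command
    command <- function(t) rep(v, length(t))
  }
  structure(list(mode = "sevc", rs = rs, command = command), class = "clamp_spec")
}

#' @rdname sevc_clamp
#' @param current A function of time (ms) returning injected somatic
#'   current (pA), or a constant (default 0).
#' @export
current_clamp <- function(current = 0) {
  if (!is.function(current)) {
    i <- current
    current <- function(t) rep(i, length(t))
  }
  structure(list(mode = "current_clamp", command = current), class = "clamp_spec")
}

#' Build a synapse table
#'
#' Synapses are specified per row: GABA-A synapses carry a fractional
#' bicarbonate conductance `p_split` and draw their branch reversals from
#' the local outermost-shell concentrations; AMPA synapses have a fixed
#' reversal `e_rev`.
#'
#' @param seg 0-based segment index (use [seg_at()] to map a section
#'   position or a path distance to a segment).
#' @param kind `"gaba"` or `"ampa"`.
#' @param g_peak Peak conductance, nS.
#' @param tau_rise,tau_decay Two-exponential kinetics, ms.
#' @param onset Activation time, ms.
#' @param p_split Fractional bicarbonate conductance (GABA only).
#' @param e_rev Reversal potential (AMPA only), mV.
#'
#' @return A tibble, one row per synapse.
#' @export
synapse <- function(seg, kind = c("gaba", "ampa"), g_peak, tau_rise = NULL,
                    tau_decay = NULL, onset = 0, p_split = 0.44, e_rev = 0) {
  kind <- match.arg(kind)
  if (is.null(tau_rise)) tau_rise <- if (kind == "gaba") 0.5 else 0.1
  if (is.null(tau_decay)) tau_decay <- if (kind == "gaba") 80 else 11
  if (any(tau_decay <= tau_rise) || any(tau_rise <= 0)) {
    abort("need tau_decay > tau_rise > 0", class = "chloridyn_invalid_parameter")
  }
  if (any(g_peak < 0)) abort("`g_peak` must be >= 0", class = "chloridyn_invalid_parameter")
  tibble(seg = as.integer(seg), kind = kind, g_peak = g_peak,
         tau_rise = tau_rise, tau_decay = tau_decay, onset = onset,
         p_split = ifelse(kind == "gaba", p_split, -1), e_rev = e_rev)
}

#' Map a location to a segment index
#'
#' @param model A [cable_model()].
#' @param section Section id; with `pos`, the fractional position along it.
#' @param pos Position along the section (0-1).
#' @param distance Alternatively, a path distance from the soma (um): the
#'   dendritic segment whose center is closest is returned.
#'
#' @return 0-based segment index.
#' @export
seg_at <- function(model, section = NULL, pos = 0.5, distance = NULL) {
  segs <- model$segments
  if (!is.null(distance)) {
    d <- segs[segs$region == "dendrite", ]
    return(d$seg[which.min(abs(d$dist - distance))])
  }
  s <- segs[segs$section_id == section, ]
  if (!nrow(s)) abort("no such section", class = "chloridyn_invalid_parameter")
  s$seg[which.min(abs(s$pos - pos))]
}

#' Simulate a cable model
#'
#' Advances the branched passive cable with synapses, optional
#' single-electrode clamp and dynamic intracellular Cl-/HCO3- (see
#' [cable_model()] for the shell geometry and the package vignette for the
#' integration scheme).
#'
#' @param model A [cable_model()].
#' @param duration Simulated time, ms.
#' @param dt Time step, ms.
#' @param synapses A tibble from [synapse()] (rows may be bound together),
#'   or `NULL`.
#' @param clamp A [sevc_clamp()] / [current_clamp()] (default: free-running
#'   current clamp with no injection).
#' @param ions An [ion_dynamics()].
#' @param record_dt Recording interval, ms.
#' @param v_init Initial potential, mV (default: the leak reversal).
#'
#' @return A tibble of class `cable_sim` with columns `time_ms`, `v_soma`
#'   (mV), `i_clamp` (pA), `cl_dend`, `hco3_dend` (volume-weighted mean
#'   dendritic concentrations, mM), `i_cl_total`, `i_hco3_total` (summed
#'   synaptic branch currents, pA). The final state is attached as
#'   attribute `state` (list of `v`, `cl`, `hco3`).
#' @export
simulate_cable <- function(model, duration, dt = 0.025, synapses = NULL,
                           clamp = current_clamp(), ions = ion_dynamics(),
                           record_dt = 1, v_init = NULL) {
  stopifnot(inherits(model, "cable_model"))
  segs <- model$segments
  nseg <- nrow(segs)
  record_every <- max(1L, round(record_dt / dt))
  nsteps <- ceiling(duration / dt / record_every) * record_every

  if (is.null(synapses)) {
    synapses <- tibble(seg = integer(), kind = character(), g_peak = double(),
                       tau_rise = double(), tau_decay = double(),
                       onset = double(), p_split = double(), e_rev = double())
  }
  if (any(synapses$seg < 0 | synapses$seg >= nseg)) {
    abort("synapse segment index out of range", class = "chloridyn_invalid_parameter")
  }

  tgrid <- (seq_len(nsteps) - 1) * dt
  if (clamp$mode == "sevc") {
    clamp_mode <- 1L
    cmd <- clamp$command(tgrid)
    i_inj <- numeric(nsteps)
    rs <- clamp$rs
  } else {
    clamp_mode <- 0L
    cmd <- numeric(nsteps)
    i_inj <- clamp$command(tgrid)
    rs <- 1
  }

  expand_conc <- function(x) {
    if (length(x) == 1L) x <- rep(x, nseg)
    if (length(x) != nseg) {
      abort("initial concentration must be scalar or one value per segment",
            class = "chloridyn_invalid_parameter")
    }
    matrix(x, nseg, model$n_shells)
  }
  cl0 <- expand_conc(ions$cl_init)
  hco30 <- expand_conc(ions$hco3_init)
  if (any(cl0 <= 0) || any(hco30 <= 0)) {
    abort("concentrations must be > 0", class = "chloridyn_invalid_parameter")
  }

  if (is.null(v_init)) v_init <- model$passive$e_leak

  res <- simulate_cable_cpp(
    parent = segs$parent, same_section = segs$same_section,
    g_ax = segs$g_ax, g_leak = segs$g_leak, cm = segs$cm_pF,
    seg_len = segs$length,
    shell_vol = model$shell_vol, iface_area = model$iface_area,
    ring_area = model$ring_area, dr = model$dr,
    is_dend = segs$region == "dendrite",
    e_leak = model$passive$e_leak, dt = dt, nsteps = nsteps,
    record_every = record_every,
    syn_seg = synapses$seg, syn_gpeak = synapses$g_peak,
    syn_taur = synapses$tau_rise, syn_taud = synapses$tau_decay,
    syn_onset = synapses$onset, syn_p = synapses$p_split,
    syn_erev = synapses$e_rev,
    clamp_mode = clamp_mode, rs = rs, cmd = cmd, i_inj = i_inj,
    cl_init = cl0, hco3_init = hco30,
    cl_rest = ions$cl_rest, hco3_rest = ions$hco3_rest,
    tau_up_ms = ions$tau_uptake * 1000, tau_ex_ms = ions$tau_extrusion * 1000,
    d_coef = ions$d_coef, cl_e = ions$cl_e, hco3_e = ions$hco3_e,
    rtf = rtf_mV(ions$temperature),
    dynamic_ions = ions$dynamic, transport_on = ions$transport,
    longitudinal_on = ions$longitudinal, v_init = v_init
  )

  out <- tibble(time_ms = res$time_ms, v_soma = res$v_soma,
                i_clamp = res$i_clamp, cl_dend = res$cl_dend,
                hco3_dend = res$hco3_dend, i_cl_total = res$i_cl_total,
                i_hco3_total = res$i_hco3_total)
  structure(out,
            state = list(v = res$v_final, cl = res$cl_final, hco3 = res$hco3_final),
            model = model, ions = ions, dt = dt,
            class = c("cable_sim", class(out)))
}

#' Volume-weighted mean dendritic concentration of a state
#'
#' @param model A [cable_model()].
#' @param state A state list as attached to a simulation result
#'   (`attr(sim, "state")`), or a concentration matrix (segments x shells).
#' @param ion `"cl"` or `"hco3"`.
#'
#' @return Mean concentration over all dendritic shells, mM.
#' @export
mean_dendritic_concentration <- function(model, state, ion = c("cl", "hco3")) {
  ion <- match.arg(ion)
  C <- if (is.list(state)) state[[ion]] else state
  dend <- model$segments$region == "dendrite"
  sum(model$shell_vol[dend, , drop = FALSE] * C[dend, , drop = FALSE]) /
    sum(model$shell_vol[dend, , drop = FALSE])
}

#' Total intracellular anion content of a state
#'
#' @inheritParams mean_dendritic_concentration
#' @return Amount in attomol-scale units of mM x um^3 (1 mM um^3 =
#'   1e-18 mol); useful for mass-conservation checks.
#' @export
total_moles <- function(model, state, ion = c("cl", "hco3")) {
  ion <- match.arg(ion)
  C <- if (is.list(state)) state[[ion]] else state
  sum(model$shell_vol * C)
}

#' Steady-state input resistance at the soma
#'
#' Solves the passive conductance matrix for a unit somatic current
#' injection.
#'
#' @param model A [cable_model()].
#' @return Input resistance, GOhm.
#' @export
input_resistance <- function(model) {
  segs <- model$segments
  n <- nrow(segs)
  G <- diag(segs$g_leak, n) # nS
  for (i in seq_len(n)) {
    p <- segs$parent[i] + 1L
    if (p == 0L) next
    G[i, i] <- G[i, i] + segs$g_ax[i]
    G[p, p] <- G[p, p] + segs$g_ax[i]
    G[i, p] <- G[i, p] - segs$g_ax[i]
    G[p, i] <- G[p, i] - segs$g_ax[i]
  }
  b <- numeric(n); b[1] <- 1000 # pA
  v <- solve(G, b)              # mV
  v[1] / 1000                   # mV/pA = GOhm
}
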