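#' Ionic conditions of the GABA-A reversal potential
#'
#' Bundles the concentrations and relative permeabilities that enter the
#' Goldman-Hodgkin-Katz (GHK) expression for the mixed Cl-/HCO3- GABA-A
#' reversal potential. Defaults reproduce the recording conditions of
#' immature CA3 pyramidal neurons at near-physiological temperature:
#' \eqn{[Cl^-]_e} = 133.5 mM, \eqn{[HCO_3^-]_i} = 14.1 mM,
#' \eqn{[HCO_3^-]_e} = 24 mM, \eqn{P_{HCO3}/P_{Cl}} = 0.44, 31 degC.
#'
#' @param cl_i Intracellular chloride, mM.
#' @param cl_e Extracellular chloride, mM.
#' @param hco3_i Intracellular bicarbonate, mM.
#' @param hco3_e Extracellular bicarbonate, mM.
#' @param p_hco3 Relative bicarbonate permeability \eqn{P_{HCO3}/P_{Cl}}
#'   (dimensionless, \eqn{P_{Cl} = 1}).
#' @param temperature Bath temperature, degrees Celsius.
#'
#' @return A list of class `ion_state`.
#' @export
#' @examples
#' s <- ion_state(cl_i = 10)
#' ghk_egaba(s)
ion_state <- function(cl_i, cl_e = 133.5, hco3_i = 14.1, hco3_e = 24,
                      p_hco3 = 0.44, temperature = 31) {
  conc <- c(cl_i = cl_i, cl_e = cl_e, hco3_i = hco3_i, hco3_e = hco3_e)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("all concentrations must be finite and > 0", class = "chloridyn_invalid_parameter")
  }
  if (!is.finite(p_hco3) || p_hco3 < 0) {
    abort("`p_hco3` must be >= 0", class = "chloridyn_invalid_parameter")
  }
  if (!is.finite(temperature) || temperature <= 0 || temperature >= 45) {
    abort("`temperature` must lie in (0, 45) degC", class = "chloridyn_invalid_parameter")
  }
  structure(
    list(cl_i = cl_i, cl_e = cl_e, hco3_i = hco3_i, hco3_e = hco3_e,
         p_hco3 = p_hco3, temperature = temperature),
    class = "ion_state"
  )
}

#' @export
print.ion_state <- function(x, ...) {
  cat("<ion_state>\n")
  cat(sprintf("  [Cl-]i %.4g  [Cl-]e %.4g  [HCO3-]i %.4g  [HCO3-]e %.4g mM\n",
              x$cl_i, x$cl_e, x$hco3_i, x$hco3_e))
  cat(sprintf("  P_HCO3/P_Cl %.3g   T %.3g degC   E_GABA %.2f mV\n",
              x$p_hco3, x$temperature, ghk_egaba(x)))
  invisible(x)
}

#' Intracellular bicarbonate from blood-gas parameters
#'
#' Henderson-Hasselbalch conversion of a CO2 partial pressure and an
#' intracellular pH to the intracellular bicarbonate concentration:
#' \deqn{[HCO_3^-]_i = s \cdot pCO_2 \cdot 10^{pH_i - pK_s}}
#' where `s` is the CO2 solubility. Defaults (38 mmHg, pH 7.2, pKs 6.128,
#' s = 0.0314 mM/mmHg) give 14.1 mM.
#'
#' @param pco2 CO2 partial pressure, mmHg.
#' @param ph_i Intracellular pH.
#' @param pks Apparent pK of the CO2/bicarbonate system.
#' @param co2_solubility CO2 solubility, mM per mmHg.
#'
#' @return Intracellular bicarbonate concentration, mM.
#' @export
#' @examples
#' hco3_from_blood_gas() # 14.1 mM
hco3_from_blood_gas <- function(pco2 = 38, ph_i = 7.2, pks = 6.128,
                                co2_solubility = 0.0314) {
  if (any(!is.finite(c(pco2, ph_i, pks, co2_solubility))) ||
      pco2 <= 0 || co2_solubility <= 0) {
    abort("`pco2` and `co2_solubility` must be finite and > 0",
          class = "chloridyn_invalid_parameter")
  }
  if (ph_i <= 6 || ph_i >= 8) {
    abort("`ph_i` must lie in (6, 8)", class = "chloridyn_invalid_parameter")
  }
  co2_solubility * pco2 * 10^(ph_i - pks)
}

#' Nernst equilibrium potential
#'
#' \deqn{E = \frac{RT}{zF}\ln\frac{c_{out}}{c_{in}}}
#' returned in mV. For a monovalent anion (`valence = -1`) a higher external
#' concentration gives a negative potential.
#'
#' @param c_in,c_out Internal / external concentration, mM (same units).
#' @param valence Ion valence (integer, e.g. -1 for Cl- and HCO3-).
#' @param temperature Temperature, degrees Celsius.
#'
#' @return Equilibrium potential, mV. Vectorised over concentrations.
#' @export
#' @examples
#' nernst(30, 133.5, -1, 31) # about -39.2 mV
nernst <- function(c_in, c_out, valence = -1, temperature = 31) {
  if (any(!is.finite(c_in)) || any(!is.finite(c_out)) ||
      any(c_in <= 0) || any(c_out <= 0)) {
    abort("concentrations must be finite and > 0", class = "chloridyn_domain_error")
  }
  if (valence == 0) abort("`valence` must be non-zero", class = "chloridyn_domain_error")
  rtf_mV(temperature) / valence * log(c_out / c_in)
}

#' GABA-A reversal potential from the GHK equation
#'
#' Mixed-anion reversal potential of the GABA-A receptor,
#' \deqn{E_{GABA} = -\frac{RT}{F}\ln
#'   \frac{[Cl^-]_e + P\,[HCO_3^-]_e}{[Cl^-]_i + P\,[HCO_3^-]_i}}
#' with \eqn{P = P_{HCO3}/P_{Cl}}. Higher internal anion concentrations make
#' the reversal less negative; with `p_hco3 = 0` this collapses to the Cl-
#' Nernst potential.
#'
#' @param state An [ion_state()], or `cl_i` in mM if the remaining fields
#'   take their defaults.
#' @inheritParams ion_state
#'
#' @return \eqn{E_{GABA}} in mV.
#' @export
#' @examples
#' ghk_egaba(10) # about -57.3 mV
ghk_egaba <- function(state, cl_e = 133.5, hco3_i = 14.1, hco3_e = 24,
                      p_hco3 = 0.44, temperature = 31) {
  if (!inherits(state, "ion_state")) {
    state <- ion_state(cl_i = state, cl_e = cl_e, hco3_i = hco3_i,
                       hco3_e = hco3_e, p_hco3 = p_hco3, temperature = temperature)
  }
  num <- state$cl_e + state$p_hco3 * state$hco3_e
  den <- state$cl_i + state$p_hco3 * state$hco3_i
  -rtf_mV(state$temperature) * log(num / den)
}

#' Intracellular chloride from a measured GABA-A reversal potential
#'
#' Exact algebraic inverse of [ghk_egaba()] in \eqn{[Cl^-]_i}:
#' \deqn{[Cl^-]_i = ([Cl^-]_e + P\,[HCO_3^-]_e)\,e^{E_{GABA} F / RT}
#'   - P\,[HCO_3^-]_i.}
#' A reversal potential so positive that the implied chloride would be
#' non-positive raises an infeasible-reversal error.
#'
#' @param e_gaba Measured reversal potential, mV.
#' @inheritParams ion_state
#'
#' @return \eqn{[Cl^-]_i} in mM.
#' @export
#' @examples
#' cl_from_egaba(ghk_egaba(50)) # 50
cl_from_egaba <- function(e_gaba, cl_e = 133.5, hco3_i = 14.1, hco3_e = 24,
                          p_hco3 = 0.44, temperature = 31) {
  if (any(!is.finite(e_gaba))) {
    abort("`e_gaba` must be finite", class = "chloridyn_domain_error")
  }
  cl_i <- (cl_e + p_hco3 * hco3_e) * exp(e_gaba / rtf_mV(temperature)) -
    p_hco3 * hco3_i
  if (any(cl_i <= 0)) {
    abort(
      "reversal potential implies a non-positive [Cl-]i (infeasible reversal)",
      class = "chloridyn_infeasible_reversal"
    )
  }
  cl_i
}

#' Chloride driving force during an event
#'
#' \eqn{DF_{Cl} = E_m - E_{GABA}}: a positive driving force means GABA-A
#' activation at `e_m` drives anion influx (chloride accumulation), a
#' negative one drives efflux.
#'
#' @param e_m Membrane potential during the event, mV.
#' @param e_gaba GABA-A reversal potential, mV.
#'
#' @return A tibble with columns `e_m`, `e_gaba`, `df_cl` (mV).
#' @export
#' @examples
#' driving_force(-46.9, -57.3)
driving_force <- function(e_m, e_gaba) {
  tibble(e_m = e_m, e_gaba = e_gaba, df_cl = e_m - e_gaba)
}

#' Chord conductance from a peak current
#'
#' Ohmic estimate \eqn{g = |I_{peak} / (E_m - E_{rev})|}; with current in pA
#' and potentials in mV the result is in nS.
#'
#' @param i_peak Peak current, pA.
#' @param e_m Holding / membrane potential, mV.
#' @param e_rev Reversal potential of the current, mV.
#'
#' @return Conductance, nS.
#' @export
#' @examples
#' conductance_from_current(46.9, 0, -60) # 0.78 nS
conductance_from_current <- function(i_peak, e_m, e_rev) {
  if (any(e_m == e_rev)) {
    abort("zero driving force: `e_m` equals `e_rev`, conductance is undefined",
          class = "chloridyn_zero_driving_force")
  }
  abs(i_peak / (e_m - e_rev))
}

#' Number of unitary synaptic inputs equivalent to an event charge
#'
#' Divides the charge transferred by a compound event (pC) by the charge of a
#' unitary post-synaptic current (fC) and rounds to the nearest integer.
#'
#' @param event_charge_pC Compound event charge, pC.
#' @param unitary_charge_fC Unitary event charge, fC.
#'
#' @return Integer count of equivalent unitary inputs.
#' @export
#' @examples
#' equivalent_input_count(88, 872.3) # 101
equivalent_input_count <- function(event_charge_pC, unitary_charge_fC) {
  if (any(!is.finite(unitary_charge_fC)) || any(unitary_charge_fC <= 0)) {
    abort("`unitary_charge_fC` must be > 0", class = "chloridyn_domain_error")
  }
  as.integer(round(event_charge_pC * 1000 / unitary_charge_fC))
}
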