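#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the time courses of a simulated network event
#'
#' @param x A `gdp_simulation` from [run_gdp_simulation()].
#' @param ... Unused.
#'
#' @return A long tibble with columns `time_ms`, `variable`
#'   (`v_soma`, `cl_dend`, `hco3_dend`) and `value`.
#' @export
tidy.gdp_simulation <- function(x, ...) {
  tidyr::pivot_longer(x$timeseries, -"time_ms",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a simulated network event
#'
#' @inheritParams tidy.gdp_simulation
#'
#' @return A one-row tibble: initial concentrations, peak signed changes of
#'   the mean dendritic concentrations, minimum bicarbonate, peak somatic
#'   potential, synapse counts.
#' @export
glance.gdp_simulation <- function(x, ...) {
  tibble(cl_init = x$cl_init, hco3_init = x$hco3_init,
         delta_cl = x$delta_cl, delta_hco3 = x$delta_hco3,
         hco3_min = x$hco3_min, v_peak = x$v_peak,
         n_gaba = x$stim$n_gaba, n_ampa = x$stim$n_ampa,
         n_seg = x$n_seg)
}

#' Tidy a cable simulation result
#'
#' @param x A `cable_sim` from [simulate_cable()].
#' @param ... Unused.
#' @return A long tibble of the recorded variables against time.
#' @export
tidy.cable_sim <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time_ms",
                      names_to = "variable", values_to = "value")
}
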