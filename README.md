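# chloridyn

Activity-dependent chloride plasticity in immature neurons: tools to turn
GABA-A reversal potentials into intracellular chloride concentrations, to
analyze the patch-clamp recordings such measurements come from, and to
simulate — in a biophysically explicit compartmental model — how the massive
GABAergic conductance of a network event moves chloride and bicarbonate
inside a developing pyramidal cell.

## Who this is for

Cellular neurophysiologists and modellers working on chloride homeostasis,
depolarizing GABA and early network activity (giant depolarizing potentials,
GDPs) in the immature hippocampus, and anyone who needs a tested,
self-contained implementation of:

* the **Goldman–Hodgkin–Katz determination of [Cl⁻]ᵢ from E_GABA** with
  bicarbonate permeability,

  E_GABA = −(RT/F) · ln( ([Cl⁻]ₑ + P·[HCO₃⁻]ₑ) / ([Cl⁻]ᵢ + P·[HCO₃⁻]ᵢ) ),
  P = P_HCO3/P_Cl = 0.44,

  plus its exact inverse, the Nernst and Henderson–Hasselbalch relations,
  driving forces, chord conductances and charge-equivalence counts;
* **trace analysis**: the online (microcontroller-style) floating-average
  GDP detector, action-potential counting, charge integration,
  voltage-ramp E_GABA extraction by control/GABA subtraction, PSC
  detection with rise/decay/charge features, and derivative-based
  separation of outward/inward events;
* a **multicompartment passive cable simulator** with two-exponential
  GABA/AMPA synapses, single-electrode voltage clamp (explicit access
  resistance), and dynamic intracellular Cl⁻/HCO₃⁻: four concentric shells
  plus core per segment, radial and longitudinal diffusion (D = 2 µm²/ms),
  and bimodal relaxation transport (τ = 174 s uptake / 321 s extrusion);
* the **in-silico protocols** built on it: access-resistance scan,
  space-clamp bias mapping, GDP-scale synaptic barrages (534 GABA × 0.789
  nS + 107 AMPA × 0.509 nS), and charge calibration;
* **seeded synthetic data**: surrogate immature CA3 morphologies (SWC
  in/out) and synthetic current-/voltage-clamp recordings with known
  ground truth.

Everything takes and returns tibbles, pipes cleanly, and exposes
`tidy()`/`glance()`/`autoplot()` methods for the simulation results.

## Worked example

Ion physics — what reversal potential does a 10 mM cell show, and what
chloride does a measured −45.4 mV reversal imply?

```r
library(chloridyn)

ghk_egaba(10)          # E_GABA at [Cl-]i = 10 mM, standard solutions
#> [1] -57.26429
cl_from_egaba(-45.4)   # invert a measured reversal potential
#> [1] 19.27746
hco3_from_blood_gas()  # [HCO3-]i from 38 mmHg CO2, pH 7.2
#> [1] 14.08359
```

−57.3 mV is why cells with ~10 mM internal chloride reverse near the
−60 mV holding potential used to isolate glutamatergic currents; 19.3 mM
is the chloride concentration a −45.4 mV reversal implies once the
bicarbonate leak through GABA-A receptors is accounted for.

Build a surrogate immature CA3 cell, and ask how much the access
resistance of a perforated-patch electrode distorts a ramp-determined
E_GABA (static 30 mM chloride):

```r
m  <- make_surrogate_morphology(seed = 1)   # 65 pF tapering tree
cm <- cable_model(m)
cm
#> <cable_model> 28 sections, 82 segments, 5 radial compartments
#>   membrane area 6500 um^2 (capacitance 65.0 pF), dendritic volume 1337 um^3

run_rs_experiment(cm)
#> # A tibble: 5 x 2
#>      rs egaba
#>   <dbl> <dbl>
#> 1   0.5 -31.0
#> 2   5   -31.2
#> 3  10   -31.3
#> 4  20   -31.4
#> 5  40   -31.4
```

An 80-fold change in access resistance moves the determined reversal by
well under half a millivolt — the clamp error vanishes at the reversal
because the GABAergic current does. The absolute value sits at the
conductance-weighted mean of the chloride and bicarbonate Nernst
potentials (−31.3 mV here), the reversal a two-branch GABA-A conductance
actually has.

Simulate the ionic consequences of a network event on the same cell:

```r
g10 <- run_gdp_simulation(cm, gdp_stimulus(seed = 11), cl_init = 10)
g10
#> <gdp_simulation>
#>   initial [Cl-]i 10.0 mM, [HCO3-]i 14.1 mM; 534 GABA + 107 AMPA synapses
#>   peak dendritic d[Cl-]i +2.16 mM, d[HCO3-]i -2.38 mM (min 11.72 mM), V peak -49.4 mV
autoplot(g10)   # V_soma and the mean dendritic [Cl-]i / [HCO3-]i time courses
```

At 10 mM initial chloride the event *loads* the dendrites with chloride
(positive driving force ⇒ influx); re-running with `cl_init = 50` drains
it, and at 30 mM the shift nearly vanishes — the direction of GDP-induced
chloride plasticity is set by each cell's own chloride level. Bicarbonate
falls in every case. `glance()` returns these summaries as a one-row
tibble for binding across conditions and seeds.

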