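// Multicompartment passive cable with synaptic conductances and dynamic
// intracellular Cl-/HCO3-.
//
// Numerics: backward-Euler voltage solve on the branched tree (Hines
// elimination, O(n) per step), then an operator-split ion update at the same
// dt: (1) synaptic anion flux into the outermost concentric shell,
// (2) implicit radial inter-shell diffusion (Thomas solve per segment, with
// the constant factorization precomputed), (3) explicit longitudinal
// diffusion between axially adjacent segments (shell-by-shell within a
// section, via the core across branch points), (4) transmembrane transport
// as an exactly integrated first-order relaxation with a bimodal time
// constant (uptake below rest, extrusion above rest).
//
// Units: mV, ms, nS, pA, pF, um, mM; currents follow the physiological
// convention that a positive (outward) anion-channel current is an anion
// influx that raises the intracellular concentration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.0; // C/mol

// [[Rcpp::export]]
List simulate_cable_cpp(
    IntegerVector parent,       // nseg, 0-based, -1 for root (soma)
    LogicalVector same_section, // segment lies in the same section as parent
    NumericVector g_ax,         // nS, axial conductance to parent
    NumericVector g_leak,       // nS
    NumericVector cm,           // pF
    NumericVector seg_len,      // um
    NumericMatrix shell_vol,    // nseg x nshell, col 0 = core, last = outermost
    NumericMatrix iface_area,   // nseg x (nshell-1), between shells k and k+1
    NumericMatrix ring_area,    // nseg x nshell, annulus cross-sections
    NumericVector dr,           // um, radial increment per segment
    LogicalVector is_dend,
    double e_leak, double dt, int nsteps, int record_every,
    IntegerVector syn_seg, NumericVector syn_gpeak,
    NumericVector syn_taur, NumericVector syn_taud,
    NumericVector syn_onset, NumericVector syn_p, // p >= 0: GABA split; p < 0: fixed reversal
    NumericVector syn_erev,
    int clamp_mode,             // 0 = current clamp, 1 = single-electrode VC
    double rs,                  // MOhm (sevc)
    NumericVector cmd,          // per-step command, mV (sevc)
    NumericVector i_inj,        // per-step injected current at soma, pA (cc)
    NumericMatrix cl_init, NumericMatrix hco3_init, // nseg x nshell
    double cl_rest, double hco3_rest,
    double tau_up_ms, double tau_ex_ms,
    double d_coef, double cl_e, double hco3_e, double rtf,
    bool dynamic_ions, bool transport_on, bool longitudinal_on,
    double v_init) {

  const int nseg = parent.size();
  const int ns = shell_vol.ncol();
  const int nsyn = syn_seg.size();

  // state (row-major: segment i, shell k -> i*ns + k)
  std::vector<double> V(nseg, v_init);
  std::vector<double> cl(nseg * ns), hco3(nseg * ns), vol(nseg * ns);
  for (int i = 0; i < nseg; ++i)
    for (int k = 0; k < ns; ++k) {
      cl[i * ns + k] = cl_init(i, k);
      hco3[i * ns + k] = hco3_init(i, k);
      vol[i * ns + k] = shell_vol(i, k);
    }

  // synapse states: two-exponential as difference of decaying components
  std::vector<double> sA(nsyn, 0.0), sB(nsyn, 0.0), sW(nsyn), fA(nsyn), fB(nsyn);
  std::vector<int> onset_step(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    double tr = syn_taur[s], td = syn_taud[s];
    double tp = tr * td / (td - tr) * std::log(td / tr);
    double norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    sW[s] = syn_gpeak[s] * norm;
    fA[s] = std::exp(-dt / tr);
    fB[s] = std::exp(-dt / td);
    onset_step[s] = (int)std::floor(syn_onset[s] / dt);
  }

  // reversal potentials per segment from the outermost shell
  std::vector<double> e_cl(nseg), e_hco3(nseg);
  auto update_reversals = [&]() {
    for (int i = 0; i < nseg; ++i) {
      e_cl[i] = -rtf * std::log(cl_e / cl[i * ns + ns - 1]);
      e_hco3[i] = -rtf * std::log(hco3_e / hco3[i * ns + ns - 1]);
    }
  };
  update_reversals();

  // transport factors (exact exponential update per step)
  const double f_up = 1.0 - std::exp(-dt / tau_up_ms);
  const double f_ex = 1.0 - std::exp(-dt / tau_ex_ms);

  // precomputed Thomas factorization of the constant radial operator:
  // (I - dt M) per segment; td_m = forward multipliers, td_bi = 1/b',
  // td_c = upper coefficients
  std::vector<double> td_m(nseg * ns, 0.0), td_bi(nseg * ns, 1.0),
      td_c(nseg * ns, 0.0);
  if (ns > 1) {
    std::vector<double> b(ns);
    for (int i = 0; i < nseg; ++i) {
      for (int k = 0; k < ns; ++k) {
        double qlo = (k > 0) ? d_coef * iface_area(i, k - 1) / dr[i] : 0.0;
        double qhi = (k < ns - 1) ? d_coef * iface_area(i, k) / dr[i] : 0.0;
        double vk = vol[i * ns + k];
        b[k] = 1.0 + dt * (qlo + qhi) / vk;
        td_c[i * ns + k] = (k < ns - 1) ? -dt * qhi / vk : 0.0;
        double a = (k > 0) ? -dt * qlo / vk : 0.0;
        if (k > 0) {
          double m = a / b[k - 1];
          b[k] -= m * td_c[i * ns + k - 1];
          td_m[i * ns + k] = m;
        }
      }
      for (int k = 0; k < ns; ++k) td_bi[i * ns + k] = 1.0 / b[k];
    }
  }

  // precomputed longitudinal exchange coefficients (um^3 per mM per step)
  // child i exchanges with parent p over rings 0..lon_nk[i]-1
  std::vector<double> lon_q(nseg * ns, 0.0);
  std::vector<int> lon_nk(nseg, 0);
  for (int i = 1; i < nseg; ++i) {
    int p = parent[i];
    double dx = 0.5 * (seg_len[i] + seg_len[p]);
    int nk = same_section[i] ? ns : 1; // branch points couple via the core
    lon_nk[i] = nk;
    for (int k = 0; k < nk; ++k) {
      double a = 0.5 * (ring_area(i, k) + ring_area(p, k));
      lon_q[i * ns + k] = d_coef * a / dx * dt;
    }
  }

  // recording buffers
  const int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_v(nrec), rec_ic(nrec),
      rec_cld(nrec), rec_hco3d(nrec), rec_icl(nrec), rec_ihco3(nrec);
  double dend_vol = 0.0;
  for (int i = 0; i < nseg; ++i)
    if (is_dend[i])
      for (int k = 0; k < ns; ++k) dend_vol += vol[i * ns + k];

  std::vector<double> g_cl(nseg), g_hco3(nseg), g_ampa(nseg), ge_ampa(nseg);
  std::vector<double> diag(nseg), rhs(nseg);
  std::vector<double> dconc(nseg * ns);

  double i_cl_tot = 0.0, i_hco3_tot = 0.0, i_clamp = 0.0;

  auto mean_dend = [&](std::vector<double> &C) {
    if (dend_vol <= 0) return NA_REAL;
    double s = 0.0;
    for (int i = 0; i < nseg; ++i)
      if (is_dend[i])
        for (int k = 0; k < ns; ++k) s += vol[i * ns + k] * C[i * ns + k];
    return s / dend_vol;
  };

  int ri = 0;
  auto record = [&](int step) {
    rec_t[ri] = step * dt;
    rec_v[ri] = V[0];
    rec_ic[ri] = i_clamp;
    rec_cld[ri] = mean_dend(cl);
    rec_hco3d[ri] = mean_dend(hco3);
    rec_icl[ri] = i_cl_tot;
    rec_ihco3[ri] = i_hco3_tot;
    ++ri;
  };
  record(0);

  for (int step = 0; step < nsteps; ++step) {
    // --- synaptic conductances at t + dt
    std::fill(g_cl.begin(), g_cl.end(), 0.0);
    std::fill(g_hco3.begin(), g_hco3.end(), 0.0);
    std::fill(g_ampa.begin(), g_ampa.end(), 0.0);
    std::fill(ge_ampa.begin(), ge_ampa.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      sA[s] *= fA[s];
      sB[s] *= fB[s];
      if (step == onset_step[s]) { sA[s] += sW[s]; sB[s] += sW[s]; }
      double g = sB[s] - sA[s];
      if (g <= 0) continue;
      int i = syn_seg[s];
      double p = syn_p[s];
      if (p >= 0) { // mixed Cl-/HCO3- GABA-A conductance
        g_cl[i] += g / (1.0 + p);
        g_hco3[i] += g * p / (1.0 + p);
      } else {      // fixed-reversal (AMPA-like)
        g_ampa[i] += g;
        ge_ampa[i] += g * syn_erev[s];
      }
    }

    // --- backward-Euler voltage solve
    for (int i = 0; i < nseg; ++i) {
      diag[i] = cm[i] / dt + g_leak[i] + g_cl[i] + g_hco3[i] + g_ampa[i];
      rhs[i] = cm[i] / dt * V[i] + g_leak[i] * e_leak +
               g_cl[i] * e_cl[i] + g_hco3[i] * e_hco3[i] + ge_ampa[i];
    }
    if (clamp_mode == 1) {
      double gc = 1000.0 / rs; // nS
      diag[0] += gc;
      rhs[0] += gc * cmd[step];
    } else {
      rhs[0] += i_inj[step];
    }
    for (int i = 1; i < nseg; ++i) {
      diag[i] += g_ax[i];
      diag[parent[i]] += g_ax[i];
    }
    for (int i = nseg - 1; i >= 1; --i) { // Hines elimination (parent < child)
      int p = parent[i];
      double f = g_ax[i] / diag[i];
      diag[p] -= f * g_ax[i];
      rhs[p] += f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < nseg; ++i) V[i] = (rhs[i] + g_ax[i] * V[parent[i]]) / diag[i];

    i_clamp = (clamp_mode == 1) ? 1000.0 / rs * (cmd[step] - V[0]) : i_inj[step];

    // --- ion dynamics
    i_cl_tot = 0.0;
    i_hco3_tot = 0.0;
    if (dynamic_ions) {
      // (1) synaptic flux into the outermost shell: d[Ion]/dt = I/(F vol)
      for (int i = 0; i < nseg; ++i) {
        if (g_cl[i] == 0.0 && g_hco3[i] == 0.0) continue;
        double icl = g_cl[i] * (V[i] - e_cl[i]);      // pA
        double ihco3 = g_hco3[i] * (V[i] - e_hco3[i]);
        i_cl_tot += icl;
        i_hco3_tot += ihco3;
        double vo = vol[i * ns + ns - 1];
        cl[i * ns + ns - 1] += icl * dt * 1000.0 / (FARADAY * vo);   // mM
        hco3[i * ns + ns - 1] += ihco3 * dt * 1000.0 / (FARADAY * vo);
      }

      // (2) implicit radial diffusion (precomputed Thomas factors)
      if (ns > 1) {
        for (int ion = 0; ion < 2; ++ion) {
          std::vector<double> &C = (ion == 0) ? cl : hco3;
          for (int i = 0; i < nseg; ++i) {
            double *c = &C[i * ns];
            const double *m = &td_m[i * ns], *bi = &td_bi[i * ns],
                         *cc = &td_c[i * ns];
            for (int k = 1; k < ns; ++k) c[k] -= m[k] * c[k - 1];
            c[ns - 1] *= bi[ns - 1];
            for (int k = ns - 2; k >= 0; --k)
              c[k] = (c[k] - cc[k] * c[k + 1]) * bi[k];
          }
        }
      }

      // (3) explicit longitudinal diffusion between adjacent segments
      if (longitudinal_on) {
        for (int ion = 0; ion < 2; ++ion) {
          std::vector<double> &C = (ion == 0) ? cl : hco3;
          std::fill(dconc.begin(), dconc.end(), 0.0);
          for (int i = 1; i < nseg; ++i) {
            int p = parent[i];
            const double *q = &lon_q[i * ns];
            for (int k = 0; k < lon_nk[i]; ++k) {
              double f = q[k] * (C[p * ns + k] - C[i * ns + k]);
              dconc[i * ns + k] += f / vol[i * ns + k];
              dconc[p * ns + k] -= f / vol[p * ns + k];
            }
          }
          for (int j = 0; j < nseg * ns; ++j) C[j] += dconc[j];
        }
      }

      // (4) transport: exact first-order relaxation, bimodal tau
      if (transport_on) {
        for (int j = 0; j < nseg * ns; ++j) {
          double c = cl[j];
          cl[j] = c + (cl_rest - c) * (c < cl_rest ? f_up : f_ex);
          double h = hco3[j];
          hco3[j] = h + (hco3_rest - h) * (h < hco3_rest ? f_up : f_ex);
        }
      }

      update_reversals();
    } else {
      for (int i = 0; i < nseg; ++i) {
        i_cl_tot += g_cl[i] * (V[i] - e_cl[i]);
        i_hco3_tot += g_hco3[i] * (V[i] - e_hco3[i]);
      }
    }

    // sanity: the solver must stay finite; name the offending stage
    if (!std::isfinite(V[0]) || !std::isfinite(cl[0])) {
      stop("cable solver produced a non-finite state at t = %f ms (%s)",
           (step + 1) * dt,
           std::isfinite(V[0]) ? "ion update" : "voltage solve");
    }

    if ((step + 1) % record_every == 0) record(step + 1);
  }

  NumericMatrix cl_out(nseg, ns), hco3_out(nseg, ns);
  for (int i = 0; i < nseg; ++i)
    for (int k = 0; k < ns; ++k) {
      cl_out(i, k) = cl[i * ns + k];
      hco3_out(i, k) = hco3[i * ns + k];
    }

  return List::create(
      _["time_ms"] = rec_t, _["v_soma"] = rec_v, _["i_clamp"] = rec_ic,
      _["cl_dend"] = rec_cld, _["hco3_dend"] = rec_hco3d,
      _["i_cl_total"] = rec_icl, _["i_hco3_total"] = rec_ihco3,
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["cl_final"] = cl_out, _["hco3_final"] = hco3_out);
}
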