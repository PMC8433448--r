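// Fixed-step exponential-Euler integrator for networks of AdExp
// integrate-and-fire neurons with exponential current synapses.
//
// Units: time ms, voltage mV, current nA, conductance nS.  The membrane
// resistance is passed pre-converted to mV/nA (= 1000/gL[nS]) so the state
// update never mixes unit scales.  Synapse state is the instantaneous
// post-synaptic current in nA; on a presynaptic spike it jumps by the signed
// effective weight and decays with the realized synaptic time constant.
//
// Spikes are registered at step boundaries: a neuron whose membrane reaches
// the cutoff during step k is recorded at t = (k+1)*dt, reset, and held at
// the reset potential for its refractory period.  A spike delivered at time
// t contributes to postsynaptic input from the following step onward.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List neurons, List synapses,
              IntegerVector ext_pre, NumericVector ext_time,
              double duration, double dt,
              IntegerVector record_ids, int n_sources) {
  NumericVector el = neurons["rest_potential"];
  NumericVector vt = neurons["exp_threshold"];
  NumericVector dT = neurons["slope_factor"];
  NumericVector vcut = neurons["spike_cutoff"];
  NumericVector vres = neurons["reset_potential"];
  NumericVector refr = neurons["refractory"];
  NumericVector taum = neurons["membrane_tau"];
  NumericVector rm = neurons["rm"];          // mV/nA
  NumericVector aad = neurons["adapt_a"];    // nS
  NumericVector bad = neurons["adapt_b"];    // nA
  NumericVector tad = neurons["adapt_tau"];
  NumericVector dc = neurons["dc"];          // nA

  const int n = el.size();
  IntegerVector spre_in = synapses["pre"];   // 1-based, may reference ext sources
  IntegerVector spost_in = synapses["post"]; // 1-based, <= n
  NumericVector sw_in = synapses["w_eff"];   // signed effective jump, nA
  NumericVector stau = synapses["tau"];
  const int ns = spre_in.size();
  // plain copies (0-based post) so the hot loops work on raw memory
  std::vector<int> spre(spre_in.begin(), spre_in.end());
  std::vector<int> spost0(ns);
  for (int s = 0; s < ns; ++s) spost0[s] = spost_in[s] - 1;
  std::vector<double> sw(sw_in.begin(), sw_in.end());

  const long nsteps = (long)std::ceil(duration / dt);

  // per-neuron precomputed decay factors
  std::vector<double> em(n), ea(n);
  for (int i = 0; i < n; ++i) {
    em[i] = std::exp(-dt / taum[i]);
    ea[i] = (tad[i] > 0) ? std::exp(-dt / tad[i]) : 0.0;
  }

  // synapse state and decay
  std::vector<double> y(ns, 0.0), dec(ns);
  for (int s = 0; s < ns; ++s) dec[s] = std::exp(-dt / stau[s]);

  // CSR adjacency: outgoing synapse indices per source id (1..n_sources)
  std::vector<int> deg(n_sources + 1, 0);
  for (int s = 0; s < ns; ++s) deg[spre[s]]++;
  std::vector<int> ptr(n_sources + 2, 0);
  for (int i = 1; i <= n_sources; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj(ns);
  {
    std::vector<int> cur(ptr.begin(), ptr.end() - 1);
    for (int s = 0; s < ns; ++s) adj[cur[spre[s]]++] = s;
  }

  // neuron state
  std::vector<double> v(n), wad(n, 0.0), refr_until(n, -1.0), isyn(n);
  for (int i = 0; i < n; ++i) v[i] = el[i];

  std::vector<int> out_id; std::vector<double> out_t;
  out_id.reserve(4096); out_t.reserve(4096);

  // membrane recording
  const int nrec = record_ids.size();
  NumericMatrix vrec(nrec > 0 ? nsteps + 1 : 0, nrec);
  if (nrec > 0) for (int j = 0; j < nrec; ++j) vrec(0, j) = v[record_ids[j] - 1];

  int ep = 0; // pointer into external events (assumed time-sorted)
  const int ne = ext_pre.size();
  std::vector<int> fired; fired.reserve(64);

  for (long k = 0; k < nsteps; ++k) {
    const double t_next = (k + 1) * dt;

    // synaptic decay (vectorizable) then input accumulation (scatter)
    std::fill(isyn.begin(), isyn.end(), 0.0);
    double *yp = y.data(); const double *dp = dec.data();
    for (int s = 0; s < ns; ++s) yp[s] *= dp[s];
    const int *pp = spost0.data();
    for (int s = 0; s < ns; ++s) isyn[pp[s]] += yp[s];

    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (t_next <= refr_until[i] + 1e-12) { v[i] = vres[i]; continue; }
      double iexp = 0.0;
      if (dT[i] > 0) {
        double arg = (v[i] - vt[i]) / dT[i];
        iexp = dT[i] * std::exp(arg > 30.0 ? 30.0 : arg);
      }
      const double vinf = el[i] + iexp + rm[i] * (isyn[i] + dc[i] - wad[i]);
      v[i] = vinf + (v[i] - vinf) * em[i];
      if (tad[i] > 0) {
        const double winf = aad[i] * (v[i] - el[i]) / 1000.0;
        wad[i] = winf + (wad[i] - winf) * ea[i];
      }
      if (v[i] >= vcut[i]) {
        out_id.push_back(i + 1);
        out_t.push_back(t_next);
        v[i] = vres[i];
        refr_until[i] = t_next + refr[i];
        wad[i] += bad[i];
        fired.push_back(i + 1);
      } else if (!std::isfinite(v[i]) || v[i] > 1e6) {
        stop("numerical divergence: membrane of neuron %d exceeded sanity bound at t = %.1f ms", i + 1, t_next);
      }
    }

    // deliver internal spikes registered at t_next
    for (size_t f = 0; f < fired.size(); ++f) {
      const int src = fired[f];
      for (int p = ptr[src]; p < ptr[src + 1]; ++p) y[adj[p]] += sw[adj[p]];
    }
    // deliver external events with time in (t_next - dt, t_next]
    while (ep < ne && ext_time[ep] <= t_next + 1e-9) {
      const int src = ext_pre[ep];
      for (int p = ptr[src]; p < ptr[src + 1]; ++p) y[adj[p]] += sw[adj[p]];
      ++ep;
    }

    if (nrec > 0) for (int j = 0; j < nrec; ++j) vrec(k + 1, j) = v[record_ids[j] - 1];
  }

  return List::create(_["neuron_id"] = wrap(out_id), _["time_ms"] = wrap(out_t),
                      _["vrec"] = vrec);
}
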