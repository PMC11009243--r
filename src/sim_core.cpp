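#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven Tsodyks-Markram update: exact exponential relaxation of
// (u, r) since the last presynaptic event, then the per-spike map
// u+ = u + U(1-u), release = A u+ r, r <- r - u+ r.
struct TMClass {
  double U, tau_rec, tau_facil, A, tau_s;
  TMClass(NumericVector p)
      : U(p[0]), tau_rec(p[1]), tau_facil(p[2]), A(p[3]), tau_s(p[4]) {}
};

struct TMBank {
  std::vector<double> u, r;
  std::vector<int> last;
  TMClass cls;
  TMBank(int n, TMClass c) : u(n, 0.0), r(n, 1.0), last(n, 0), cls(c) {}
  inline double event(int k, int step, double dt) {
    double el = (step - last[k]) * dt;
    double uu = (cls.tau_facil > 0.0)
                    ? u[k] * std::exp(-el / cls.tau_facil) : 0.0;
    double rr = (cls.tau_rec > 0.0)
                    ? 1.0 - (1.0 - r[k]) * std::exp(-el / cls.tau_rec) : 1.0;
    uu += cls.U * (1.0 - uu);
    double rel = cls.A * uu * rr;
    rr -= uu * rr;
    u[k] = uu; r[k] = rr; last[k] = step;
    return rel;
  }
};

// Peak value of the unit double-exponential kernel exp(-t/td) - exp(-t/tr),
// used to normalize readout conductance increments to unit kernel peak.
static inline double biexp_peak(double td, double tr) {
  if (tr <= 0.0 || tr >= td) return 1.0;
  double tpk = std::log(td / tr) * (tr * td) / (td - tr);
  return std::exp(-tpk / td) - std::exp(-tpk / tr);
}

// [[Rcpp::export]]
List sim_core_cpp(int n_steps, double dt,
                  int n_stn, int n_gpe, double stn_rate,
                  IntegerVector s2g_pre, IntegerVector s2g_post,
                  NumericVector s2g_w,
                  IntegerVector g2g_pre, IntegerVector g2g_post,
                  NumericVector g2g_w,
                  NumericVector stn_base_syn, // baseline Poisson-driven STN->GPe
                  NumericVector eff_syn,      // pulse-activated STN efferent
                  NumericVector col_syn,
                  double gg_spike_scale,
                  NumericVector ctx_syn, NumericVector gstn_syn,
                  NumericVector fb_syn,
                  int n_aff_exc, int n_aff_inh,
                  IntegerVector pulse_steps,
                  bool collaterals, bool hyperdirect,
                  double ou_mu, double ou_alpha, double ou_tau,
                  NumericVector gpe_par, // C, g_L, V_p, V_th, V_r, t_ref, E_exc, E_inh, I_e
                  int d_eff, int d_col, int d_aff, int d_fb,
                  double tau_rise, double fb_weight,
                  double stn_mod_gain) {
  RNGScope scope;

  const int n_s2g = s2g_pre.size();
  const int n_g2g = g2g_pre.size();

  // out-adjacency (synapse indices grouped by presynaptic unit)
  std::vector<std::vector<int> > out_s2g(n_stn), out_g2g(n_gpe);
  for (int k = 0; k < n_s2g; ++k) out_s2g[s2g_pre[k]].push_back(k);
  for (int k = 0; k < n_g2g; ++k) out_g2g[g2g_pre[k]].push_back(k);

  // TM banks: baseline and pulse-activated states are distinct even where
  // they share an anatomical connection (the DBS pulse recruits the axon
  // directly, modeled as its own synaptic resource pool)
  TMBank bank_base(n_s2g, TMClass(stn_base_syn));
  TMBank bank_eff(n_s2g, TMClass(eff_syn));
  TMBank bank_col(n_g2g, TMClass(col_syn));
  // baseline spiking-driven GPe-GPe releases are static (gg_spike_scale is
  // their weight relative to a full pulse-driven release)
  TMBank bank_fb(n_gpe, TMClass(fb_syn));
  TMBank bank_ctx(1, TMClass(ctx_syn));
  TMBank bank_gstn(1, TMClass(gstn_syn));

  const double tau_e = TMClass(stn_base_syn).tau_s;
  const double tau_i = TMClass(col_syn).tau_s;

  // GPe membrane parameters
  const double Cm = gpe_par[0], gL = gpe_par[1], Vp = gpe_par[2],
               Vth = gpe_par[3], Vr = gpe_par[4], tref = gpe_par[5],
               Eexc = gpe_par[6], Einh = gpe_par[7], Ie = gpe_par[8];
  const int ref_steps = (int)std::ceil(tref / dt);

  std::vector<double> g_e(n_gpe, 0.0), g_i(n_gpe, 0.0), V(n_gpe),
      x_ou(n_gpe);
  std::vector<int> refr(n_gpe, 0);
  const double dec_e = std::exp(-dt / tau_e), dec_i = std::exp(-dt / tau_i);
  const double ou_dec = std::exp(-dt / ou_tau);
  const double ou_sd = ou_alpha * std::sqrt(1.0 - ou_dec * ou_dec);

  for (int n = 0; n < n_gpe; ++n) {
    V[n] = Vp + (Vth - Vp) * unif_rand();
    x_ou[n] = ou_mu + ou_alpha * norm_rand();
  }

  // delayed-increment ring buffers for GPe conductances
  int L_g = std::max(d_eff, d_col) + 1;
  std::vector<double> ring_e((size_t)L_g * n_gpe, 0.0),
      ring_i((size_t)L_g * n_gpe, 0.0);
  // scalar rings for the STN readout (population-summed conductances)
  int L_p = std::max(d_aff, d_fb) + 1;
  std::vector<double> ring_pi(L_p, 0.0), ring_pe(L_p, 0.0);

  // STN readout conductances: double-exponential (finite rise) so evoked
  // peaks are interior extrema; increments normalized to unit kernel peak
  double pi_dec = 0.0, pi_rise = 0.0, pe_dec = 0.0, pe_rise = 0.0;
  const double tau_pi = TMClass(gstn_syn).tau_s,
               tau_pe = TMClass(ctx_syn).tau_s;
  const double dec_pi = std::exp(-dt / tau_pi),
               dec_pe = std::exp(-dt / tau_pe);
  const double dec_rise = std::exp(-dt / tau_rise);
  const double norm_pi = 1.0 / biexp_peak(tau_pi, tau_rise);
  const double norm_pe = 1.0 / biexp_peak(tau_pe, tau_rise);

  std::vector<bool> is_pulse(n_steps, false);
  for (int k = 0; k < pulse_steps.size(); ++k) {
    int s = pulse_steps[k];
    if (s >= 0 && s < n_steps) is_pulse[s] = true;
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(n_gpe * 64);
  spike_id.reserve(n_gpe * 64);
  NumericVector proxy_inh(n_steps), proxy_exc(n_steps);
  long stn_spikes = 0;
  const double p_base = stn_rate * dt / 1000.0;

  for (int i = 0; i < n_steps; ++i) {
    // decay
    for (int n = 0; n < n_gpe; ++n) { g_e[n] *= dec_e; g_i[n] *= dec_i; }
    pi_dec *= dec_pi; pe_dec *= dec_pe;
    pi_rise *= dec_rise; pe_rise *= dec_rise;

    // deliver delayed increments due this step
    int slot = i % L_g;
    double *re = &ring_e[(size_t)slot * n_gpe];
    double *ri = &ring_i[(size_t)slot * n_gpe];
    for (int n = 0; n < n_gpe; ++n) {
      g_e[n] += re[n]; re[n] = 0.0;
      g_i[n] += ri[n]; ri[n] = 0.0;
    }
    int pslot = i % L_p;
    pi_dec += ring_pi[pslot]; pi_rise += ring_pi[pslot]; ring_pi[pslot] = 0.0;
    pe_dec += ring_pe[pslot]; pe_rise += ring_pe[pslot]; ring_pe[pslot] = 0.0;

    double prox_i = (pi_dec - pi_rise) * norm_pi / n_stn;
    double prox_e = (pe_dec - pe_rise) * norm_pe / n_stn;
    proxy_inh[i] = prox_i;
    proxy_exc[i] = prox_e;

    // DBS pulse: afferent bank, STN efferents, GPe-GPe collaterals
    if (is_pulse[i]) {
      if (hyperdirect && n_aff_exc > 0) {
        double rel = bank_ctx.event(0, i, dt);
        ring_pe[(i + d_aff) % L_p] += rel * n_aff_exc;
      }
      if (n_aff_inh > 0) {
        double rel = bank_gstn.event(0, i, dt);
        ring_pi[(i + d_aff) % L_p] += rel * n_aff_inh;
      }
      int eslot = (i + d_eff) % L_g;
      for (int k = 0; k < n_s2g; ++k) {
        ring_e[(size_t)eslot * n_gpe + s2g_post[k]] +=
            s2g_w[k] * bank_eff.event(k, i, dt);
      }
      if (collaterals) {
        int cslot = (i + d_col) % L_g;
        for (int k = 0; k < n_g2g; ++k) {
          ring_i[(size_t)cslot * n_gpe + g2g_post[k]] +=
              g2g_w[k] * bank_col.event(k, i, dt);
        }
      }
    }

    // STN Poisson drive (optionally modulated by the inhibitory readout)
    double p_spk = p_base;
    if (stn_mod_gain > 0.0) {
      double f = 1.0 - stn_mod_gain * prox_i;
      p_spk = p_base * (f > 0.0 ? f : 0.0);
    }
    int eslot = (i + d_eff) % L_g;
    for (int s = 0; s < n_stn; ++s) {
      if (unif_rand() < p_spk) {
        ++stn_spikes;
        const std::vector<int> &syn = out_s2g[s];
        for (size_t q = 0; q < syn.size(); ++q) {
          int k = syn[q];
          ring_e[(size_t)eslot * n_gpe + s2g_post[k]] +=
              s2g_w[k] * bank_base.event(k, i, dt);
        }
      }
    }

    // OU noise + membrane integration
    int cslot = (i + d_col) % L_g;
    int fslot = (i + d_fb) % L_p;
    for (int n = 0; n < n_gpe; ++n) {
      x_ou[n] = ou_mu + (x_ou[n] - ou_mu) * ou_dec +
                (ou_sd > 0.0 ? ou_sd * norm_rand() : 0.0);
      if (refr[n] > 0) { --refr[n]; V[n] = Vr; continue; }
      double dV = (-gL * (V[n] - Vp) - g_e[n] * (V[n] - Eexc) -
                   g_i[n] * (V[n] - Einh) + Ie + x_ou[n]) / Cm;
      V[n] += dt * dV;
      if (!std::isfinite(V[n])) {
        stop("membrane voltage diverged (dt = %f ms); reduce dt", dt);
      }
      if (V[n] >= Vth) {
        V[n] = Vr;
        refr[n] = ref_steps;
        spike_t.push_back(i * dt / 1000.0);
        spike_id.push_back(n + 1);
        // propagate: reciprocal GPe-GPe synapses + feedback GPe->STN
        const std::vector<int> &syn = out_g2g[n];
        for (size_t q = 0; q < syn.size(); ++q) {
          int k = syn[q];
          ring_i[(size_t)cslot * n_gpe + g2g_post[k]] +=
              gg_spike_scale * g2g_w[k];
        }
        ring_pi[fslot] += fb_weight * bank_fb.event(n, i, dt);
      }
    }
  }

  return List::create(
      _["spike_t"] = wrap(spike_t),
      _["spike_id"] = wrap(spike_id),
      _["proxy_inh"] = proxy_inh,
      _["proxy_exc"] = proxy_exc,
      _["n_stn_spikes"] = (double)stn_spikes);
}
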