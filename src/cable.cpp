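#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Double-cable myelinated axon driven by an extracellular potential profile.
// Nodes of Ranvier carry fast Na, persistent Na, slow K and leak channels;
// internodes are passive axolemma under a passive myelin sheath, with the
// periaxonal space opening to the extracellular medium at the flanking nodes.
// Semi-implicit backward-Euler voltage step (channel gates advanced by
// Rush-Larsen using the previous membrane potential), banded direct solve.
// Units: mV, ms, mS, uF (currents in uA).

static inline double vtrap(double x, double y) {
  // x/(1-exp(-x/y)) with removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Rates {
  double am, bm, ah, bh, ap, bp, as, bs;
};

static Rates gate_rates(double v, double q1, double q2, double q3) {
  Rates r;
  r.am = q1 * 6.57 * vtrap(v + 20.4, 10.3);
  r.bm = q1 * 0.304 * vtrap(-(v + 25.7), 9.16);
  r.ah = q1 * 0.34 * vtrap(-(v + 114.0), 11.0);
  r.bh = q1 * 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = q2 * 0.0353 * vtrap(v + 27.0, 10.2);
  r.bp = q2 * 0.000883 * vtrap(-(v + 34.0), 10.0);
  r.as = q3 * 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  r.bs = q3 * 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  return r;
}

// Banded Gaussian elimination without pivoting, kl = ku = 2. The system is
// strongly diagonally dominant for the time steps used here.
static void band_solve(std::vector<double>& ab, std::vector<double>& rhs, int n) {
  const int ku = 2, ld = 5;  // ab[(ku + i - j) + ld*j] = A(i,j)
  for (int j = 0; j < n; ++j) {
    double piv = ab[ku + ld * j];
    for (int i = j + 1; i <= std::min(j + 2, n - 1); ++i) {
      double f = ab[ku + i - j + ld * j] / piv;
      if (f == 0.0) continue;
      for (int c = j + 1; c <= std::min(j + 2, n - 1); ++c)
        ab[ku + i - c + ld * c] -= f * ab[ku + j - c + ld * c];
      rhs[i] -= f * rhs[j];
      ab[ku + i - j + ld * j] = 0.0;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double acc = rhs[i];
    for (int c = i + 1; c <= std::min(i + 2, n - 1); ++c)
      acc -= ab[ku + i - c + ld * c] * rhs[c];
    rhs[i] = acc / ab[ku + ld * i];
  }
}

// [[Rcpp::export]]
List cpp_simulate_axon(NumericVector ve_mv, IntegerVector kinds, List electr,
                       List wf, double threshold_mv) {
  const int nc = ve_mv.size();
  if (kinds.size() != nc) stop("profile/compartment length mismatch");

  NumericVector Cm = electr["Cm_uF"];       // axolemma capacitance per comp
  NumericVector Gax = electr["Gax_mS"];     // axial, length nc-1
  NumericVector Gi = electr["Gi_mS"];       // internodal axolemma leak
  NumericVector Cmy = electr["Cmy_uF"];     // myelin capacitance
  NumericVector Gmy = electr["Gmy_mS"];     // myelin conductance
  NumericVector Gp = electr["Gp_mS"];       // periaxonal end conductance (each end)
  NumericVector gnaf = electr["gnaf_mS"], gnap = electr["gnap_mS"];
  NumericVector gks = electr["gks_mS"], gl = electr["gl_mS"];
  const double ena = electr["ena_mV"], ek = electr["ek_mV"];
  const double vrest = electr["vrest_mV"], celsius = electr["celsius"];

  const double amp = wf["amplitude_scale"];
  const double pw = wf["pulse_width_ms"], tau = wf["tau_ms"], a2 = wf["a2"];
  const double period = wf["period_ms"], ttotal = wf["total_ms"];
  const double dt = wf["dt_ms"];
  const int npulses = wf["n_pulses"];

  const double q1 = std::pow(2.2, (celsius - 20.0) / 10.0);
  const double q2 = std::pow(2.9, (celsius - 20.0) / 10.0);
  const double q3 = std::pow(3.0, (celsius - 36.0) / 10.0);

  // unknown layout: u for every compartment, w appended after u at internodes
  std::vector<int> uidx(nc, -1), widx(nc, -1);
  int nunk = 0;
  for (int c = 0; c < nc; ++c) {
    uidx[c] = nunk++;
    if (kinds[c] == 1) widx[c] = nunk++;
  }

  std::vector<int> node_ids;
  for (int c = 0; c < nc; ++c)
    if (kinds[c] == 0) node_ids.push_back(c);
  const int nn = (int)node_ids.size();
  if (nn < 2) stop("axon needs at least two nodes");

  // gate states at rest
  Rates r0 = gate_rates(vrest, q1, q2, q3);
  std::vector<double> m(nn, r0.am / (r0.am + r0.bm)), h(nn, r0.ah / (r0.ah + r0.bh));
  std::vector<double> p(nn, r0.ap / (r0.ap + r0.bp)), s(nn, r0.as / (r0.as + r0.bs));

  // leak reversal balancing the resting ionic currents (per unit area, all
  // nodes share channel densities so a single value suffices)
  double el;
  {
    int c0 = node_ids[0];
    double ion = gnaf[c0] * m[0] * m[0] * m[0] * h[0] * (vrest - ena) +
                 gnap[c0] * p[0] * p[0] * p[0] * (vrest - ena) +
                 gks[c0] * s[0] * (vrest - ek);
    el = vrest + ion / gl[c0];
  }

  std::vector<double> u(nc, vrest), w(nc, 0.0);
  std::vector<double> ve_now(nc, 0.0), ve_new(nc, 0.0);
  std::vector<double> tfirst(nn, -1.0);
  double vm_max = vrest;

  auto wfval = [&](double t) -> double {
    if (t <= 0.0) return 0.0;
    double tp = t;
    int ip = 0;
    if (period > 0.0) {
      ip = (int)std::floor(t / period);
      tp = t - ip * period;
    }
    if (ip >= npulses) return 0.0;
    if (tp <= pw) return 1.0;
    return -a2 * std::exp(-(tp - pw) / tau);
  };

  const int nsteps = (int)std::ceil(ttotal / dt);
  std::vector<double> ab(5 * nunk), rhs(nunk);

  bool activated = false;
  int check_every = 25;

  for (int step = 1; step <= nsteps; ++step) {
    double tnew = step * dt;
    double scl_new = amp * wfval(tnew);
    for (int c = 0; c < nc; ++c) ve_new[c] = scl_new * ve_mv[c];

    // gate update with membrane potential at time t
    for (int q = 0; q < nn; ++q) {
      int c = node_ids[q];
      double vm = u[c] - ve_now[c];
      Rates r = gate_rates(vm, q1, q2, q3);
      double tm = 1.0 / (r.am + r.bm), minf = r.am * tm;
      double th = 1.0 / (r.ah + r.bh), hinf = r.ah * th;
      double tp2 = 1.0 / (r.ap + r.bp), pinf = r.ap * tp2;
      double ts = 1.0 / (r.as + r.bs), sinf = r.as * ts;
      m[q] = minf + (m[q] - minf) * std::exp(-dt / tm);
      h[q] = hinf + (h[q] - hinf) * std::exp(-dt / th);
      p[q] = pinf + (p[q] - pinf) * std::exp(-dt / tp2);
      s[q] = sinf + (s[q] - sinf) * std::exp(-dt / ts);
    }

    std::fill(ab.begin(), ab.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    const int ku = 2, ld = 5;
    auto A = [&](int i, int j) -> double& { return ab[ku + i - j + ld * j]; };

    int nq = 0;
    for (int c = 0; c < nc; ++c) {
      int iu = uidx[c];
      double GaxL = (c > 0) ? Gax[c - 1] : 0.0;
      double GaxR = (c + 1 < nc) ? Gax[c] : 0.0;
      if (kinds[c] == 0) {  // node of Ranvier
        double m3h = m[nq] * m[nq] * m[nq] * h[nq];
        double p3 = p[nq] * p[nq] * p[nq];
        double gtot = gnaf[c] * m3h + gnap[c] * p3 + gks[c] * s[nq] + gl[c];
        double gE = gnaf[c] * m3h * ena + gnap[c] * p3 * ena +
                    gks[c] * s[nq] * ek + gl[c] * el;
        double cdt = Cm[c] / dt;
        double vm_old = u[c] - ve_now[c];
        A(iu, iu) += cdt + gtot + GaxL + GaxR;
        if (c > 0) A(iu, uidx[c - 1]) -= GaxL;
        if (c + 1 < nc) A(iu, uidx[c + 1]) -= GaxR;
        rhs[iu] += cdt * vm_old + gE + (cdt + gtot) * ve_new[c];
        ++nq;
      } else {  // internode: axolemma row (u) and periaxonal row (w)
        int iw = widx[c];
        double cdt = Cm[c] / dt;
        double vax_old = u[c] - w[c];
        // axolemma
        A(iu, iu) += cdt + Gi[c] + GaxL + GaxR;
        A(iu, iw) -= cdt + Gi[c];
        if (c > 0) A(iu, uidx[c - 1]) -= GaxL;
        if (c + 1 < nc) A(iu, uidx[c + 1]) -= GaxR;
        rhs[iu] += cdt * vax_old + Gi[c] * vrest;
        // periaxonal balance (sign flipped for a positive diagonal)
        double cmydt = Cmy[c] / dt;
        double vmy_old = w[c] - ve_now[c];
        double veL = (c > 0) ? ve_new[c - 1] : ve_new[c];
        double veR = (c + 1 < nc) ? ve_new[c + 1] : ve_new[c];
        A(iw, iw) += (cdt + Gi[c]) + (cmydt + Gmy[c]) + 2.0 * Gp[c];
        A(iw, iu) -= cdt + Gi[c];
        rhs[iw] += -(cdt * vax_old + Gi[c] * vrest) + cmydt * vmy_old +
                   (cmydt + Gmy[c]) * ve_new[c] + Gp[c] * veL + Gp[c] * veR;
      }
    }

    band_solve(ab, rhs, nunk);
    for (int c = 0; c < nc; ++c) {
      u[c] = rhs[uidx[c]];
      if (widx[c] >= 0) w[c] = rhs[widx[c]];
    }
    ve_now.swap(ve_new);

    for (int q = 0; q < nn; ++q) {
      int c = node_ids[q];
      double vm = u[c] - ve_now[c];
      if (vm > vm_max) vm_max = vm;
      if (tfirst[q] < 0.0 && vm >= threshold_mv) tfirst[q] = tnew;
    }

    if (step % check_every == 0 || step == nsteps) {
      int run0 = 0;
      while (run0 < nn && tfirst[run0] >= 0.0) ++run0;
      int run1 = 0;
      while (run1 < nn && tfirst[nn - 1 - run1] >= 0.0) ++run1;
      if (run0 >= 3 || run1 >= 3) { activated = true; break; }
    }
  }

  int api_node = NA_INTEGER, api_comp = NA_INTEGER;
  if (activated) {
    double tbest = R_PosInf;
    for (int q = 0; q < nn; ++q)
      if (tfirst[q] >= 0.0 && tfirst[q] < tbest) {
        tbest = tfirst[q];
        api_node = q + 1;
        api_comp = node_ids[q] + 1;
      }
  }

  NumericVector tf(nn), vm_final(nn);
  int nfired = 0;
  for (int q = 0; q < nn; ++q) {
    tf[q] = tfirst[q] >= 0.0 ? tfirst[q] : NA_REAL;
    if (tfirst[q] >= 0.0) ++nfired;
    vm_final[q] = u[node_ids[q]] - ve_now[node_ids[q]];
  }

  return List::create(_["activated"] = activated, _["api_node"] = api_node,
                      _["api_compartment"] = api_comp, _["t_first_ms"] = tf,
                      _["vm_final_mV"] = vm_final, _["vm_max_mV"] = vm_max,
                      _["n_fired"] = nfired);
}
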