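// Compiled core of the conductance-based canonical microcircuit network.
//
// The network holds 6 sources x 6 populations; each population carries a
// membrane potential V and three conductance states (AMPA, NMDA, GABA-A),
// i.e. a 144-dimensional state. Dynamics follow the conductance-based
// mean-field form
//
//   C dV/dt  = gL (VL - V) + gA (VE - V) + gN m(V) (VE - V) + gG (VI - V) + u
//   dgk/dt   = kappa_k (Wk r(V) - gk)
//
// with r(V) the baseline-subtracted, rectified logistic rate and m(V) the
// magnesium gate 1 / (1 + 0.2 exp(-0.06 V)). All synaptic weights enter as
// prior-mean values scaled by exp(theta); the scaling is applied in R before
// the integrator is called, except in cmm_predict_multi which applies the
// theta -> matrix mapping itself so finite-difference Jacobians stay in
// compiled code.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

struct CmmConsts {
  double gl, Cm, VL, VE, VI, kA, kN, kG, thresh, slope, mg_a, mg_b;
  double lin_gain;
  bool linear;
  double r0; // resting rate, subtracted so V = VL is a fixed point
};

static CmmConsts parse_consts(const Rcpp::List& cn) {
  CmmConsts c;
  c.gl = cn["gl"]; c.Cm = cn["Cm"];
  c.VL = cn["VL"]; c.VE = cn["VE"]; c.VI = cn["VI"];
  c.kA = cn["kappa_ampa"]; c.kN = cn["kappa_nmda"]; c.kG = cn["kappa_gabaa"];
  c.thresh = cn["threshold"]; c.slope = cn["slope"];
  c.mg_a = cn["mg_a"]; c.mg_b = cn["mg_b"];
  c.linear = cn["linear"];
  c.lin_gain = cn["lin_gain"];
  c.r0 = 1.0 / (1.0 + std::exp(-c.slope * (c.VL - c.thresh)));
  return c;
}

// Interpolation tables for the two voltage nonlinearities (logistic rate
// and magnesium gate). On a 0.05 mV grid the linear-interpolation error is
// below 1e-9 -- far inside every numerical tolerance of the model -- and
// it removes ~300k libm exp() calls per integration.
struct VTables {
  double v0, dv_inv;
  std::vector<double> sig, mg;
  double sig0; // interpolated resting rate, so V = VL gives rate exactly 0
  void build(const CmmConsts& c, double vbound) {
    const double lo = c.VL - vbound - 4.0, hi = c.VL + vbound + 4.0,
                 step = 0.05;
    const uword m = (uword)((hi - lo) / step) + 2;
    v0 = lo; dv_inv = 1.0 / step;
    sig.resize(m); mg.resize(m);
    for (uword i = 0; i < m; ++i) {
      const double v = lo + i * step;
      sig[i] = 1.0 / (1.0 + std::exp(-c.slope * (v - c.thresh)));
      mg[i] = 1.0 / (1.0 + c.mg_a * std::exp(-c.mg_b * v));
    }
    sig0 = look(sig, c.VL);
  }
  inline double look(const std::vector<double>& tab, double v) const {
    double x = (v - v0) * dv_inv;
    if (x < 0) x = 0;
    if (x > tab.size() - 2.0) x = tab.size() - 2.0;
    const uword i = (uword)x;
    const double w = x - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
  }
};

// triplet form of a weight matrix: intrinsic blocks plus a few extrinsic
// edges give ~5% fill, so the sparse product cuts the matvec work ~20x
struct SpW {
  std::vector<uword> row, col;
  std::vector<double> val;
  void build(const mat& W) {
    row.reserve(128); col.reserve(128); val.reserve(128);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i)
        if (W(i, j) != 0.0) {
          row.push_back(i); col.push_back(j); val.push_back(W(i, j));
        }
  }
  inline void mult(const vec& x, vec& out) const {
    out.zeros();
    for (size_t k = 0; k < val.size(); ++k)
      out(row[k]) += val[k] * x(col[k]);
  }
};

// d(state)/dt for the whole network; all outputs written in place
static void derivs(const vec& V, const vec& gA, const vec& gN, const vec& gG,
                   double t, const SpW& WA, const SpW& WN, const SpW& WG,
                   const vec& b, double amp, double lat, double isd,
                   const CmmConsts& c, const VTables& tb, vec& r,
                   vec& dV, vec& dgA, vec& dgN, vec& dgG) {
  const uword n = V.n_elem;
  const double ut = amp * std::exp(-0.5 * std::pow((t - lat) / isd, 2.0));
  if (c.linear) {
    // diagnostic mode: rate linearised, magnesium gate fixed at 1, driving
    // forces frozen at their resting values -> exactly linear system
    const double fE = c.VE - c.VL, fI = c.VI - c.VL;
    for (uword i = 0; i < n; ++i) {
      dV(i) = (c.gl * (c.VL - V(i)) + gA(i) * fE + gN(i) * fE +
               gG(i) * fI + b(i) * ut) / c.Cm;
      r(i) = c.lin_gain * (V(i) - c.VL);
    }
  } else {
    for (uword i = 0; i < n; ++i) {
      const double vi = V(i);
      const double ri = tb.look(tb.sig, vi) - tb.sig0;
      r(i) = ri > 0.0 ? ri : 0.0;
      const double mg = tb.look(tb.mg, vi);
      const double fE = c.VE - vi, fI = c.VI - vi;
      dV(i) = (c.gl * (c.VL - vi) + gA(i) * fE + gN(i) * mg * fE +
               gG(i) * fI + b(i) * ut) / c.Cm;
    }
  }
  WA.mult(r, dgA); dgA -= gA; dgA *= c.kA;
  WN.mult(r, dgN); dgN -= gN; dgN *= c.kN;
  WG.mult(r, dgG); dgG -= gG; dgG *= c.kG;
}

// exact (libm) evaluation of the same derivative, used by the exported
// single-point derivative so module-level oracle tests see the closed form
static void derivs_exact(const vec& V, const vec& gA, const vec& gN,
                         const vec& gG, double t, const mat& WA,
                         const mat& WN, const mat& WG, const vec& b,
                         double amp, double lat, double isd,
                         const CmmConsts& c,
                         vec& dV, vec& dgA, vec& dgN, vec& dgG) {
  const uword n = V.n_elem;
  const double ut = amp * std::exp(-0.5 * std::pow((t - lat) / isd, 2.0));
  vec r(n);
  if (c.linear) {
    const double fE = c.VE - c.VL, fI = c.VI - c.VL;
    for (uword i = 0; i < n; ++i) {
      dV(i) = (c.gl * (c.VL - V(i)) + gA(i) * fE + gN(i) * fE +
               gG(i) * fI + b(i) * ut) / c.Cm;
      r(i) = c.lin_gain * (V(i) - c.VL);
    }
  } else {
    for (uword i = 0; i < n; ++i) {
      const double vi = V(i);
      const double ri =
        1.0 / (1.0 + std::exp(-c.slope * (vi - c.thresh))) - c.r0;
      r(i) = ri > 0.0 ? ri : 0.0;
      const double mg = 1.0 / (1.0 + c.mg_a * std::exp(-c.mg_b * vi));
      const double fE = c.VE - vi, fI = c.VI - vi;
      dV(i) = (c.gl * (c.VL - vi) + gA(i) * fE + gN(i) * mg * fE +
               gG(i) * fI + b(i) * ut) / c.Cm;
    }
  }
  dgA = WA * r; dgA -= gA; dgA *= c.kA;
  dgN = WN * r; dgN -= gN; dgN *= c.kN;
  dgG = WG * r; dgG -= gG; dgG *= c.kG;
}

// Fixed-step RK4 over the epoch. When `proj` has rows, only the projected
// ERF (proj * (V - VL), one column per sample) is stored in `out`;
// otherwise the full state (V, gA, gN, gG stacked, one column per sample).
// Returns false on divergence (|V - VL| > vbound or non-finite).
static bool integrate_core(const mat& WAd, const mat& WNd, const mat& WGd,
                           const vec& b, double amp, double lat, double isd,
                           const CmmConsts& c, const VTables& tb,
                           const vec& tgrid, double vbound,
                           const mat& proj, mat& out) {
  const uword n = WAd.n_rows, T = tgrid.n_elem;
  const bool project = proj.n_rows > 0;
  SpW WA, WN, WG;
  WA.build(WAd); WN.build(WNd); WG.build(WGd);
  vec V(n, fill::value(c.VL)), gA(n, fill::zeros), gN(n, fill::zeros),
      gG(n, fill::zeros);
  out.set_size(project ? proj.n_rows : 4 * n, T);
  vec r(n), vt(n), at(n), nt(n), gt(n);
  vec k1V(n), k1A(n), k1N(n), k1G(n), k2V(n), k2A(n), k2N(n), k2G(n),
      k3V(n), k3A(n), k3N(n), k3G(n), k4V(n), k4A(n), k4N(n), k4G(n);
  for (uword i = 0; i < T; ++i) {
    if (project) {
      out.col(i) = proj * (V - c.VL);
    } else {
      out(span(0, n - 1), span(i, i)) = V;
      out(span(n, 2 * n - 1), span(i, i)) = gA;
      out(span(2 * n, 3 * n - 1), span(i, i)) = gN;
      out(span(3 * n, 4 * n - 1), span(i, i)) = gG;
    }
    if (abs(V - c.VL).max() > vbound || !V.is_finite()) return false;
    if (i + 1 == T) break;
    double t = tgrid(i), h = tgrid(i + 1) - tgrid(i);
    derivs(V, gA, gN, gG, t, WA, WN, WG, b, amp, lat, isd, c, tb, r,
           k1V, k1A, k1N, k1G);
    vt = V + 0.5 * h * k1V; at = gA + 0.5 * h * k1A;
    nt = gN + 0.5 * h * k1N; gt = gG + 0.5 * h * k1G;
    derivs(vt, at, nt, gt, t + 0.5 * h, WA, WN, WG, b, amp, lat, isd, c, tb,
           r, k2V, k2A, k2N, k2G);
    vt = V + 0.5 * h * k2V; at = gA + 0.5 * h * k2A;
    nt = gN + 0.5 * h * k2N; gt = gG + 0.5 * h * k2G;
    derivs(vt, at, nt, gt, t + 0.5 * h, WA, WN, WG, b, amp, lat, isd, c, tb,
           r, k3V, k3A, k3N, k3G);
    vt = V + h * k3V; at = gA + h * k3A; nt = gN + h * k3N; gt = gG + h * k3G;
    derivs(vt, at, nt, gt, t + h, WA, WN, WG, b, amp, lat, isd, c, tb, r,
           k4V, k4A, k4N, k4G);
    const double h6 = h / 6.0;
    for (uword j = 0; j < n; ++j) {
      V(j) += h6 * (k1V(j) + 2 * k2V(j) + 2 * k3V(j) + k4V(j));
      double a = gA(j) + h6 * (k1A(j) + 2 * k2A(j) + 2 * k3A(j) + k4A(j));
      double m = gN(j) + h6 * (k1N(j) + 2 * k2N(j) + 2 * k3N(j) + k4N(j));
      double g = gG(j) + h6 * (k1G(j) + 2 * k2G(j) + 2 * k3G(j) + k4G(j));
      // conductances are non-negative by model structure; clip FP noise
      gA(j) = a > 0.0 ? a : 0.0;
      gN(j) = m > 0.0 ? m : 0.0;
      gG(j) = g > 0.0 ? g : 0.0;
    }
  }
  return true;
}

// [[Rcpp::export]]
Rcpp::List cmm_integrate(const arma::mat& WA, const arma::mat& WN,
                         const arma::mat& WG, const arma::vec& b,
                         double amp, double lat, double isd,
                         const Rcpp::List& consts, const arma::vec& tgrid,
                         double vbound) {
  CmmConsts c = parse_consts(consts);
  VTables tb;
  tb.build(c, vbound);
  mat out, noproj(0, 0);
  bool ok = integrate_core(WA, WN, WG, b, amp, lat, isd, c, tb, tgrid,
                           vbound, noproj, out);
  return Rcpp::List::create(Rcpp::Named("state") = mat(out.t()),
                            Rcpp::Named("ok") = ok);
}

// [[Rcpp::export]]
arma::vec cmm_derivs(const arma::vec& state, double t, const arma::mat& WA,
                     const arma::mat& WN, const arma::mat& WG,
                     const arma::vec& b, double amp, double lat, double isd,
                     const Rcpp::List& consts) {
  CmmConsts c = parse_consts(consts);
  const uword n = WA.n_rows;
  vec V = state.subvec(0, n - 1), gA = state.subvec(n, 2 * n - 1),
      gN = state.subvec(2 * n, 3 * n - 1), gG = state.subvec(3 * n, 4 * n - 1);
  vec dV(n), dgA(n), dgN(n), dgG(n);
  derivs_exact(V, gA, gN, gG, t, WA, WN, WG, b, amp, lat, isd, c,
               dV, dgA, dgN, dgG);
  return join_cols(dV, dgA, dgN, dgG);
}

// Predicted source ERFs for a batch of parameter vectors. `map` encodes the
// theta -> weight-entry mapping: columns (param_id, receptor, entry) with
// receptor 0 = AMPA, 1 = NMDA, 2 = GABA-A, 3 = both AMPA and NMDA
// (extrinsic, NMDA scaled by ext_nmda). amp_id / lat_id / gain_id index
// theta entries acting multiplicatively (exp(theta)) on input amplitude,
// input latency and observation gain (-1 when fixed). Returns a list of
// 6 x T ERF matrices, with an R NULL entry on integration failure.
// [[Rcpp::export]]
Rcpp::List cmm_predict_multi(const arma::mat& Theta, const arma::mat& WA0,
                             const arma::mat& WN0, const arma::mat& WG0,
                             const arma::imat& map, const arma::vec& base,
                             double ext_nmda, int amp_id, int lat_id,
                             int gain_id, double amp0, double lat0, double isd,
                             double gain0, const arma::vec& b,
                             const arma::mat& Jproj, const Rcpp::List& consts,
                             const arma::vec& tgrid, double vbound) {
  CmmConsts c = parse_consts(consts);
  VTables tb;
  tb.build(c, vbound);
  Rcpp::List res(Theta.n_cols);
  for (uword k = 0; k < Theta.n_cols; ++k) {
    vec th = Theta.col(k);
    mat WA = WA0, WN = WN0, WG = WG0;
    for (uword e = 0; e < map.n_rows; ++e) {
      double w = base(e) * std::exp(th(map(e, 0)));
      uword idx = (uword)map(e, 2);
      switch (map(e, 1)) {
      case 0: WA(idx) += w; break;
      case 1: WN(idx) += w; break;
      case 2: WG(idx) += w; break;
      default: WA(idx) += w; WN(idx) += ext_nmda * w; break;
      }
    }
    double amp = amp0 * (amp_id >= 0 ? std::exp(th(amp_id)) : 1.0);
    double lat = lat0 * (lat_id >= 0 ? std::exp(th(lat_id)) : 1.0);
    double gain = gain0 * (gain_id >= 0 ? std::exp(th(gain_id)) : 1.0);
    mat erf;
    bool ok = integrate_core(WA, WN, WG, b, amp, lat, isd, c, tb, tgrid,
                             vbound, Jproj, erf);
    if (!ok) { res[k] = R_NilValue; continue; }
    erf *= gain;
    res[k] = erf;
  }
  return res;
}
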