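// Numerical core: feedforward network evaluation and Jacobians, fixed-step
// RK4 integration of the hybrid mass-balance system, and forward sensitivity
// propagation (indirect: d state / d weight carried through the stages;
// semidirect: per-step transition + output-channel sources composed with the
// per-stage weight Jacobians of the network).
//
// State vector y = [c (n_s concentrations), V (volume)].  Balances:
//   dc/dt = v(c,V; w) * Xv + sum_k F_k/V * c_in,k - c * sum_k F_k/V
//   dV/dt = sum_k F_k
// Feed rates are piecewise constant and constant within each substep
// (the R layer aligns substep boundaries with schedule breakpoints).
//
// Weight flattening order (must match the R layer): layer by layer,
// connection matrix row-major (all incoming weights of node 1, then node 2,
// ...), then the bias vector of that layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  int L;                  // number of weight layers
  int act;                // 0 = tanh, 1 = relu
  int n_in, n_out;
  std::vector<mat> W;
  std::vector<vec> b;
  std::vector<vec> maskscale;  // per hidden layer; empty => no dropout
  bool masked;
};

Net build_net(const Rcpp::IntegerVector& sizes, int act, const vec& wflat,
              const vec& maskflat) {
  Net net;
  net.L = sizes.size() - 1;
  net.act = act;
  net.n_in = sizes[0];
  net.n_out = sizes[net.L];
  net.masked = maskflat.n_elem > 0;
  std::size_t pos = 0;
  for (int l = 0; l < net.L; ++l) {
    int nin = sizes[l], nout = sizes[l + 1];
    mat W(nout, nin);
    for (int i = 0; i < nout; ++i)
      for (int j = 0; j < nin; ++j) W(i, j) = wflat[pos++];
    vec b(nout);
    for (int i = 0; i < nout; ++i) b[i] = wflat[pos++];
    net.W.push_back(W);
    net.b.push_back(b);
  }
  if (pos != wflat.n_elem) Rcpp::stop("weight vector length mismatch");
  if (net.masked) {
    std::size_t mp = 0;
    for (int l = 1; l < net.L; ++l) {  // hidden layers only
      int nh = sizes[l];
      net.maskscale.push_back(maskflat.subvec(mp, mp + nh - 1));
      mp += nh;
    }
    if (mp != maskflat.n_elem) Rcpp::stop("mask length mismatch");
  }
  return net;
}

// forward pass; stores layer activations a_0..a_{L-1} and, for each hidden
// layer, the elementwise derivative of its (masked) activation wrt its
// pre-activation.
vec net_forward(const Net& net, const vec& H0, std::vector<vec>& acts,
                std::vector<vec>& dact) {
  acts.clear();
  dact.clear();
  vec a = H0;
  acts.push_back(a);
  for (int l = 0; l < net.L - 1; ++l) {
    vec z = net.W[l] * a + net.b[l];
    vec s(z.n_elem), ds(z.n_elem);
    if (net.act == 0) {
      s = tanh(z);
      ds = 1.0 - s % s;
    } else {
      for (uword i = 0; i < z.n_elem; ++i) {
        // ReLU; subgradient at 0 taken as 0
        s[i] = z[i] > 0 ? z[i] : 0.0;
        ds[i] = z[i] > 0 ? 1.0 : 0.0;
      }
    }
    if (net.masked) {
      s %= net.maskscale[l];
      ds %= net.maskscale[l];
    }
    a = s;
    acts.push_back(a);
    dact.push_back(ds);
  }
  return net.W[net.L - 1] * a + net.b[net.L - 1];
}

mat net_jac_inputs(const Net& net, const std::vector<vec>& dact) {
  mat J = net.W[net.L - 1];
  for (int l = net.L - 2; l >= 0; --l) J = J * diagmat(dact[l]) * net.W[l];
  return J;
}

// d v / d (w, b) in the documented flattening order; n_out x nw
mat net_jac_weights(const Net& net, const std::vector<vec>& acts,
                    const std::vector<vec>& dact, int nw) {
  std::vector<mat> P(net.L);  // P[l] = d v / d z_l (pre-activation, layer l)
  P[net.L - 1] = eye(net.n_out, net.n_out);
  for (int l = net.L - 2; l >= 0; --l)
    P[l] = P[l + 1] * net.W[l + 1] * diagmat(dact[l]);
  mat Jw(net.n_out, nw, fill::zeros);
  std::size_t pos = 0;
  for (int l = 0; l < net.L; ++l) {
    int nin = acts[l].n_elem;
    int non = net.W[l].n_rows;
    for (int i = 0; i < non; ++i) {
      Jw.cols(pos, pos + nin - 1) = P[l].col(i) * acts[l].t();
      pos += nin;
    }
    Jw.cols(pos, pos + non - 1) = P[l];
    pos += non;
  }
  return Jw;
}

struct HybSpec {
  vec cmax;
  double vmax;     // <= 0 means no volume input
  int xv;          // 0-based index of Xv in c
  bool volin;
  bool clampin;
  mat cin;         // n_s x n_streams
};

// one right-hand-side evaluation; optionally the state Jacobian and the
// network weight Jacobian at this point
struct StageOut {
  vec v, dc;
  double dV;
  double XvClamped;
  mat Jy;    // (n_s+1) x (n_s+1)
  mat Wjac;  // n_out x nw
};

void stage_eval(const Net& net, const HybSpec& sp, const vec& c, double V,
                const rowvec& F, bool wantJ, bool wantW, int nw,
                StageOut& out) {
  const int ns = c.n_elem;
  vec cc = sp.clampin ? clamp(c, 0.0, datum::inf) : c;
  vec H0(net.n_in);
  H0.head(ns) = cc / sp.cmax;
  if (sp.volin) H0[ns] = V / sp.vmax;
  std::vector<vec> acts, dact;
  out.v = net_forward(net, H0, acts, dact);
  double Ftot = accu(F);
  vec feedin = (sp.cin * F.t()) / V;
  double Dtot = Ftot / V;
  double Xv = c[sp.xv];
  out.XvClamped = Xv;
  out.dc = out.v * Xv + feedin - c * Dtot;
  out.dV = Ftot;
  if (wantJ) {
    mat Jin = net_jac_inputs(net, dact);  // n_out x n_in
    vec dh(ns);
    for (int i = 0; i < ns; ++i)
      dh[i] = (sp.clampin && c[i] <= 0.0) ? 0.0 : 1.0 / sp.cmax[i];
    mat dvdc = Jin.cols(0, ns - 1);
    dvdc.each_row() %= dh.t();
    out.Jy.zeros(ns + 1, ns + 1);
    out.Jy.submat(0, 0, ns - 1, ns - 1) = Xv * dvdc;
    for (int i = 0; i < ns; ++i) {
      out.Jy(i, sp.xv) += out.v[i];
      out.Jy(i, i) -= Dtot;
    }
    vec dvdV(out.v.n_elem, fill::zeros);
    if (sp.volin) dvdV = Jin.col(ns) / sp.vmax;
    out.Jy.submat(0, ns, ns - 1, ns) = Xv * dvdV - feedin / V + c * (Dtot / V);
    // last row (dV/dt) does not depend on the state
  }
  if (wantW) {
    out.Wjac = net_jac_weights(net, acts, dact, nw);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_nn_forward(Rcpp::IntegerVector sizes, int act,
                          arma::vec wflat, arma::vec H0, arma::vec maskflat) {
  Net net = build_net(sizes, act, wflat, maskflat);
  std::vector<vec> acts, dact;
  vec v = net_forward(net, H0, acts, dact);
  return Rcpp::List::create(Rcpp::Named("v") = v);
}

// [[Rcpp::export]]
arma::mat cpp_nn_jac_inputs(Rcpp::IntegerVector sizes, int act,
                            arma::vec wflat, arma::vec H0, arma::vec maskflat) {
  Net net = build_net(sizes, act, wflat, maskflat);
  std::vector<vec> acts, dact;
  net_forward(net, H0, acts, dact);
  return net_jac_inputs(net, dact);
}

// [[Rcpp::export]]
arma::mat cpp_nn_jac_weights(Rcpp::IntegerVector sizes, int act,
                             arma::vec wflat, arma::vec H0,
                             arma::vec maskflat) {
  Net net = build_net(sizes, act, wflat, maskflat);
  std::vector<vec> acts, dact;
  net_forward(net, H0, acts, dact);
  return net_jac_weights(net, acts, dact, wflat.n_elem);
}

// Integrate one experiment; optionally propagate weight sensitivities and
// accumulate the weighted least-squares objective and its gradient.
//
// mode: 0 simulate only, 1 indirect sensitivities, 2 semidirect.
// grid: substep time grid (first entry = first output time).
// Fint: (length(grid)-1) x n_streams matrix of per-interval feed rates.
// out_idx: 0-based indices into grid at which outputs are reported.
// meas/sig: (length(out_idx)) x n_s matrices; NaN = missing (only used when
//           mode > 0).
//
// [[Rcpp::export]]
Rcpp::List cpp_run(Rcpp::IntegerVector sizes, int act, arma::vec wflat,
                   arma::vec maskflat, arma::vec cmax, double vmax,
                   int xv_idx0, bool volin, bool clampin, bool project,
                   arma::vec c0, double V0, arma::vec grid, arma::mat Fint,
                   arma::mat cin, arma::uvec out_idx, int mode,
                   arma::mat meas, arma::mat sig, bool want_jres) {
  Net net = build_net(sizes, act, wflat, maskflat);
  HybSpec sp;
  sp.cmax = cmax;
  sp.vmax = vmax;
  sp.xv = xv_idx0;
  sp.volin = volin;
  sp.clampin = clampin;
  sp.cin = cin;
  const int ns = c0.n_elem;
  const int ny = ns + 1;
  const int nw = wflat.n_elem;
  const int nout_t = out_idx.n_elem;
  if (net.n_out != ns) Rcpp::stop("network output count must equal species count");
  if (mode > 0 && project)
    Rcpp::stop("sensitivity propagation with state projection is not supported");

  vec c = c0;
  double V = V0;
  mat S;  // ny x nw sensitivity of the state wrt flattened weights
  if (mode > 0) S.zeros(ny, nw);

  mat C(nout_t, ns), RATES(nout_t, ns);
  vec Vout(nout_t);
  double ss = 0.0;
  int nres = 0;
  vec g_ss(nw, fill::zeros);
  mat Jres;
  std::vector<double> resid_v;
  std::vector<int> res_row, res_col;
  if (mode > 0 && want_jres) {
    int maxres = meas.n_elem;
    Jres.set_size(maxres, nw);
  }

  StageOut st1, st2, st3, st4;
  int oi = 0;
  const bool have_meas = meas.n_rows == (uword)nout_t;

  auto record = [&](int gi) {
    while (oi < nout_t && (int)out_idx[oi] == gi) {
      C.row(oi) = c.t();
      Vout[oi] = V;
      {  // diagnostics: network rates at the recorded state
        vec cc = sp.clampin ? clamp(c, 0.0, datum::inf) : c;
        vec H0(net.n_in);
        H0.head(ns) = cc / sp.cmax;
        if (sp.volin) H0[ns] = V / sp.vmax;
        std::vector<vec> acts, dact;
        RATES.row(oi) = net_forward(net, H0, acts, dact).t();
      }
      if (have_meas) {
        for (int s = 0; s < ns; ++s) {
          double m = meas(oi, s);
          if (!std::isfinite(m)) continue;
          double sg = sig(oi, s);
          double r = (c[s] - m) / sg;
          ss += r * r;
          if (mode > 0) {
            g_ss += (2.0 * r / sg) * S.row(s).t();
            if (want_jres) {
              Jres.row(nres) = S.row(s) / sg;
              resid_v.push_back(r);
              res_row.push_back(oi);
              res_col.push_back(s);
            }
          }
          ++nres;
        }
      }
      ++oi;
    }
  };

  record(0);

  const int nint = grid.n_elem - 1;
  for (int m = 0; m < nint; ++m) {
    double h = grid[m + 1] - grid[m];
    rowvec F = Fint.row(m);
    bool wj = mode > 0;

    stage_eval(net, sp, c, V, F, wj, wj, nw, st1);
    vec c2 = c + 0.5 * h * st1.dc;
    double V2 = V + 0.5 * h * st1.dV;
    stage_eval(net, sp, c2, V2, F, wj, wj, nw, st2);
    vec c3 = c + 0.5 * h * st2.dc;
    double V3 = V + 0.5 * h * st2.dV;
    stage_eval(net, sp, c3, V3, F, wj, wj, nw, st3);
    vec c4 = c + h * st3.dc;
    double V4 = V + h * st3.dV;
    stage_eval(net, sp, c4, V4, F, wj, wj, nw, st4);

    vec cnew = c + (h / 6.0) * (st1.dc + 2.0 * st2.dc + 2.0 * st3.dc + st4.dc);
    double Vnew = V + (h / 6.0) * (st1.dV + 2.0 * st2.dV + 2.0 * st3.dV + st4.dV);

    if (mode == 1) {
      // carry S through the stage recursion: exact derivative of the
      // discrete RK4 map (sensitivity source = dfdv * dv/dw at each stage)
      mat B1(ny, nw, fill::zeros), B2(ny, nw, fill::zeros),
          B3(ny, nw, fill::zeros), B4(ny, nw, fill::zeros);
      B1.rows(0, ns - 1) = st1.XvClamped * st1.Wjac;
      B2.rows(0, ns - 1) = st2.XvClamped * st2.Wjac;
      B3.rows(0, ns - 1) = st3.XvClamped * st3.Wjac;
      B4.rows(0, ns - 1) = st4.XvClamped * st4.Wjac;
      mat l1 = st1.Jy * S + B1;
      mat l2 = st2.Jy * (S + 0.5 * h * l1) + B2;
      mat l3 = st3.Jy * (S + 0.5 * h * l2) + B3;
      mat l4 = st4.Jy * (S + h * l3) + B4;
      S += (h / 6.0) * (l1 + 2.0 * l2 + 2.0 * l3 + l4);
    } else if (mode == 2) {
      // semidirect: carried quantities are the step transition A (ny x ny)
      // and per-stage output-channel sources N_i (ny x n_out) -- their
      // dimensions do not depend on nw; composition with the per-stage
      // network weight Jacobians happens outside the stage recursion.
      const mat& J1 = st1.Jy;
      const mat& J2 = st2.Jy;
      const mat& J3 = st3.Jy;
      const mat& J4 = st4.Jy;
      mat D1 = J1;
      mat D2 = J2 + (0.5 * h) * (J2 * D1);
      mat D3 = J3 + (0.5 * h) * (J3 * D2);
      mat D4 = J4 + h * (J4 * D3);
      mat A = eye(ny, ny) + (h / 6.0) * (D1 + 2.0 * D2 + 2.0 * D3 + D4);
      // Fv_i = dF/dv at stage i = [Xv_i * I_ns ; 0]; products J * Fv_i
      // reduce to Xv_i * (columns 0..ns-1 of J)
      auto JtimesFv = [&](const mat& J, double Xv) {
        return mat(Xv * J.cols(0, ns - 1));
      };
      mat e2_1 = (0.5 * h) * JtimesFv(J2, st1.XvClamped);
      mat e3_1 = (0.5 * h) * (J3 * e2_1);
      mat e3_2 = (0.5 * h) * JtimesFv(J3, st2.XvClamped);
      mat e4_1 = h * (J4 * e3_1);
      mat e4_2 = h * (J4 * e3_2);
      mat e4_3 = h * JtimesFv(J4, st3.XvClamped);
      mat Fv1(ny, ns, fill::zeros), Fv2(ny, ns, fill::zeros),
          Fv3(ny, ns, fill::zeros), Fv4(ny, ns, fill::zeros);
      Fv1.rows(0, ns - 1) = st1.XvClamped * eye(ns, ns);
      Fv2.rows(0, ns - 1) = st2.XvClamped * eye(ns, ns);
      Fv3.rows(0, ns - 1) = st3.XvClamped * eye(ns, ns);
      Fv4.rows(0, ns - 1) = st4.XvClamped * eye(ns, ns);
      mat N1 = (h / 6.0) * (Fv1 + 2.0 * e2_1 + 2.0 * e3_1 + e4_1);
      mat N2 = (h / 6.0) * (2.0 * Fv2 + 2.0 * e3_2 + e4_2);
      mat N3 = (h / 6.0) * (2.0 * Fv3 + e4_3);
      mat N4 = (h / 6.0) * Fv4;
      S = A * S + N1 * st1.Wjac + N2 * st2.Wjac + N3 * st3.Wjac + N4 * st4.Wjac;
    }

    c = cnew;
    V = Vnew;
    if (project) c = clamp(c, 0.0, datum::inf);

    if (!c.is_finite() || !std::isfinite(V) ||
        (mode > 0 && !S.is_finite())) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = grid[m + 1]);
    }
    record(m + 1);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("C") = C,
      Rcpp::Named("V") = Vout, Rcpp::Named("rates") = RATES,
      Rcpp::Named("ss") = ss, Rcpp::Named("nres") = nres,
      Rcpp::Named("g_ss") = g_ss);
  if (mode > 0 && want_jres) {
    out["jres"] = mat(Jres.rows(0, std::max(nres - 1, 0)));
    out["resid"] = Rcpp::NumericVector(resid_v.begin(), resid_v.end());
    out["res_time"] = Rcpp::IntegerVector(res_row.begin(), res_row.end());
    out["res_species"] = Rcpp::IntegerVector(res_col.begin(), res_col.end());
  }
  out["carried_dim"] =
      (mode == 2) ? Rcpp::IntegerVector::create(ny, ns)
                  : Rcpp::IntegerVector::create(ny, nw);
  return out;
}
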