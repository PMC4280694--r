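// Explicit-Euler integrator for compiled lumped-parameter networks.
//
// The network arrives as flat vectors (see compileNetwork() on the R side):
// storage elements (capacitors / variable-elastance chambers) own the node
// pressures; resistive branches are algebraic; inductive branches carry a
// flow state.  State layout: [storage volumes, inductive flows].

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double raisedCosine(double t, double onset, double Tsys,
                                  double period) {
  double u = (t - onset) / period;
  double tau = (u - std::floor(u)) * period;  // wrap into [0, period)
  if (tau >= Tsys) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * tau / Tsys));
}

// [[Rcpp::export(name = ".eulerRunCpp")]]
List eulerRunCpp(List net, NumericVector state0, double t0, int nsteps,
                 double dt, int recordEvery, double divergenceBound) {
  const IntegerVector stor_node = net["stor_node"];
  const IntegerVector stor_type = net["stor_type"];  // 0 cap, 1 chamber
  const NumericVector stor_C = net["stor_C"];
  const NumericVector stor_Vu = net["stor_Vu"];
  const NumericVector stor_Emax = net["stor_Emax"];
  const NumericVector stor_Emin = net["stor_Emin"];
  const NumericVector stor_V0 = net["stor_V0"];
  const NumericVector stor_onset = net["stor_onset"];
  const NumericVector stor_Tsys = net["stor_Tsys"];
  const IntegerVector stor_ext = net["stor_ext"];  // 0 ambient, 1 Pt, 2 gamma*Plv
  const IntegerVector res_up = net["res_up"];
  const IntegerVector res_down = net["res_down"];
  const IntegerVector res_type = net["res_type"];  // 0 linear, 1 diode, 2 flow-dep
  const NumericVector res_R = net["res_R"];
  const NumericVector res_k = net["res_k"];
  const IntegerVector ind_up = net["ind_up"];
  const IntegerVector ind_down = net["ind_down"];
  const NumericVector ind_R = net["ind_R"];
  const NumericVector ind_L = net["ind_L"];
  const IntegerVector node_stor = net["node_stor"];
  const double Pt = as<double>(net["Pt"]);
  const double gamma = as<double>(net["gamma"]);
  const double septal = as<double>(net["septal"]);
  const double period = as<double>(net["period"]);
  const int lv = as<int>(net["lv_stor"]);  // 0-based, -1 if absent
  const int rv = as<int>(net["rv_stor"]);

  const int ns = stor_node.size();
  const int nr = res_up.size();
  const int ni = ind_up.size();
  const int nn = node_stor.size();
  const int nstate = ns + ni;
  if (state0.size() != nstate) stop("state vector length mismatch");

  int nrec = nsteps / recordEvery + 1;
  if (nsteps % recordEvery != 0) nrec += 1;
  NumericVector time(nrec);
  NumericMatrix series(nrec, ns + nn + nr + ni);

  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> Pstor(ns), Pnode(nn), Qres(nr), dx(nstate);
  int row = 0, badSlot = -1, badStep = -1;

  for (int i = 0; i <= nsteps; ++i) {
    const double t = t0 + i * dt;

    // chamber pressures first (the intramyocardial reference needs Plv)
    for (int s = 0; s < ns; ++s) {
      if (stor_type[s] == 1) {
        double a = raisedCosine(t, stor_onset[s], stor_Tsys[s], period);
        double e = stor_Emin[s] + (stor_Emax[s] - stor_Emin[s]) * a;
        double pext = (stor_ext[s] == 1) ? Pt : 0.0;
        Pstor[s] = e * (x[s] - stor_V0[s]) + pext;
      }
    }
    if (septal != 0.0 && lv >= 0 && rv >= 0) {
      double plv = Pstor[lv], prv = Pstor[rv];
      Pstor[lv] = plv + septal * (prv - Pt);
      Pstor[rv] = prv + septal * (plv - Pt);
    }
    const double plvNow = (lv >= 0) ? Pstor[lv] : 0.0;
    for (int s = 0; s < ns; ++s) {
      if (stor_type[s] == 0) {
        double pext = 0.0;
        if (stor_ext[s] == 1) pext = Pt;
        else if (stor_ext[s] == 2) pext = gamma * plvNow;
        Pstor[s] = (x[s] - stor_Vu[s]) / stor_C[s] + pext;
      }
    }
    for (int n = 0; n < nn; ++n) Pnode[n] = Pstor[node_stor[n]];

    std::fill(dx.begin(), dx.end(), 0.0);
    for (int r = 0; r < nr; ++r) {
      const double dp = Pnode[res_up[r]] - Pnode[res_down[r]];
      double q;
      if (res_type[r] == 1) {
        q = dp > 0.0 ? dp / res_R[r] : 0.0;
      } else if (res_type[r] == 2) {
        // invert dP = R0*q + k*q*|q| (sign-preserving quadratic)
        const double k = res_k[r], R0 = res_R[r];
        if (k <= 0.0) {
          q = dp / R0;
        } else {
          const double ad = std::fabs(dp);
          q = (-R0 + std::sqrt(R0 * R0 + 4.0 * k * ad)) / (2.0 * k);
          if (dp < 0.0) q = -q;
        }
      } else if (res_type[r] == 3) {
        // vascular waterfall: drains against max(downstream, gamma*Plv)
        double back = Pnode[res_down[r]];
        double pim = gamma * plvNow;
        if (pim > back) back = pim;
        double g = Pnode[res_up[r]] - back;
        q = g > 0.0 ? g / res_R[r] : 0.0;
      } else {
        q = dp / res_R[r];
      }
      Qres[r] = q;
      dx[node_stor[res_up[r]]] -= q;
      dx[node_stor[res_down[r]]] += q;
    }
    for (int b = 0; b < ni; ++b) {
      const double q = x[ns + b];
      dx[node_stor[ind_up[b]]] -= q;
      dx[node_stor[ind_down[b]]] += q;
      dx[ns + b] = (Pnode[ind_up[b]] - Pnode[ind_down[b]] - ind_R[b] * q) /
                   ind_L[b];
    }

    if (i % recordEvery == 0 || i == nsteps) {
      time[row] = t;
      for (int s = 0; s < ns; ++s) series(row, s) = x[s];
      for (int n = 0; n < nn; ++n) series(row, ns + n) = Pnode[n];
      for (int r = 0; r < nr; ++r) series(row, ns + nn + r) = Qres[r];
      for (int b = 0; b < ni; ++b) series(row, ns + nn + nr + b) = x[ns + b];
      ++row;
    }
    if (i == nsteps) break;

    for (int j = 0; j < nstate; ++j) {
      x[j] += dt * dx[j];
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > divergenceBound) {
        if (badSlot < 0) { badSlot = j; badStep = i + 1; }
      }
    }
    if (badSlot >= 0) break;
  }

  return List::create(_["time"] = time, _["series"] = series,
                      _["state"] = NumericVector(x.begin(), x.end()),
                      _["rows"] = row, _["badSlot"] = badSlot + 1,
                      _["badStep"] = badStep);
}
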